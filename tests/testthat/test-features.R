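test_that("kinetic features follow the enhancement-ratio definitions", {
  dc <- disk_case(si = c(100, 250, 175))
  kin <- kinetic_features(dc$series, dc$mask)
  expect_equal(kin$slope, 1.5, tolerance = 1e-12)
  expect_equal(kin$ser, 2.0, tolerance = 1e-12)

  # no enhancement at all: both zero
  flat <- disk_case(si = c(100, 100, 100))
  kin0 <- kinetic_features(flat$series, flat$mask)
  expect_equal(kin0$slope, 0)
  expect_equal(kin0$ser, 0)

  # plateau (last = first): SER exactly 1
  pl <- disk_case(si = c(100, 250, 250))
  expect_equal(kinetic_features(pl$series, pl$mask)$ser, 1, tolerance = 1e-12)

  # washout to baseline: SER undefined, flagged missing
  wb <- disk_case(si = c(100, 250, 100))
  expect_warning(kw <- kinetic_features(wb$series, wb$mask), "SER")
  expect_true(is.na(kw$ser))

  neg <- disk_case(si = c(-5, 10, 10))
  expect_error(kinetic_features(neg$series, neg$mask), "pre-contrast")
})

test_that("morphological descriptors are correct on canonical shapes", {
  # disk: round, solid, concentric
  dc <- disk_case(radius = 20)
  geo <- geometry_from_contour(dc$poly, dim(dc$mask))
  m <- morphological_features(geo, 1, image = dc$series$first)
  expect_gte(m$circularity, 0.95)
  expect_gte(m$solidity, 0.98)
  expect_lte(m$eccentricity, 0.1)
  expect_lte(m$elongation, 1.05)
  expect_lte(m$radial_length_entropy, 0.5)
  expect_equal(m$area, sum(dc$mask))
  expect_gte(m$fractal_dimension, 1); expect_lte(m$fractal_dimension, 2)

  # star polygon: spiculation counts the planted zero crossings exactly
  theta <- seq(0, 2 * pi, length.out = 161)[-161]
  star <- cbind(r = 47.5 + 20 * (1 + 0.3 * cos(8 * theta)) * sin(theta),
                c = 47.5 + 20 * (1 + 0.3 * cos(8 * theta)) * cos(theta))
  gs <- geometry_from_contour(star, c(96, 96))
  ms <- morphological_features(gs, 1)
  expect_equal(ms$spiculation, 16 / 160, tolerance = 1e-12)

  # axis-aligned rectangle: extent and solidity 1 up to rasterisation
  rect <- cbind(r = c(10, 10, 30, 30) - 0.5, c = c(10, 40, 40, 10) - 0.5)
  gr <- geometry_from_contour(rect, c(64, 64))
  mr <- morphological_features(gr, 1)
  expect_equal(mr$extent, 1.0, tolerance = 1e-6)
  expect_equal(mr$solidity, 1.0, tolerance = 0.02)

  # physical units: area scales with spacing^2, dimensionless shapes do not
  m2 <- morphological_features(geo, 2, image = dc$series$first)
  expect_equal(m2$area, 4 * m$area)
  expect_equal(m2$circularity, m$circularity, tolerance = 1e-12)
  expect_equal(m2$solidity, m$solidity, tolerance = 1e-12)
  expect_equal(m2$extent, m$extent, tolerance = 1e-12)
})

test_that("GLCM accumulation matches hand enumeration and is symmetric", {
  # [[0,0],[1,1]] in (row, col) layout, horizontal offset only, symmetric:
  # two like-pairs -> all mass on the diagonal
  img <- rbind(c(0, 0), c(1, 1))
  g <- build_glcm(img, matrix(TRUE, 2, 2),
                  glcm_spec(n_levels = 2, offsets = rbind(c(0, 1))))
  expect_equal(unclass(g), rbind(c(0.5, 0), c(0, 0.5)))

  # constant image: single cell, sums to 1
  gc <- build_glcm(matrix(5, 4, 4), matrix(TRUE, 4, 4), glcm_spec(n_levels = 8))
  expect_equal(sum(gc), 1)
  expect_equal(gc[1, 1], 1)

  # symmetry postcondition on random masked images
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(runif(64), 8, 8)
    mask <- matrix(runif(64) > 0.3, 8, 8)
    if (sum(mask) < 4) next
    g <- build_glcm(img, mask, glcm_spec(n_levels = 8))
    expect_equal(g, t(g), tolerance = 1e-12)
    expect_equal(sum(g), 1, tolerance = 1e-12)
  }

  expect_error(build_glcm(matrix(1, 2, 2), matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2),
                          glcm_spec(n_levels = 2, offsets = rbind(c(0, 1)))),
               "no valid pixel pairs")
})

test_that("Haralick statistics evaluate exactly on degenerate matrices", {
  # uniform 2x2 GLCM
  h <- haralick_features(matrix(0.25, 2, 2))
  expect_equal(h$asm, 0.25)
  expect_equal(h$entropy, 2)
  expect_equal(h$contrast, 0.5)
  expect_equal(h$inverse_difference, 0.75)

  # all mass in one cell
  p1 <- matrix(0, 3, 3); p1[2, 2] <- 1
  h1 <- haralick_features(p1)
  expect_equal(h1$asm, 1)
  expect_equal(h1$entropy, 0)
  expect_equal(h1$contrast, 0)
  expect_equal(h1$inverse_difference, 1)

  expect_error(haralick_features(matrix(0.5, 2, 2)), "sum to 1")
})

test_that("all 13 Haralick features match the brute-force oracle", {
  set.seed(77)
  for (rep in 1:20) {
    img <- matrix(runif(64), 8, 8)
    mask <- matrix(runif(64) > 0.25, 8, 8)
    if (sum(mask) < 6) next
    g <- build_glcm(img, mask, glcm_spec(n_levels = 6))
    got <- haralick_features(g)
    ref <- oracle_haralick(g)
    for (nm in names(ref)) {
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-10, label = nm,
                   ignore_attr = TRUE)
    }
  }
})

test_that("ADC estimation inverts the diffusion decay and applies the area rule", {
  dc <- disk_case(s0 = 1000, adc = 1.5)
  res <- adc_features(dc$dwi, dc$mask, 1)
  expect_equal(res$mean_adc, 1.5, tolerance = 1e-4)
  expect_true(res$valid)

  # S_b = S_0 everywhere: ADC map identically zero
  same <- dc$dwi; same$bhigh <- same$b0
  r0 <- adc_features(same, dc$mask, 1)
  expect_true(all(r0$adc_map[dc$mask] == 0))

  # high-signal region below 20 mm^2 is flagged invalid
  tiny <- disk_case(radius = 6, n = 64)       # ~113 px
  shrunk <- adc_features(tiny$dwi, tiny$mask, pixel_spacing_mm = 0.4)
  expect_false(shrunk$valid)                  # 113 * 0.16 = 18.1 mm^2 < 20
  expect_lt(shrunk$roi_area_mm2, 20)
})

test_that("planted ADC and kinetics are recovered through the full chain", {
  co <- small_cohort()
  cfg <- co$config
  for (i in c(1, 2)) {
    cs <- co$cases[[i]]
    img0 <- render_case(cs, cfg, noise_scale = 0)
    geo <- geometry_from_contour(cs$true_contour, rep(cfg$image_size, 2))
    adc <- adc_features(img0$dwi, geo$mask, cfg$pixel_spacing_mm)
    expect_equal(adc$mean_adc, cs$true_adc_mean, tolerance = 0.01)
    kin <- kinetic_features(img0$series, geo$mask)
    expect_equal(kin$slope, cs$true_slope, tolerance = 0.01)
    expect_equal(kin$ser, cs$true_ser, tolerance = 0.01)
  }
  # with default noise the ADC error stays within 5% (median over cases)
  errs <- vapply(co$cases, function(cs) {
    geo <- geometry_from_contour(cs$true_contour, rep(cfg$image_size, 2))
    adc <- adc_features(cs$images$dwi, geo$mask, cfg$pixel_spacing_mm)
    abs(adc$mean_adc - cs$true_adc_mean) / cs$true_adc_mean
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the assembled table carries exactly the 28-feature registry", {
  co <- small_cohort()
  ft <- suppressMessages(assemble_features(co))
  reg <- feature_registry()
  expect_equal(nrow(reg), 28)
  expect_setequal(setdiff(names(ft), c("case_id", "label")), reg$name)
  expect_false(anyNA(ft[reg$name]))
  g <- feature_groups(ft)
  expect_equal(unname(table(g)[c("pathology", "kinetic", "morphology",
                                 "texture", "dwi")]),
               c(1L, 2L, 11L, 13L, 1L), ignore_attr = TRUE)
  # duplicate ids refused
  co2 <- co
  co2$cases[[2]]$case_id <- co2$cases[[1]]$case_id
  expect_error(suppressMessages(assemble_features(co2)), "duplicate")
})

test_that("texture and shape features are robust to 90-degree rotation", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  cfg <- co$config
  n <- cfg$image_size
  geo <- geometry_from_contour(cs$true_contour, c(n, n))
  img <- cs$images$series$first
  # rotate image and mask by 90 degrees
  rot <- function(m) t(m)[, nrow(m):1]  # new(i,j) = old(N-j+1, i)
  poly_rot <- cbind(r = cs$true_contour[, 2], c = n - 1 - cs$true_contour[, 1])
  geo_r <- geometry_from_contour(poly_rot, c(n, n))
  img_r <- rot(img)
  expect_equal(sum(geo$mask), sum(geo_r$mask))
  t1 <- haralick_features(build_glcm(img, geo$mask))
  t2 <- haralick_features(build_glcm(img_r, geo_r$mask))
  for (nm in names(t1)) {
    expect_equal(t1[[nm]], t2[[nm]], tolerance = 0.01, label = nm)
  }
  m1 <- morphological_features(geo, 1, img)
  m2 <- morphological_features(geo_r, 1, img_r)
  for (nm in c("area", "circularity", "solidity", "extent", "eccentricity",
               "elongation", "spiculation", "heterogeneity")) {
    expect_equal(m1[[nm]], m2[[nm]], tolerance = 0.02, label = nm)
  }
})

test_that("feature aliases resolve to canonical registry names", {
  expect_equal(canonical_feature_name(c("Energy", "Inertia", "Rectangular degree")),
               c("asm", "contrast", "extent"))
  expect_equal(canonical_feature_name("Information Correlation 1"), "info_correlation_1")
  expect_equal(canonical_feature_name("adc"), "adc")
  expect_error(canonical_feature_name("bogus"), "unknown feature")
})
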