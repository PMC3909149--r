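test_that("FCM clustering satisfies its update-rule contracts", {
  # reference iteration as oracle on well-separated 1-D data
  x <- c(0, 0, 0, 10, 10, 10) + c(0.01, -0.01, 0, 0.01, -0.01, 0)
  fit <- fcm_cluster(x, c = 2, m = 2, tol = 1e-10)
  ref <- oracle_fcm(x, centers = quantile(x, c(0.1, 0.9), names = FALSE))
  expect_equal(fit$centers, ref, tolerance = 1e-6)

  # membership normalisation and range at convergence
  set.seed(2)
  y <- c(rnorm(60, 0, 1), rnorm(60, 8, 1))
  fit2 <- fcm_cluster(y, c = 2)
  expect_true(all(abs(rowSums(fit2$memberships) - 1) < 1e-12))
  expect_true(all(fit2$memberships >= 0 & fit2$memberships <= 1))

  # objective descent, every step
  expect_true(all(diff(fit2$objective_history) <= 1e-9))

  # symmetry: a point equidistant from both centers gets (1/2, 1/2)
  z <- c(rep(0, 10), rep(10, 10), 5)
  f3 <- fcm_cluster(z, c = 2)
  mid <- which(z == 5)
  expect_equal(unname(f3$memberships[mid, ]), c(0.5, 0.5), tolerance = 1e-6)

  expect_error(fcm_cluster(rep(1, 50), c = 2), "distinct")
  expect_error(fcm_cluster(y, c = 1), "c must be")

  # cross-check against the established implementation
  cm <- e1071::cmeans(matrix(y), centers = matrix(c(0, 8)), m = 2)
  expect_equal(sort(as.numeric(cm$centers)), fcm_cluster(y, 2)$centers,
               tolerance = 1e-3)
})

test_that("initial mask keeps the largest bright component and fills holes", {
  img <- matrix(100, 40, 40)
  img[10:25, 10:25] <- 250   # main blob
  img[30:32, 30:32] <- 250   # small distractor
  img[17, 17] <- 100         # interior hole at the cluster level
  fit <- fcm_cluster(as.vector(img), c = 2)
  m <- initial_mask(fit, dim(img))
  expect_true(all(m[10:25, 10:25]))   # hole filled
  expect_false(any(m[30:32, 30:32]))  # distractor dropped
  expect_equal(sum(m), 16 * 16)
})

test_that("GVF field behaves like a diffused edge gradient", {
  # uniform edge map: zero field, with a warning
  expect_warning(f0 <- gvf_field(matrix(1, 16, 16)), "zero gradient")
  expect_true(all(f0$vr == 0) && all(f0$vc == 0))

  # vertical step edge: columns point toward the edge from both sides
  em <- matrix(0, 32, 32); em[, 16] <- 1
  f <- gvf_field(em, mu = 0.2, iters = 200)
  mid <- 8:24
  expect_true(all(f$vc[mid, 10:14] > 0))   # left of edge: push right
  expect_true(all(f$vc[mid, 18:22] < 0))   # right of edge: push left
  expect_true(max(abs(f$vr[mid, c(10:14, 18:22)])) <
                0.1 * max(abs(f$vc[mid, c(10:14, 18:22)])))

  # field magnitude never exceeds the (normalised) edge gradient's maximum
  g <- massdx:::image_gradient(em / max(em))
  expect_lte(max(sqrt(f$vr^2 + f$vc^2)),
             max(sqrt(g$dr^2 + g$dc^2)) + 1e-9)
  expect_true(all(is.finite(f$vr)) && all(is.finite(f$vc)))
})

test_that("the snake respects its fixed points and convergence contract", {
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  circle <- cbind(r = 16 + 8 * sin(theta), c = 16 + 8 * cos(theta))
  zf <- list(vr = matrix(0, 33, 33), vc = matrix(0, 33, 33))
  # no internal energy, no force: exact fixed point
  out <- evolve_snake(circle, zf, snake_params(alpha = 0, beta = 0,
                                               snake_iters = 25, n_vertices = 64))
  expect_true(attr(out, "converged"))
  rad <- sqrt(rowSums(sweep(unclass(out), 2, c(16, 16))^2))
  expect_equal(rad, rep(8, 64), tolerance = 1e-6)

  # vertex spacing uniform within 10 percent after evolution
  d <- unclass(out); d2 <- d[c(2:64, 1), ] - d
  seg <- sqrt(rowSums(d2^2))
  expect_lt((max(seg) - min(seg)) / mean(seg), 0.1)

  expect_error(evolve_snake(circle[1:8, ], zf), ">= 16")
})

test_that("the snake converges onto a disk edge from a distant circle", {
  dc <- disk_case(radius = 20, n = 96)
  roi <- dc$series$first[11:86, 11:86]
  eg <- massdx:::image_gradient(massdx:::gaussian_blur(roi, 1.0))
  field <- gvf_field(eg$dr^2 + eg$dc^2, mu = 0.05, iters = 60)
  theta <- seq(0, 2 * pi, length.out = 97)[-97]
  init <- cbind(r = 37.5 + 26 * sin(theta), c = 37.5 + 26 * cos(theta))
  out <- evolve_snake(init, field, snake_params(snake_iters = 300))
  rad <- sqrt(rowSums(sweep(unclass(out), 2, colMeans(unclass(out)))^2))
  expect_lt(mean(abs(rad - 20)), 1)

  # running longer after convergence changes nothing appreciable
  out2 <- evolve_snake(init, field, snake_params(snake_iters = 600))
  expect_lt(mean(abs(unclass(out2) - unclass(out))), 0.05)
})

test_that("full segmentation recovers phantom lesions", {
  co <- small_cohort()
  cfg <- co$config
  n <- cfg$image_size
  # noiseless: near-perfect recovery for both classes
  idx <- c(which(co$truth$label == "benign")[1],
           which(co$truth$label == "malignant")[1])
  for (i in idx) {
    cs <- co$cases[[i]]
    img0 <- render_case(cs, cfg, noise_scale = 0)
    geo <- segment_lesion(img0$series, cs$roi_box)
    tru <- massdx:::rasterize_polygon(cs$true_contour, c(n, n))
    expect_gte(dice_coefficient(geo$mask, tru), 0.98)
    expect_true(massdx:::polygon_is_simple(geo$contour))
    lab <- EBImage::bwlabel(geo$mask * 1)
    expect_equal(max(lab), 1)  # single connected component
  }
  # an ROI with no lesion fails loudly
  flat <- list(first = co$cases[[1]]$images$series$first)
  expect_error(segment_lesion(flat, c(r0 = 0, c0 = 0, r1 = 20, c1 = 20)),
               "segment_lesion")
})
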