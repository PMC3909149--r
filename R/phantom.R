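#' Configuration for the DCE-MRI / DWI phantom cohort
#'
#' Defines the statistical structure of the simulated cohort. Defaults
#' emulate the reference clinical cohort: 234 cases with 149 malignant and
#' 85 benign lesions (malignant fraction 149/234), patient ages truncated to
#' 18-78 years with class means chosen so the cohort mean is about 46
#' years, malignant lesions with washout kinetics (SER > 1), spiculated
#' boundaries, heterogeneous texture and low ADC (mean 1.0e-3 mm^2/s), and
#' benign lesions with persistent enhancement (SER < 1), smooth boundaries
#' and high ADC (mean 1.7e-3 mm^2/s).
#'
#' Per class, `shape` holds `mean_radius_px`, `radius_sd_px`, `spike_count`
#' (a (min, max) range sampled per case), `spike_amplitude` with
#' `spike_amplitude_sd` (case-level draw, fraction of the radius) and
#' `boundary_noise` (fractional sd of a smooth periodic perturbation);
#' `kinetics` holds `si_pre`,
#' `enh_mean`/`enh_sd` (first-post enhancement fraction), `washout_mean`/
#' `washout_sd` (fractional signal loss from first to last post frame;
#' negative = persistent rise) and `noise_sd` (multiplicative pixel noise);
#' `texture` holds the intra-lesion multiplicative field sd (class mean
#' `sd`, case-level spread `sd_sd`) and its spatial correlation length in
#' px (class mean `corr_len`, case-level spread `corr_len_sd`); `adc` holds the between-case mean and sd in
#' 1e-3 mm^2/s; `age` holds mean and sd in years.
#'
#' @param n_cases number of cases (>= 20 so 10-fold CV is feasible).
#' @param malignant_fraction proportion of malignant cases, in (0,1).
#' @param image_size image side length in pixels (>= 64).
#' @param pixel_spacing_mm pixel spacing, mm per pixel.
#' @param b_value_high high diffusion weighting, s/mm^2.
#' @param seed integer seed controlling the whole cohort.
#' @param age_bounds truncation bounds for sampled ages, years.
#' @param benign,malignant,background per-tissue parameter lists; any field
#'   supplied overrides the default of that class.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_cases = 234,
                           malignant_fraction = 149 / 234,
                           image_size = 128,
                           pixel_spacing_mm = 1,
                           b_value_high = 800,
                           seed = 1,
                           age_bounds = c(18, 78),
                           benign = list(),
                           malignant = list(),
                           background = list()) {
  def_benign <- list(
    shape = list(mean_radius_px = 18, radius_sd_px = 2, spike_count = c(5, 10),
                 spike_amplitude = 0.16, spike_amplitude_sd = 0.07,
                 boundary_noise = 0.05),
    kinetics = list(si_pre = 100, enh_mean = 0.80, enh_sd = 0.35,
                    washout_mean = -0.10, washout_sd = 0.15, noise_sd = 0.05),
    texture = list(sd = 0.09, sd_sd = 0.035, corr_len = 2.5, corr_len_sd = 0.7),
    adc = list(mean = 1.7, sd = 0.5),
    age = list(mean = 41, sd = 10)
  )
  def_malignant <- list(
    shape = list(mean_radius_px = 18, radius_sd_px = 2, spike_count = c(6, 11),
                 spike_amplitude = 0.18, spike_amplitude_sd = 0.07,
                 boundary_noise = 0.05),
    kinetics = list(si_pre = 100, enh_mean = 1.20, enh_sd = 0.35,
                    washout_mean = 0.20, washout_sd = 0.15, noise_sd = 0.05),
    texture = list(sd = 0.12, sd_sd = 0.045, corr_len = 1.5, corr_len_sd = 0.5),
    adc = list(mean = 1.0, sd = 0.5),
    age = list(mean = 49.5, sd = 10)
  )
  def_background <- list(si_pre = 100, enh = 0.1, washout = 0,
                         s0 = 300, adc = 2.2, lesion_s0 = 800)
  merge2 <- function(def, usr) {
    for (nm in names(usr)) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        utils::modifyList(def[[nm]], usr[[nm]])
      } else usr[[nm]]
    }
    def
  }
  cfg <- structure(list(
    n_cases = n_cases, malignant_fraction = malignant_fraction,
    image_size = image_size, pixel_spacing_mm = pixel_spacing_mm,
    b_value_high = b_value_high, seed = seed, age_bounds = age_bounds,
    roi_margin_px = 8,
    benign = merge2(def_benign, benign),
    malignant = merge2(def_malignant, malignant),
    background = merge2(def_background, background)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (!is_count(cfg$n_cases) || cfg$n_cases < 20) {
    stopf("n_cases must be an integer >= 20 (10-fold CV infeasible below that)")
  }
  if (!is_number(cfg$malignant_fraction) || cfg$malignant_fraction <= 0 ||
      cfg$malignant_fraction >= 1) {
    stopf("malignant_fraction must lie strictly inside (0,1)")
  }
  if (!is_count(cfg$image_size) || cfg$image_size < 64) {
    stopf("image_size must be an integer >= 64")
  }
  if (!is_number(cfg$pixel_spacing_mm) || cfg$pixel_spacing_mm <= 0) {
    stopf("pixel_spacing_mm must be positive")
  }
  for (cls in c("benign", "malignant")) {
    p <- cfg[[cls]]
    if (p$adc$mean <= 0) stopf("%s ADC mean must be positive", cls)
    sds <- c(p$shape$radius_sd_px, p$kinetics$enh_sd, p$kinetics$washout_sd,
             p$kinetics$noise_sd, p$texture$sd, p$adc$sd, p$age$sd,
             p$shape$boundary_noise)
    if (any(sds < 0)) stopf("%s: all sd parameters must be >= 0", cls)
    if (any(p$shape$spike_count < 0)) stopf("%s: spike_count must be >= 0", cls)
  }
  invisible(cfg)
}

#' Simulate a lesion boundary polygon
#'
#' Benign lesions get a near-elliptical low-perturbation boundary; malignant
#' lesions a star-shaped boundary r(theta) = R (1 + a cos(k theta + phase))
#' plus a smooth periodic noise term, emulating spiculated margins. The
#' polygon is returned centred at `center` with at least 64 vertices,
#' uniformly spaced in angle, closed implicitly (last vertex connects to the
#' first) and guaranteed simple.
#'
#' @param label "benign" or "malignant" (only used for error messages; the
#'   class difference is carried by `shape_params`).
#' @param shape_params list with `mean_radius_px`, `spike_count`,
#'   `spike_amplitude`, `boundary_noise` (and optionally `radius_sd_px`,
#'   already resolved to a concrete radius by the caller via `radius`).
#' @param center (row, col) 0-based center.
#' @param n_vertices number of boundary vertices (>= 64).
#' @param radius optional concrete mean radius overriding
#'   `shape_params$mean_radius_px`.
#' @return matrix with columns `r`, `c`: 0-based (row, col) vertices.
#' @export
make_lesion_shape <- function(label, shape_params, center = c(0, 0),
                              n_vertices = 128, radius = NULL) {
  R <- if (is.null(radius)) shape_params$mean_radius_px else radius
  if (is.null(R) || !is_number(R) || R < 5) {
    stopf("lesion mean radius must be >= 5 px, got %s", toString(R))
  }
  k <- shape_params$spike_count
  a <- shape_params$spike_amplitude
  if (k < 0) stopf("spike_count must be >= 0")
  n_vertices <- max(64L, as.integer(n_vertices))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  phase <- stats::runif(1, 0, 2 * pi)
  r <- R * (1 + a * cos(k * theta + phase))
  noise <- shape_params$boundary_noise
  if (noise > 0) {
    # smooth periodic perturbation: 3 low harmonics with random phase
    for (h in 2:4) {
      r <- r + R * noise * stats::rnorm(1) * cos(h * theta + stats::runif(1, 0, 2 * pi))
    }
  }
  r <- pmax(r, 0.3 * R)  # avoid collapse onto the centroid
  poly <- cbind(r = center[1] + r * sin(theta), c = center[2] + r * cos(theta))
  if (!polygon_is_simple(poly)) {
    # extreme parameter draws can self-intersect; smooth radially until simple
    for (pass in 1:5) {
      r <- (r + r[c(2:n_vertices, 1)] + r[c(n_vertices, 1:(n_vertices - 1))]) / 3
      poly <- cbind(r = center[1] + r * sin(theta), c = center[2] + r * cos(theta))
      if (polygon_is_simple(poly)) break
    }
    if (!polygon_is_simple(poly)) stopf("%s lesion boundary is irreparably self-intersecting", label)
  }
  poly
}

#' Render one phantom case to image frames
#'
#' Produces the three-frame dynamic series (pre-contrast, first and last
#' post-contrast) and the diffusion pair (b = 0 and the high b-value). Inside
#' the lesion, frame means follow the case's true kinetics and the
#' diffusion pair satisfies S_b = S_0 exp(-b ADC) pixelwise before noise;
#' background tissue has flat kinetics and higher ADC. A spatially
#' correlated multiplicative texture field (shared across frames, i.e. a
#' tissue property) and independent multiplicative pixel noise are applied
#' within the lesion.
#'
#' @param phantom a `case_phantom` as produced by [generate_cohort()] (or
#'   hand-built: needs `label`, `true_contour`, `true_kinetics`,
#'   `true_adc_mean`).
#' @param config a [phantom_config()].
#' @param noise_scale multiplier on all noise sds (0 gives a noiseless
#'   render of the same case).
#' @return list with `series` (list `pre`, `first`, `last`),
#'   `dwi` (list `b0`, `bhigh`, `b_value`) and `mask` (true lesion mask).
#' @export
render_case <- function(phantom, config, noise_scale = 1) {
  n <- config$image_size
  ctr <- phantom$true_contour
  if (min(ctr) < 0 || max(ctr) > n - 1) stopf("lesion exceeds image bounds")
  mask <- rasterize_polygon(ctr, c(n, n))
  cls <- config[[phantom$label]]
  bg <- config$background
  kin <- phantom$true_kinetics
  tex_sd <- (phantom$true_texture_sd %||% cls$texture$sd) * noise_scale
  tex_corr <- phantom$true_texture_corr_len %||% cls$texture$corr_len
  tex <- if (tex_sd > 0) {
    1 + tex_sd * gaussian_field(n, n, tex_corr)
  } else matrix(1, n, n)
  noise_sd <- cls$kinetics$noise_sd * noise_scale
  pix_noise <- function() {
    if (noise_sd > 0) matrix(1 + noise_sd * stats::rnorm(n * n), n, n) else 1
  }
  frame <- function(lesion_val, bg_val, textured = TRUE) {
    img <- matrix(bg_val, n, n)
    img[mask] <- lesion_val
    if (textured) img[mask] <- img[mask] * tex[mask]
    img * pix_noise()
  }
  series <- list(
    pre   = frame(kin[["si_pre"]],  bg$si_pre),
    first = frame(kin[["si_first"]], bg$si_pre * (1 + bg$enh)),
    last  = frame(kin[["si_last"]],  bg$si_pre * (1 + bg$enh) * (1 - bg$washout))
  )
  b <- config$b_value_high
  s0_lesion <- bg$lesion_s0
  s0 <- frame(s0_lesion, bg$s0)
  adc_map <- matrix(bg$adc, n, n)
  adc_map[mask] <- phantom$true_adc_mean
  # ADC in 1e-3 mm^2/s, b in s/mm^2: exponent = b * 1e-3 * ADC
  decay <- exp(-b * 1e-3 * adc_map)
  bhigh0 <- matrix(bg$s0, n, n)
  bhigh0[mask] <- s0_lesion * tex[mask]
  bhigh <- bhigh0 * decay * pix_noise()
  list(series = series,
       dwi = list(b0 = s0, bhigh = bhigh, b_value = b),
       mask = mask)
}

#' Generate a phantom cohort
#'
#' Draws `n_cases` cases with class counts `round(malignant_fraction *
#' n_cases)` malignant and the rest benign, samples per-case lesion shape,
#' kinetics, texture, ADC and age from the per-class distributions in
#' `config`, renders every case, and returns the cases together with a
#' ground-truth table. Fully determined by `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param render if `FALSE`, skip image rendering (truth and geometry only).
#' @return list of class `phantom_cohort` with elements `cases` (list of
#'   `case_phantom`, each holding `case_id`, `label`, `age`,
#'   `true_contour`, `true_adc_mean`, `true_kinetics`, `roi_box`, and if
#'   rendered `images`), `truth` (data.frame: case_id, label, age, true_adc,
#'   true_slope, true_ser, area_px) and `config`.
#' @export
generate_cohort <- function(config, render = TRUE) {
  validate_phantom_config(config)
  n <- config$n_cases
  n_mal <- round(config$malignant_fraction * n)
  if (n_mal < 1 || n_mal > n - 1) stopf("degenerate class split")
  labels <- c(rep("malignant", n_mal), rep("benign", n - n_mal))
  with_seed(config$seed, {
    labels <- sample(labels)
    cases <- vector("list", n)
    for (i in seq_len(n)) {
      cases[[i]] <- simulate_case(sprintf("case_%03d", i), labels[i], config)
      if (render) cases[[i]]$images <- render_case(cases[[i]], config)
    }
  })
  truth <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id, label = cs$label, age = cs$age,
               true_adc = cs$true_adc_mean,
               true_slope = cs$true_slope, true_ser = cs$true_ser,
               area_px = cs$true_area_px, stringsAsFactors = FALSE)
  }))
  structure(list(cases = cases, truth = truth, config = config),
            class = "phantom_cohort")
}

# Draw one case's latent truth (shape, kinetics, ADC, age) from the class
# distributions; uses the current RNG stream.
simulate_case <- function(case_id, label, config) {
  cls <- config[[label]]
  n <- config$image_size
  center <- c(n / 2 - 0.5, n / 2 - 0.5)
  radius <- max(5, stats::rnorm(1, cls$shape$mean_radius_px, cls$shape$radius_sd_px))
  shp <- cls$shape
  kr <- range(shp$spike_count)
  shp$spike_count <- sample(seq(kr[1], kr[2]), 1)
  shp$spike_amplitude <- max(0, stats::rnorm(1, shp$spike_amplitude,
                                             shp$spike_amplitude_sd %||% 0))
  contour <- make_lesion_shape(label, shp, center = center, radius = radius)
  tex_sd <- max(0.02, stats::rnorm(1, cls$texture$sd, cls$texture$sd_sd %||% 0))
  tex_corr <- max(0.6, stats::rnorm(1, cls$texture$corr_len,
                                    cls$texture$corr_len_sd %||% 0))
  e <- stats::rnorm(1, cls$kinetics$enh_mean, cls$kinetics$enh_sd)
  # an enhancing mass by definition enhances well above the ~10% background
  # parenchyma; the floor keeps the lesion the brighter FCM cluster
  e <- max(e, 0.3)
  w <- stats::rnorm(1, cls$kinetics$washout_mean, cls$kinetics$washout_sd)
  # washout never drives the late signal to within 30% of baseline: keeps
  # the SER denominator bounded away from zero (SER stays in a clinical
  # range instead of exploding as a near-singular ratio)
  w <- min(w, (e - 0.3) / (1 + e))
  w <- max(w, -0.45)
  si_pre <- cls$kinetics$si_pre
  si_first <- si_pre * (1 + e)
  si_last <- si_first * (1 - w)
  denom <- si_last - si_pre
  true_ser <- if (abs(denom) < 1e-9) NA_real_ else (si_first - si_pre) / denom
  adc <- max(0.2, stats::rnorm(1, cls$adc$mean, cls$adc$sd))
  age <- round(rtruncnorm(1, cls$age$mean, cls$age$sd,
                          config$age_bounds[1], config$age_bounds[2]))
  m <- config$roi_margin_px
  rr <- range(contour[, 1]); cr <- range(contour[, 2])
  roi_box <- c(r0 = max(0, floor(rr[1]) - m), c0 = max(0, floor(cr[1]) - m),
               r1 = min(n - 1, ceiling(rr[2]) + m), c1 = min(n - 1, ceiling(cr[2]) + m))
  structure(list(
    case_id = case_id, label = label, age = age,
    true_contour = contour,
    true_spike_count = shp$spike_count,
    true_texture_sd = tex_sd,
    true_texture_corr_len = tex_corr,
    true_adc_mean = adc,
    true_kinetics = c(si_pre = si_pre, si_first = si_first, si_last = si_last),
    true_slope = e, true_ser = true_ser,
    true_area_px = sum(rasterize_polygon(contour, c(n, n))),
    roi_box = roi_box
  ), class = "case_phantom")
}

#' Write a rendered cohort to plain files
#'
#' Frames go out as NIfTI (one file per frame role per case), ground truth
#' as CSV, true contours as CSV vertex lists, and the configuration as YAML.
#'
#' @param cohort a rendered `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @param png_masks also write the true masks as 8-bit PNG.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, png_masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  for (cs in cohort$cases) {
    if (is.null(cs$images)) next
    cdir <- file.path(dir, cs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    sp <- cohort$config$pixel_spacing_mm
    wr <- function(img, name) {
      RNifti::writeNifti(RNifti::asNifti(img, reference = NULL),
                         file.path(cdir, paste0(name, ".nii.gz")))
    }
    wr(cs$images$series$pre, "dce_pre")
    wr(cs$images$series$first, "dce_first")
    wr(cs$images$series$last, "dce_last")
    wr(cs$images$dwi$b0, "dwi_b0")
    wr(cs$images$dwi$bhigh, sprintf("dwi_b%d", cohort$config$b_value_high))
    utils::write.csv(as.data.frame(cs$true_contour),
                     file.path(cdir, "true_contour.csv"), row.names = FALSE)
    if (png_masks) {
      png::writePNG(t(cs$images$mask * 1), file.path(cdir, "true_mask.png"))
    }
  }
  invisible(dir)
}
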