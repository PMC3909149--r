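#' Enhancement-kinetic features of a lesion
#'
#' Computed on lesion-mean signal intensities of the three-frame dynamic
#' series: slope (early-phase enhancement) = (SI_first - SI_pre) / SI_pre
#' and the signal enhancement ratio SER = (SI_first - SI_pre) /
#' (SI_last - SI_pre). SER > 1 indicates washout, SER < 1 persistent
#' enhancement.
#'
#' @param series list with frames `pre`, `first`, `last` (matrices).
#' @param mask binary lesion mask on the same grid.
#' @param epsilon SER is flagged missing when |SI_last - SI_pre| < epsilon
#'   times SI_pre (plateau at baseline: ratio undefined).
#' @return list with `slope` and `ser` (`ser` is `NA` with a warning when
#'   undefined).
#' @export
kinetic_features <- function(series, mask, epsilon = 1e-6) {
  mask <- as.logical(mask)
  if (!any(mask)) stopf("kinetic_features: empty mask")
  si_pre <- mean(series$pre[mask])
  si_first <- mean(series$first[mask])
  si_last <- mean(series$last[mask])
  if (si_pre <= 0) stopf("kinetic_features: mean pre-contrast intensity must be > 0")
  slope <- (si_first - si_pre) / si_pre
  denom <- si_last - si_pre
  if (abs(denom) < epsilon * si_pre) {
    if (abs(si_first - si_pre) < epsilon * si_pre) {
      ser <- 0  # no enhancement at all
    } else {
      warnf("kinetic_features: SER denominator near zero; SER flagged missing")
      ser <- NA_real_
    }
  } else {
    ser <- (si_first - si_pre) / denom
  }
  list(slope = slope, ser = ser)
}

#' Morphological descriptors of a segmented lesion
#'
#' The eleven shape/appearance features: area (mm^2), circularity
#' 4 pi A / P^2, compactness P^2 / (4 pi A), extent (area over bounding-box
#' area), solidity (area over convex-hull area), eccentricity and elongation
#' from the second-central-moment ellipse, entropy (base 2) of the 10-bin
#' histogram of max-normalised radial lengths, spiculation (zero crossings
#' of the centred radial profile per vertex), box-counting fractal dimension
#' of the rasterised boundary, and heterogeneity (intra-lesion sd/mean on
#' the first post-contrast frame).
#'
#' @param geometry a `lesion_geometry` (mask + closed contour).
#' @param pixel_spacing_mm pixel spacing, mm.
#' @param image first post-contrast frame for the heterogeneity feature;
#'   `NULL` gives `NA` heterogeneity.
#' @return named list of the 11 features.
#' @export
morphological_features <- function(geometry, pixel_spacing_mm = 1, image = NULL) {
  mask <- geometry$mask
  poly <- geometry$contour
  sp <- pixel_spacing_mm
  if (sp <= 0) stopf("pixel_spacing_mm must be > 0")
  npx <- sum(mask)
  if (npx == 0) stopf("morphological_features: empty mask")
  area <- npx * sp^2
  P <- polygon_perimeter(poly) * sp
  if (P <= 0) stopf("morphological_features: zero perimeter")
  circularity <- min(4 * pi * area / P^2, 1)
  compactness <- P^2 / (4 * pi * area)
  idx <- which(mask, arr.ind = TRUE)
  bb <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  extent <- npx / bb
  hull <- grDevices::chull(poly[, 2], poly[, 1])
  hull_area <- polygon_area(poly[hull, , drop = FALSE]) * sp^2
  solidity <- min(area / hull_area, 1)
  # second central moments of the pixel set
  mu_r <- mean(idx[, 1]); mu_c <- mean(idx[, 2])
  m20 <- mean((idx[, 1] - mu_r)^2) + 1 / 12  # + pixel self-moment
  m02 <- mean((idx[, 2] - mu_c)^2) + 1 / 12
  m11 <- mean((idx[, 1] - mu_r) * (idx[, 2] - mu_c))
  tr <- m20 + m02; det_ <- m20 * m02 - m11^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det_, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det_, 0))
  l2 <- max(l2, 1e-12)
  eccentricity <- sqrt(max(1 - l2 / l1, 0))
  elongation <- sqrt(l1 / l2)
  # radial profile from the mask centroid (0-based coords)
  centroid <- c(mu_r - 1, mu_c - 1)
  rad <- sqrt((poly[, 1] - centroid[1])^2 + (poly[, 2] - centroid[2])^2)
  centroid_inside <- {
    ri <- round(centroid[1]) + 1; ci <- round(centroid[2]) + 1
    ri >= 1 && ci >= 1 && ri <= nrow(mask) && ci <= ncol(mask) && mask[ri, ci]
  }
  if (!centroid_inside) {
    warnf("morphological_features: centroid outside mask; radial features flagged")
  }
  rn <- rad / max(rad)
  h <- tabulate(pmin(floor(rn * 10) + 1, 10), nbins = 10) / length(rn)
  h <- h[h > 0]
  radial_length_entropy <- -sum(h * log2(h))
  dev <- rad - mean(rad)
  s <- sign(dev); s[s == 0] <- 1
  crossings <- sum(s != s[c(2:length(s), 1)])
  spiculation <- crossings / nrow(poly)
  fractal_dimension <- box_counting_dimension(poly, nrow(mask), ncol(mask))
  heterogeneity <- if (is.null(image)) NA_real_ else {
    stats::sd(image[mask]) / mean(image[mask])
  }
  list(compactness = compactness, spiculation = spiculation, extent = extent,
       elongation = elongation, solidity = solidity, circularity = circularity,
       radial_length_entropy = radial_length_entropy,
       fractal_dimension = fractal_dimension, heterogeneity = heterogeneity,
       area = area, eccentricity = eccentricity)
}

# Box-counting dimension of the rasterised contour: slope of log2 N(s) vs
# log2(1/s) over dyadic box sizes {1,2,4,8,16}, clamped to [1,2].
box_counting_dimension <- function(poly, nr, nc) {
  # densify the polygon so every boundary pixel is hit
  dense <- resample_polygon(poly, max(4 * nrow(poly), 512))
  pr <- pmin(pmax(round(dense[, 1]), 0), nr - 1)
  pc <- pmin(pmax(round(dense[, 2]), 0), nc - 1)
  pix <- unique(cbind(pr, pc))
  sizes <- c(1, 2, 4, 8, 16)
  counts <- vapply(sizes, function(s) {
    nrow(unique(cbind(pix[, 1] %/% s, pix[, 2] %/% s)))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log2(1 / sizes)), log2(counts))
  max(1, min(2, fit$coefficients[2]))
}

#' GLCM specification
#'
#' @param n_levels gray levels after linear quantisation (>= 2).
#' @param offsets integer matrix of (dr, dc) displacements; default the four
#'   distance-1 directions.
#' @param symmetric accumulate each pair in both orders.
#' @return list of class `glcm_spec`.
#' @export
glcm_spec <- function(n_levels = 32,
                      offsets = rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                      symmetric = TRUE) {
  if (!is_count(n_levels) || n_levels < 2) stopf("glcm_spec: n_levels must be >= 2")
  structure(list(n_levels = n_levels, offsets = offsets, symmetric = symmetric),
            class = "glcm_spec")
}

#' Gray-level co-occurrence matrix within a mask
#'
#' Intensities inside the mask are linearly quantised to `n_levels` over
#' their observed range; pixel pairs are counted only when both ends fall
#' inside the mask, accumulated (symmetrically by default) over the offsets
#' and normalised to sum 1.
#'
#' @param image intensity matrix.
#' @param mask binary matrix; only intra-mask pairs are counted.
#' @param spec a [glcm_spec()].
#' @return `n_levels` x `n_levels` matrix summing to 1.
#' @export
build_glcm <- function(image, mask, spec = glcm_spec()) {
  mask <- as.logical(mask)
  dim(mask) <- dim(image)
  if (sum(mask) < 2) stopf("build_glcm: need >= 2 masked pixels")
  vals <- image[mask]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi > lo) {
    q[mask] <- pmin(floor((image[mask] - lo) / (hi - lo) * spec$n_levels) + 1L,
                    spec$n_levels)
  } else {
    q[mask] <- 1L
  }
  L <- spec$n_levels
  acc <- matrix(0, L, L)
  nr <- nrow(image); nc <- ncol(image)
  for (k in seq_len(nrow(spec$offsets))) {
    dr <- spec$offsets[k, 1]; dc <- spec$offsets[k, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 1:L), factor(b[ok], levels = 1:L))
    acc <- acc + tab
    if (spec$symmetric) acc <- acc + t(tab)
  }
  if (sum(acc) == 0) stopf("build_glcm: no valid pixel pairs inside the mask")
  out <- unclass(acc / sum(acc))
  dimnames(out) <- NULL
  out
}

#' The 13 Haralick texture statistics of a normalised GLCM
#'
#' Angular second moment, contrast, correlation, inverse difference moment,
#' sum average, sum variance, sum entropy, entropy, difference average,
#' difference variance, difference entropy, and the two information
#' measures of correlation, computed from p(i, j), its marginals and the
#' sum/difference distributions. Logs are base 2 with 0 log 0 := 0;
#' IMC1 = (HXY - HXY1) / max(HX, HY);
#' IMC2 = sqrt(1 - exp(-2 (HXY2 - HXY))). Sum/difference variances are
#' taken about the sum/difference averages.
#'
#' @param glcm square matrix, non-negative, summing to 1 (tolerance 1e-8).
#' @return named list of the 13 features (registry texture names).
#' @export
haralick_features <- function(glcm) {
  p <- as.matrix(glcm)
  if (nrow(p) != ncol(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stopf("haralick_features: glcm must be square, non-negative and sum to 1")
  }
  N <- nrow(p)
  i <- row(p); j <- col(p)
  log2z <- function(x) ifelse(x > 0, log2(x), 0)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:N) * px); mu_y <- sum((1:N) * py)
  sd_x <- sqrt(sum(((1:N) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:N) - mu_y)^2 * py))
  # p_{x+y}(k), k = 2..2N and p_{x-y}(k), k = 0..N-1
  psum <- vapply(2:(2 * N), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(N - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * N); kd <- 0:(N - 1)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  inverse_difference <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * log2z(psum))
  entropy <- -sum(p * log2z(p))
  difference_average <- sum(kd * pdif)
  difference_variance <- sum((kd - difference_average)^2 * pdif)
  difference_entropy <- -sum(pdif * log2z(pdif))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxy))
  hxy2 <- -sum(pxy * log2z(pxy))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  info_correlation_1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  info_correlation_2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  list(asm = asm, contrast = contrast, correlation = correlation,
       inverse_difference = inverse_difference, sum_average = sum_average,
       sum_variance = sum_variance, sum_entropy = sum_entropy,
       entropy = entropy, difference_average = difference_average,
       difference_variance = difference_variance,
       difference_entropy = difference_entropy,
       info_correlation_1 = info_correlation_1,
       info_correlation_2 = info_correlation_2)
}

#' ADC quantification from a diffusion-weighted pair
#'
#' Per-pixel ADC map ln(S_0 / S_b) / b (reported in 1e-3 mm^2/s). The
#' lesion's diffusion ROI is dichotomised against background: only mask
#' pixels whose high-b signal exceeds the mean high-b signal of a
#' surrounding annulus (mask dilated by `band_px`, minus the mask) count as
#' high-signal, and the mean ADC is taken over those. A result whose
#' high-signal area is below `min_area_mm2` is flagged invalid.
#'
#' @param dwi list with `b0`, `bhigh` matrices and `b_value` (s/mm^2).
#' @param mask binary lesion mask.
#' @param pixel_spacing_mm pixel spacing, mm.
#' @param band_px width of the background annulus, px.
#' @param min_area_mm2 minimum retained high-signal area, mm^2.
#' @return object of class `adc_result`: `adc_map` (NA where undefined),
#'   `mean_adc`, `roi_area_mm2`, `high_signal_mask`, `valid`,
#'   `n_excluded_pixels`.
#' @export
adc_features <- function(dwi, mask, pixel_spacing_mm = 1, band_px = 5,
                         min_area_mm2 = 20) {
  mask <- as.logical(mask); dim(mask) <- dim(dwi$b0)
  if (!any(mask)) stopf("adc_features: empty mask")
  s0 <- dwi$b0; sb <- dwi$bhigh
  if (any(s0[mask] <= 0)) stopf("adc_features: non-positive b=0 signal inside mask")
  b <- dwi$b_value
  ok <- s0 > 0 & sb > 0
  n_excluded <- sum(mask & !ok)
  adc_map <- matrix(NA_real_, nrow(s0), ncol(s0))
  adc_map[ok] <- log(s0[ok] / sb[ok]) / (b * 1e-3)
  brush <- EBImage::makeBrush(2 * band_px + 1, shape = "disc")
  dil <- EBImage::dilate(mask * 1, brush) > 0
  band <- dil & !mask
  bg_level <- if (any(band)) mean(sb[band]) else 0
  high <- mask & ok & (sb > bg_level)
  area <- sum(high) * pixel_spacing_mm^2
  valid <- area >= min_area_mm2
  if (!valid && sum(mask & ok) == 0) {
    stopf("adc_features: entire mask excluded; invalid diffusion ROI")
  }
  mean_adc <- if (any(high)) mean(adc_map[high]) else NA_real_
  structure(list(adc_map = adc_map, mean_adc = mean_adc,
                 roi_area_mm2 = area, high_signal_mask = high,
                 valid = valid, n_excluded_pixels = n_excluded),
            class = "adc_result")
}

#' Extract all 28 features for one case
#'
#' @param images rendered case images (`series`, `dwi`) as produced by
#'   [render_case()].
#' @param geometry a `lesion_geometry` (segmented or ground truth).
#' @param age patient age in years.
#' @param pixel_spacing_mm pixel spacing.
#' @param spec a [glcm_spec()].
#' @return named list: the 28 registry features plus `adc_valid`.
#' @export
extract_case_features <- function(images, geometry, age, pixel_spacing_mm = 1,
                                  spec = glcm_spec()) {
  kin <- kinetic_features(images$series, geometry$mask)
  morph <- morphological_features(geometry, pixel_spacing_mm,
                                  image = images$series$first)
  glcm <- build_glcm(images$series$first, geometry$mask, spec)
  tex <- haralick_features(glcm)
  adc <- adc_features(images$dwi, geometry$mask, pixel_spacing_mm)
  c(list(age = age), kin, morph, tex,
    list(adc = adc$mean_adc, adc_valid = adc$valid))
}

#' Assemble the cohort feature table
#'
#' Runs [extract_case_features()] for every case and binds the results into
#' a cases x 28 table (plus `case_id` and `label`). Rows with any invalid
#' or missing feature (e.g. a diffusion ROI below the minimum area, or an
#' undefined SER) are excluded; exclusions are reported via a message and
#' the `excluded` attribute.
#'
#' @param cohort a `phantom_cohort` with rendered images.
#' @param geometries optional list of `lesion_geometry` per case (same
#'   order); defaults to ground-truth geometry from each case's planted
#'   contour.
#' @param spec a [glcm_spec()].
#' @return data.frame with columns `case_id`, `label`, then the 28 registry
#'   features; attributes `groups` (named group tag per feature column) and
#'   `excluded` (data.frame of dropped cases and reasons).
#' @export
assemble_features <- function(cohort, geometries = NULL, spec = glcm_spec()) {
  cases <- cohort$cases
  ids <- vapply(cases, `[[`, character(1), "case_id")
  if (anyDuplicated(ids)) stopf("assemble_features: duplicate case_id")
  sp <- cohort$config$pixel_spacing_mm
  n_img <- cohort$config$image_size
  reg <- feature_registry()
  rows <- vector("list", length(cases))
  excl <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (is.null(cs$images)) stopf("assemble_features: case %s has no rendered images", cs$case_id)
    geo <- if (is.null(geometries)) {
      geometry_from_contour(cs$true_contour, c(n_img, n_img))
    } else geometries[[i]]
    feats <- tryCatch(
      suppressWarnings(extract_case_features(cs$images, geo, cs$age, sp, spec)),
      error = function(e) conditionMessage(e))
    if (is.character(feats)) {
      excl[[length(excl) + 1]] <- data.frame(case_id = cs$case_id, reason = feats)
      next
    }
    if (!isTRUE(feats$adc_valid)) {
      excl[[length(excl) + 1]] <- data.frame(
        case_id = cs$case_id, reason = "diffusion ROI below minimum area")
      next
    }
    vals <- unlist(feats[reg$name])
    if (anyNA(vals)) {
      excl[[length(excl) + 1]] <- data.frame(
        case_id = cs$case_id,
        reason = paste("missing feature:",
                       paste(reg$name[is.na(vals)], collapse = ", ")))
      next
    }
    rows[[i]] <- data.frame(case_id = cs$case_id, label = cs$label,
                            t(vals), stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stopf("assemble_features: every case was excluded")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(case_id = character(0), reason = character(0))
  if (nrow(excluded)) {
    message(sprintf("assemble_features: excluded %d case(s): %s",
                    nrow(excluded),
                    paste(excluded$case_id, collapse = ", ")))
  }
  attr(out, "groups") <- stats::setNames(reg$group, reg$name)
  attr(out, "excluded") <- excluded
  out
}

#' Feature-table column groups
#'
#' @param features a table from [assemble_features()] (or any table whose
#'   feature columns use registry names).
#' @return named character vector mapping feature column -> group.
#' @export
feature_groups <- function(features) {
  g <- attr(features, "groups")
  if (!is.null(g)) return(g)
  reg <- feature_registry()
  stats::setNames(reg$group, reg$name)[intersect(reg$name, names(features))]
}
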