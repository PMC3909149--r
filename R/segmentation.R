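#' Fuzzy c-means clustering of ROI intensities
#'
#' Soft clustering of 1-D pixel intensities by the standard fuzzy c-means
#' alternating updates: centers c_k = sum_i u_ik^m x_i / sum_i u_ik^m and
#' memberships u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1)). Centers are
#' initialised at evenly spaced intensity percentiles (10th and 90th for
#' c = 2), making the run deterministic for given data.
#'
#' @param intensities numeric vector of pixel values (ROI pixels).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier, > 1.
#' @param tol stop when the largest center shift falls below `tol`.
#' @param max_iter iteration cap.
#' @return object of class `fcm_result`: `centers` (sorted ascending),
#'   `memberships` (n x c, rows sum to 1, columns follow `centers` order),
#'   `objective_history` (J per iteration, non-increasing), `m`,
#'   `iterations`, `converged`.
#' @export
fcm_cluster <- function(intensities, c = 2, m = 2, tol = 1e-6, max_iter = 200) {
  x <- as.numeric(intensities)
  if (c < 2) stopf("fcm_cluster: c must be >= 2")
  if (!is_number(m) || m <= 1) stopf("fcm_cluster: fuzzifier m must be > 1")
  if (length(unique(x)) < c) {
    stopf("fcm_cluster: need at least c distinct intensity values (no contrast to cluster)")
  }
  probs <- seq(0.1, 0.9, length.out = c)
  centers <- as.numeric(stats::quantile(x, probs, names = FALSE))
  if (any(duplicated(centers))) centers <- seq(min(x), max(x), length.out = c)
  n <- length(x)
  expo <- 2 / (m - 1)
  history <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    zero <- d < 1e-12
    u <- matrix(0, n, c)
    anyz <- rowSums(zero) > 0
    if (any(anyz)) u[anyz, ] <- zero[anyz, , drop = FALSE] / rowSums(zero[anyz, , drop = FALSE])
    if (any(!anyz)) {
      dn <- d[!anyz, , drop = FALSE]
      inv <- dn^(-expo)
      u[!anyz, ] <- inv / rowSums(inv)
    }
    um <- u^m
    history <- c(history, sum(um * d^2))
    new_centers <- colSums(um * x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  ord <- order(centers)
  structure(list(centers = centers[ord],
                 memberships = u[, ord, drop = FALSE],
                 objective_history = history, m = m, iterations = it,
                 converged = shift < tol),
            class = "fcm_result")
}

#' Initial lesion mask from an FCM clustering
#'
#' Step one of the two-step segmentation: pixels are assigned to the cluster
#' with the highest mean enhancement (the top intensity center), hard
#' thresholded at membership > 0.5; the largest connected component is kept
#' and interior holes are filled.
#'
#' @param fcm an `fcm_result` for the ROI pixels, in ROI raster order.
#' @param roi_dim (rows, cols) of the ROI raster the intensities came from.
#' @return binary matrix of `roi_dim`.
#' @export
initial_mask <- function(fcm, roi_dim) {
  k <- which.max(fcm$centers)
  memb <- matrix(fcm$memberships[, k], roi_dim[1], roi_dim[2])
  mask <- memb > 0.5
  if (!any(mask)) stopf("segmentation failure: lesion cluster mask is empty")
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  mask <- EBImage::fillHull(mask * 1) > 0
  mask
}

#' Gradient vector flow field of an edge map
#'
#' Iterative diffusion solution of the GVF equations: the field v minimises
#' int mu |grad v|^2 + |grad f|^2 |v - grad f|^2. The edge map is first
#' rescaled to [0, 1] (the customary normalisation, which fixes the balance
#' between the two energy terms independently of image contrast), then the
#' Euler-Lagrange equations are solved by explicit time stepping
#' v <- v + dt (mu lap(v) - |grad f|^2 (v - grad f)) with dt chosen inside
#' the stability bound dt < 1 / (4 mu + max |grad f|^2).
#'
#' @param edge_map non-negative raster f (high where edges are).
#' @param mu regularisation weight, > 0.
#' @param iters diffusion iterations, >= 1.
#' @return list `vr`, `vc`: per-pixel field components (row/col
#'   directions), for the normalised edge map.
#' @export
gvf_field <- function(edge_map, mu = 0.2, iters = 80) {
  if (any(!is.finite(edge_map)) || any(edge_map < 0)) {
    stopf("gvf_field: edge map must be finite and non-negative")
  }
  if (mu <= 0) stopf("gvf_field: mu must be > 0")
  if (iters < 1) stopf("gvf_field: iters must be >= 1")
  mx <- max(edge_map)
  f <- if (mx > 0) edge_map / mx else edge_map
  g <- image_gradient(f)
  fr <- g$dr; fc <- g$dc
  b <- fr^2 + fc^2
  if (max(b) == 0) {
    warnf("gvf_field: edge map has zero gradient; snake will not move")
    return(list(vr = fr, vc = fc))
  }
  dt <- 0.9 / (4 * mu + max(b))
  vr <- fr; vc <- fc
  for (i in seq_len(iters)) {
    vr <- vr + dt * (mu * laplacian(vr) - b * (vr - fr))
    vc <- vc + dt * (mu * laplacian(vc) - b * (vc - fc))
  }
  list(vr = vr, vc = vc)
}

#' Snake evolution parameters
#'
#' @param alpha tension (first-derivative) weight.
#' @param beta rigidity (second-derivative) weight.
#' @param gamma time step.
#' @param mu GVF regularisation weight.
#' @param gvf_iters GVF diffusion iterations.
#' @param snake_iters snake iteration cap.
#' @param convergence_tol mean vertex displacement (px) below which the
#'   snake is declared converged.
#' @param n_vertices number of snake vertices after each arc-length
#'   resampling.
#' @param sigma Gaussian smoothing (px) used to build the edge map.
#' @param relocate_px half-width (px) of the final sub-pixel edge
#'   relocation search along each vertex normal (0 disables it).
#' @param relocate_sigma Gaussian smoothing (px) of the gradient used for
#'   that relocation (smaller than `sigma`: localisation, not capture).
#' @return list of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.05, beta = 0.02, gamma = 1, mu = 0.05,
                         gvf_iters = 40, snake_iters = 150,
                         convergence_tol = 0.05, n_vertices = 160,
                         sigma = 1.0, relocate_px = 2.5,
                         relocate_sigma = 0.75) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
            gvf_iters = gvf_iters, snake_iters = snake_iters,
            convergence_tol = convergence_tol, n_vertices = n_vertices,
            sigma = sigma, relocate_px = relocate_px,
            relocate_sigma = relocate_sigma)
  if (any(!vapply(p, is_number, logical(1)))) stopf("snake_params: all fields must be finite numbers")
  if (alpha < 0 || beta < 0) stopf("snake_params: alpha and beta must be >= 0")
  if (gamma <= 0) stopf("snake_params: gamma must be > 0")
  if (gvf_iters < 1 || snake_iters < 1) stopf("snake_params: iteration counts must be >= 1")
  structure(p, class = "snake_params")
}

#' Evolve an active contour under a GVF external force
#'
#' Semi-implicit evolution: internal tension/rigidity handled by solving
#' (I + gamma K) v_new = v + gamma F_ext(v) with the cyclic pentadiagonal
#' stiffness K built from `alpha`/`beta`; the external force is the GVF
#' field, normalised to unit maximum magnitude, sampled bilinearly at the
#' vertices. Vertices are resampled to uniform arc length every iteration.
#'
#' @param init_contour polygon (>= 16 vertices) in 0-based (row, col).
#' @param field list `vr`, `vc` from [gvf_field()] (on the same raster as
#'   the contour's coordinate frame).
#' @param params a [snake_params()].
#' @param normalize_force normalise the field to unit max magnitude.
#' @return polygon matrix (n_vertices x 2), simple and closed, with
#'   attributes `iterations` and `converged`.
#' @export
evolve_snake <- function(init_contour, field, params = snake_params(),
                         normalize_force = TRUE) {
  if (nrow(init_contour) < 16) stopf("evolve_snake: need >= 16 initial vertices")
  if (!polygon_is_simple(init_contour)) stopf("evolve_snake: initial contour self-intersects")
  n <- params$n_vertices
  v <- resample_polygon(init_contour, n)
  vr <- field$vr; vc <- field$vc
  if (normalize_force) {
    mx <- max(sqrt(vr^2 + vc^2))
    if (mx > 0) { vr <- vr / mx; vc <- vc / mx }
  }
  # cyclic pentadiagonal stiffness: K = -alpha D2 + beta D4
  a <- params$alpha; b <- params$beta
  idx <- function(s) ((seq_len(n) - 1 + s) %% n) + 1
  K <- matrix(0, n, n)
  diag(K) <- 2 * a + 6 * b
  K[cbind(seq_len(n), idx(1))] <- K[cbind(seq_len(n), idx(-1))] <- -a - 4 * b
  K[cbind(seq_len(n), idx(2))] <- K[cbind(seq_len(n), idx(-2))] <- b
  Minv <- solve(diag(n) + params$gamma * K)
  converged <- FALSE
  for (it in seq_len(params$snake_iters)) {
    fr <- bilinear(vr, v[, 1], v[, 2])
    fc <- bilinear(vc, v[, 1], v[, 2])
    v_new <- Minv %*% (v + params$gamma * cbind(fr, fc))
    disp <- mean(sqrt(rowSums((v_new - v)^2)))
    v <- resample_polygon(v_new, n)
    if (disp < params$convergence_tol) { converged <- TRUE; break }
  }
  colnames(v) <- c("r", "c")
  if (!polygon_is_simple(v)) {
    # light radial smoothing from the centroid usually repairs pixel-scale loops
    ctr <- colMeans(v)
    rel <- sweep(v, 2, ctr)
    rad <- sqrt(rowSums(rel^2)); ang <- atan2(rel[, 1], rel[, 2])
    for (pass in 1:5) {
      rad <- (rad + rad[c(2:n, 1)] + rad[c(n, 1:(n - 1))]) / 3
      v <- cbind(r = ctr[1] + rad * sin(ang), c = ctr[2] + rad * cos(ang))
      if (polygon_is_simple(v)) break
    }
    if (!polygon_is_simple(v)) {
      # last resort: project onto the nearest star-shaped polygon (radius as
      # a single-valued function of angle about the centroid) — always
      # simple, and faithful for the star-shaped masses this snake targets
      v <- star_project(v, n)
      warnf("evolve_snake: self-intersection at iteration %d repaired by star projection", it)
    }
  }
  structure(v, iterations = it, converged = converged)
}

# Project a (possibly tangled) closed polygon onto a star-shaped one: bin
# vertices by angle about the centroid, average radii per bin, interpolate
# to `n_out` uniform angles. Single-valued r(theta) implies simplicity.
star_project <- function(v, n_out) {
  ctr <- colMeans(v)
  rel <- sweep(v, 2, ctr)
  ang <- atan2(rel[, 1], rel[, 2])
  rad <- sqrt(rowSums(rel^2))
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  # wrap for periodic interpolation
  ang_w <- c(ang - 2 * pi, ang, ang + 2 * pi)
  rad_w <- rep(rad, 3)
  theta <- seq(-pi, pi, length.out = n_out + 1)[-(n_out + 1)]
  r_new <- stats::approx(ang_w, rad_w, xout = theta, ties = mean, rule = 2)$y
  # light smoothing to remove bin noise
  r_new <- (r_new + r_new[c(2:n_out, 1)] + r_new[c(n_out, 1:(n_out - 1))]) / 3
  cbind(r = ctr[1] + r_new * sin(theta), c = ctr[2] + r_new * cos(theta))
}

# Sub-pixel edge relocation: move each vertex along its local normal to the
# maximum of the edge-strength profile within +/- tmax px. Removes the
# curvature-dependent localisation bias the smoothed edge map induces at
# spiculation tips and valleys. Vertices on a flat profile stay put.
relocate_to_edge <- function(v, edge_map, tmax = 2.5, step = 0.25) {
  n <- nrow(v)
  tg <- v[c(2:n, 1), , drop = FALSE] - v[c(n, 1:(n - 1)), , drop = FALSE]
  nrm <- cbind(tg[, 2], -tg[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  ts <- seq(-tmax, tmax, by = step)
  prof <- vapply(ts, function(t) {
    bilinear(edge_map, v[, 1] + t * nrm[, 1], v[, 2] + t * nrm[, 2])
  }, numeric(n))
  flat <- apply(prof, 1, function(p) max(p) - min(p) < 1e-12)
  best <- ts[apply(prof, 1, which.max)]
  best[flat] <- 0
  v + best * nrm
}

# Ordered outer boundary of a binary mask as a 0-based (row, col) polygon,
# via EBImage's oriented contour tracer.
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  # ocontour works in EBImage's (x, y) = (dim1, dim2) 0-based index space,
  # which for a plain matrix is (row, col) already
  cbind(r = oc[, 1], c = oc[, 2])
}

#' Two-step semi-automated lesion segmentation
#'
#' Composition of the full scheme on the first post-contrast frame: FCM
#' clustering of the ROI intensities (c = 2) -> hard initial mask (largest
#' component, holes filled) -> contour extraction -> GVF snake refinement on
#' the edge map |grad(Gaussian-smoothed frame)|^2 -> rasterisation back to
#' the full image grid.
#'
#' @param series dynamic series: list with at least `first` (first
#'   post-contrast frame matrix).
#' @param roi_box named vector (r0, c0, r1, c1), 0-based inclusive pixel
#'   bounds of the rectangular ROI around the lesion.
#' @param params a [snake_params()].
#' @param fcm_c,fcm_m FCM cluster count and fuzzifier.
#' @return object of class `lesion_geometry`: `mask` (full-grid binary
#'   matrix, one connected component, holes filled), `contour` (closed
#'   simple polygon, 0-based full-grid (row, col)), plus the per-stage
#'   diagnostics `fcm` and `snake_iterations`.
#' @export
segment_lesion <- function(series, roi_box, params = snake_params(),
                           fcm_c = 2, fcm_m = 2) {
  img <- series$first
  nr <- nrow(img); nc <- ncol(img)
  rb <- round(roi_box)
  if (is.null(names(rb))) names(rb) <- c("r0", "c0", "r1", "c1")
  if (rb["r0"] < 0 || rb["c0"] < 0 || rb["r1"] > nr - 1 || rb["c1"] > nc - 1 ||
      rb["r0"] >= rb["r1"] || rb["c0"] >= rb["c1"]) {
    stopf("segment_lesion: roi_box must be a non-empty rectangle inside the image")
  }
  rows <- (rb["r0"]:rb["r1"]) + 1
  cols <- (rb["c0"]:rb["c1"]) + 1
  roi <- img[rows, cols]
  fcm <- tryCatch(fcm_cluster(as.vector(roi), c = fcm_c, m = fcm_m),
                  error = function(e) stopf("segment_lesion [fcm]: %s", conditionMessage(e)))
  mask0 <- tryCatch(initial_mask(fcm, dim(roi)),
                    error = function(e) stopf("segment_lesion [initial_mask]: %s", conditionMessage(e)))
  if (sum(mask0) < 9) stopf("segment_lesion [initial_mask]: ROI contains no lesion-scale component")
  # plausibility: an enhancing mass is substantially brighter than the
  # tissue band around it; clustering pure background noise is not
  sm <- gaussian_blur(roi, 1)
  band <- (EBImage::dilate(mask0 * 1, EBImage::makeBrush(11, "disc")) > 0) & !mask0
  if (!any(band) || sum(mask0) > 0.9 * length(roi) ||
      mean(sm[mask0]) < 1.08 * mean(sm[band])) {
    stopf("segment_lesion [initial_mask]: ROI contains no enhancing lesion")
  }
  contour0 <- mask_contour(mask0)
  if (nrow(contour0) < 16) stopf("segment_lesion [contour]: initial contour too small")
  edge <- image_gradient(gaussian_blur(roi, params$sigma))
  edge_map <- edge$dr^2 + edge$dc^2
  field <- gvf_field(edge_map, mu = params$mu, iters = params$gvf_iters)
  snake <- tryCatch(evolve_snake(contour0, field, params),
                    error = function(e) stopf("segment_lesion [snake]: %s", conditionMessage(e)))
  snake <- unclass(snake)
  if (params$relocate_px > 0) {
    # final sub-pixel localisation on a sharper gradient than the capture
    # edge map (the initial contour runs through boundary-pixel centers,
    # half a pixel inside the physical edge; this also corrects that)
    eg <- image_gradient(gaussian_blur(roi, params$relocate_sigma))
    snake <- relocate_to_edge(snake, eg$dr^2 + eg$dc^2, tmax = params$relocate_px)
  } else {
    snake <- offset_polygon(snake, 0.5)
  }
  contour <- cbind(r = snake[, 1] + rb["r0"], c = snake[, 2] + rb["c0"])
  mask <- rasterize_polygon(contour, c(nr, nc))
  if (!any(mask)) stopf("segment_lesion [rasterize]: empty final mask")
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  mask <- EBImage::fillHull(mask * 1) > 0
  structure(list(mask = mask, contour = contour, fcm = fcm,
                 snake_iterations = attr(snake, "iterations")),
            class = "lesion_geometry")
}

#' Lesion geometry from a ground-truth contour
#'
#' Wraps a known boundary polygon (e.g. a phantom's planted contour) in the
#' same container [segment_lesion()] returns, so feature extraction can run
#' on either segmented or true geometry.
#'
#' @param contour closed simple polygon, 0-based (row, col).
#' @param dim image dimensions (rows, cols).
#' @return a `lesion_geometry`.
#' @export
geometry_from_contour <- function(contour, dim) {
  mask <- rasterize_polygon(contour, dim)
  if (!any(mask)) stopf("geometry_from_contour: contour rasterises to an empty mask")
  structure(list(mask = mask, contour = contour, fcm = NULL,
                 snake_iterations = 0L),
            class = "lesion_geometry")
}
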