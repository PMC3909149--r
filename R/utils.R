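# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All exported stochastic operations funnel
# their seed through this so a cohort/selection/evaluation run never perturbs
# the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed, kept inside the
# 32-bit signed integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 0

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Truncated-normal sampler by rejection; bounds are wide relative to sd in
# every configuration used here so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Stationary Gaussian random field on an nr x nc grid, zero mean, unit
# marginal sd, with spatial correlation length `corr_len` pixels (Gaussian
# kernel smoothing of white noise, re-standardised).
gaussian_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 0) {
    z <- gaussian_blur(z, sigma = corr_len)
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

# Separable Gaussian blur with replicate padding (own kernel convolution so
# image orientation conventions stay explicit).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(m) {
    nr <- nrow(m)
    idx <- outer(seq_len(nr), -half:half, "+")
    idx[idx < 1] <- 1L
    idx[idx > nr] <- nr
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

# Central-difference gradient with replicate boundaries; returns d/drow and
# d/dcol components.
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- img[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

# 5-point Laplacian with replicate boundaries.
laplacian <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- img[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  up + dn + lf + rt - 4 * img
}

# Bilinear interpolation of matrix `img` at continuous 0-based (row, col)
# positions; positions are clamped to the valid grid.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i0 <- r0 + 1; j0 <- c0 + 1
  img[cbind(i0, j0)] * (1 - fr) * (1 - fc) +
    img[cbind(i0 + 1, j0)] * fr * (1 - fc) +
    img[cbind(i0, j0 + 1)] * (1 - fr) * fc +
    img[cbind(i0 + 1, j0 + 1)] * fr * fc
}

# Shoelace area of a closed polygon given as (row, col) vertices.
polygon_area <- function(poly) {
  r <- poly[, 1]; c <- poly[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  abs(sum(c * r2 - c2 * r)) / 2
}

polygon_perimeter <- function(poly) {
  d <- poly - poly[c(seq_len(nrow(poly))[-1], 1), ]
  sum(sqrt(rowSums(d^2)))
}

#' Rasterise a closed polygon to a binary mask
#'
#' Pixels whose 0-based centers fall inside the polygon are set (crossing
#' number test, vectorised over pixels edge by edge).
#'
#' @param poly closed polygon, (row, col) vertices, 0-based pixel-center
#'   coordinates.
#' @param dim target raster dimensions (rows, cols).
#' @return logical matrix.
#' @export
rasterize_polygon <- function(poly, dim) {
  nr <- dim[1]; nc <- dim[2]
  rr <- range(poly[, 1]); cr <- range(poly[, 2])
  i0 <- max(1L, floor(rr[1]) + 1L); i1 <- min(nr, ceiling(rr[2]) + 1L)
  j0 <- max(1L, floor(cr[1]) + 1L); j1 <- min(nc, ceiling(cr[2]) + 1L)
  mask <- matrix(FALSE, nr, nc)
  if (i0 > i1 || j0 > j1) return(mask)
  py <- rep(seq(i0, i1) - 1, times = j1 - j0 + 1)
  px <- rep(seq(j0, j1) - 1, each = i1 - i0 + 1)
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  y1 <- poly[, 1]; x1 <- poly[, 2]
  y2 <- poly[c(2:n, 1), 1]; x2 <- poly[c(2:n, 1), 2]
  for (e in seq_len(n)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      xint <- (x2[e] - x1[e]) * (py[crosses] - y1[e]) / (y2[e] - y1[e]) + x1[e]
      hit <- px[crosses] < xint
      inside[crosses][hit] <- !inside[crosses][hit]
    }
  }
  mask[cbind(py + 1, px + 1)] <- inside
  mask
}

# Does the closed polygon self-intersect? Proper-intersection test on all
# non-adjacent edge pairs, vectorised over the second edge.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  p1r <- poly[, 1]; p1c <- poly[, 2]
  nxt <- c(2:n, 1)
  p2r <- p1r[nxt]; p2c <- p1c[nxt]
  cross <- function(ar, ac, br, bc, cr, cc) (br - ar) * (cc - ac) - (bc - ac) * (cr - ar)
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, if (i == 1) n - 1 else n)
    d1 <- cross(p1r[j], p1c[j], p2r[j], p2c[j], p1r[i], p1c[i])
    d2 <- cross(p1r[j], p1c[j], p2r[j], p2c[j], p2r[i], p2c[i])
    d3 <- cross(p1r[i], p1c[i], p2r[i], p2c[i], p1r[j], p1c[j])
    d4 <- cross(p1r[i], p1c[i], p2r[i], p2c[i], p2r[j], p2c[j])
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))) return(FALSE)
  }
  TRUE
}

# Resample a closed polygon to `n_out` vertices uniformly spaced in arc
# length (linear interpolation along the closed boundary).
resample_polygon <- function(poly, n_out) {
  n <- nrow(poly)
  closed <- rbind(poly, poly[1, ])
  d <- sqrt(rowSums((closed[-1, , drop = FALSE] - closed[-(n + 1), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  total <- s[n + 1]
  if (total <= 0) stopf("degenerate polygon: zero perimeter")
  target <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  r <- stats::approx(s, closed[, 1], xout = target, rule = 2)$y
  c_ <- stats::approx(s, closed[, 2], xout = target, rule = 2)$y
  cbind(r = r, c = c_)
}

# Offset a closed polygon by `d` pixels along the outward normal (outward
# determined against the centroid; adequate for star-shaped lesion
# boundaries). Used to undo the half-pixel erosion of tracing a contour
# through boundary-pixel centers before re-rasterising.
offset_polygon <- function(poly, d = 0.5) {
  n <- nrow(poly)
  tg <- poly[c(2:n, 1), , drop = FALSE] - poly[c(n, 1:(n - 1)), , drop = FALSE]
  nrm <- cbind(tg[, 2], -tg[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  rel <- sweep(poly, 2, colMeans(poly))
  sgn <- sign(rowSums(nrm * rel)); sgn[sgn == 0] <- 1
  poly + d * nrm * sgn
}

#' Dice overlap coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|); `NA` when both masks are empty.
#'
#' @param a,b binary masks of equal dimensions.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a
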