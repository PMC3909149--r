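# Independent brute-force oracles, written against the definitions rather
# than the package implementation, for dual-route checks.

# All 13 Haralick statistics by naive nested loops over the GLCM.
oracle_haralick <- function(p) {
  N <- nrow(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:N) * px); mu_y <- sum((1:N) * py)
  sd_x <- sqrt(sum(((1:N) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:N) - mu_y)^2 * py))
  asm <- 0; contrast <- 0; corr_num <- 0; idm <- 0; ent <- 0
  hxy1 <- 0
  psum <- rep(0, 2 * N - 1)   # k = 2..2N
  pdif <- rep(0, N)           # k = 0..N-1
  for (i in 1:N) for (j in 1:N) {
    v <- p[i, j]
    asm <- asm + v^2
    contrast <- contrast + (i - j)^2 * v
    corr_num <- corr_num + i * j * v
    idm <- idm + v / (1 + (i - j)^2)
    ent <- ent - v * lg(v)
    hxy1 <- hxy1 - v * lg(px[i] * py[j])
    psum[i + j - 1] <- psum[i + j - 1] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
  }
  ks <- 2:(2 * N); kd <- 0:(N - 1)
  sa <- sum(ks * psum)
  sv <- sum((ks - sa)^2 * psum)
  se <- -sum(vapply(psum, function(v) v * lg(v), numeric(1)))
  da <- sum(kd * pdif)
  dv <- sum((kd - da)^2 * pdif)
  de <- -sum(vapply(pdif, function(v) v * lg(v), numeric(1)))
  hx <- -sum(vapply(px, function(v) v * lg(v), numeric(1)))
  hy <- -sum(vapply(py, function(v) v * lg(v), numeric(1)))
  hxy2 <- 0
  for (i in 1:N) for (j in 1:N) {
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  list(asm = asm, contrast = contrast,
       correlation = if (sd_x > 0 && sd_y > 0) (corr_num - mu_x * mu_y) / (sd_x * sd_y) else 0,
       inverse_difference = idm, sum_average = sa, sum_variance = sv,
       sum_entropy = se, entropy = ent, difference_average = da,
       difference_variance = dv, difference_entropy = de,
       info_correlation_1 = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
       info_correlation_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))))
}

# AUC by O(n^2) all-pairs counting, ties half.
oracle_auc <- function(scores, truth, positive = "malignant") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Welch two-sample t statistic and p-value in closed form.
oracle_welch <- function(x, g) {
  x1 <- x[g == unique(g)[1]]; x2 <- x[g == unique(g)[2]]
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1); v2 <- var(x2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Reference 1-D fuzzy c-means iteration (straight transcription of the
# update equations, no vectorisation tricks), run to convergence.
oracle_fcm <- function(x, centers, m = 2, iters = 500) {
  c_ <- length(centers)
  for (it in seq_len(iters)) {
    u <- matrix(0, length(x), c_)
    for (i in seq_along(x)) {
      d <- abs(x[i] - centers)
      if (any(d < 1e-12)) {
        u[i, which.min(d)] <- 1
      } else {
        for (k in 1:c_) u[i, k] <- 1 / sum((d[k] / d)^(2 / (m - 1)))
      }
    }
    for (k in 1:c_) centers[k] <- sum(u[, k]^m * x) / sum(u[, k]^m)
  }
  sort(centers)
}
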