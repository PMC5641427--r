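# Independent oracles used across the suite. These stay deliberately naive
# (direct integration, exhaustive scans, permutation) so that they share no
# code path with the implementations they check.

# Dense per-segment trapezoid quadrature of the Fourier line integrals over
# the piecewise-linear contour; independent of the closed-form estimator.
efd_quadrature_oracle <- function(xy, n_harmonics, samples_per_unit = 400) {
  x <- c(xy[, 1L], xy[1L, 1L]); y <- c(xy[, 2L], xy[1L, 2L])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- seg > 0
  tcum <- c(0, cumsum(seg))
  Tper <- tcum[length(tcum)]
  # sample densely inside every segment (integrand is smooth there)
  ss <- unlist(lapply(which(keep), function(i) {
    m <- max(4L, ceiling(samples_per_unit * seg[i] / Tper * length(seg)))
    seq(tcum[i], tcum[i + 1L], length.out = m)
  }))
  ss <- sort(unique(ss))
  xs <- approx(tcum, x, xout = ss)$y
  ys <- approx(tcum, y, xout = ss)$y
  trap <- function(f) sum(diff(ss) * (f[-1L] + f[-length(f)]) / 2)
  out <- matrix(0, n_harmonics, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / Tper
    out[n, "a"] <- 2 / Tper * trap(xs * cos(w * ss))
    out[n, "b"] <- 2 / Tper * trap(xs * sin(w * ss))
    out[n, "c"] <- 2 / Tper * trap(ys * cos(w * ss))
    out[n, "d"] <- 2 / Tper * trap(ys * sin(w * ss))
  }
  out
}

# Random smooth star-shaped polygon (always simple), optionally transformed.
random_star_polygon <- function(n_vertices = 200, n_modes = 5, max_amp = 0.12) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(1, n_vertices)
  for (k in 2:(n_modes + 1L)) {
    r <- r + runif(1, 0, max_amp) * cos(k * th + runif(1, 0, 2 * pi))
  }
  cbind(x = r * cos(th), y = 0.7 * r * sin(th))
}

# Exhaustive between-class-variance scan over all 256 grey levels.
brute_otsu <- function(img) {
  best_k <- NA_integer_; best_v <- -1
  for (k in 1:255) {
    fg <- img >= k
    w1 <- mean(fg)
    if (w1 == 0 || w1 == 1) next
    v <- (1 - w1) * w1 * (mean(img[!fg]) - mean(img[fg]))^2
    if (v > best_v + 1e-12) { best_v <- v; best_k <- k }
  }
  best_k
}

# O(V^2) polygon diameter scan over all vertex pairs.
brute_diameter <- function(xy) {
  n <- nrow(xy)
  best <- 0
  for (i in 1:(n - 1L)) {
    d2 <- (xy[(i + 1L):n, 1L] - xy[i, 1L])^2 + (xy[(i + 1L):n, 2L] - xy[i, 2L])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Pairwise standardized rank-sum z statistic (shared by the permutation
# oracle only; the package computes its own inside steel_dwass).
.rank_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) 0 else (R1 - E) / sqrt(V)
}

# Monte-Carlo familywise permutation p-values for all pairs: the null
# distribution of the maximum |z| over pairs under full exchangeability.
permutation_steel_dwass <- function(groups, n_perm = 1e5) {
  k <- length(groups)
  pool <- unlist(groups)
  idx <- rep(seq_len(k), vapply(groups, length, 1L))
  pairs <- utils::combn(k, 2L)
  obs <- vapply(seq_len(ncol(pairs)), function(j) {
    abs(.rank_z(groups[[pairs[1L, j]]], groups[[pairs[2L, j]]]))
  }, numeric(1L))
  maxz <- replicate(n_perm, {
    p <- sample(idx)
    gg <- split(pool, p)
    max(vapply(seq_len(ncol(pairs)), function(j) {
      abs(.rank_z(gg[[pairs[1L, j]]], gg[[pairs[2L, j]]]))
    }, numeric(1L)))
  })
  vapply(obs, function(o) mean(maxz >= o - 1e-9), numeric(1L))
}

# Random closed Freeman chain: a random walk whose displacement is closed by
# retracing the walk with inverted directions (guaranteed closure).
random_closed_chain <- function(id, len = 20) {
  fwd <- sample(0:7, len, replace = TRUE)
  back <- rev((fwd + 4L) %% 8L)
  chain_code(id, start = c(sample(-5:5, 1), sample(-5:5, 1)),
             codes = c(fwd, back))
}

measured_d1 <- function(xy, n_harmonics = 20L) {
  unname(efd_normalize(efd_estimate(ensure_ccw(xy), n_harmonics))$coef[1L, "d"])
}
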