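# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's convolutional / vectorized code paths: plain scalar
# loops and sorts, so they can arbitrate the fast implementations.

rand_image <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(runif(h * w), h, w))
}

# symmetric-reflection index, written independently of the package helper
reflect_idx <- function(i, n) {
  if (n == 1L) return(1L)
  j <- (i - 1L) %% (2L * n)
  if (j < n) j + 1L else 2L * n - j
}

# direct double-sum evaluation of the smoothed CDF at every pixel and bin:
# R_k(p) = 1 - sum_{p' in V(p)} C(I(p') - s_k) W(||p - p'||) with W
# truncated, normalized to unit sum, and C the Gaussian CDF of the
# intensity kernel
direct_cdf_field <- function(img, spec) {
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  r <- spec$window_radius
  d <- -r:r
  w1 <- if (spec$sigma_w > 0) exp(-d^2 / (2 * spec$sigma_w^2)) else rep(1, length(d))
  W2 <- outer(w1, w1)
  W2 <- W2 / sum(W2)
  R <- array(0, c(h, w, spec$nb))
  for (i in seq_len(h)) {
    ri <- vapply(i + d, reflect_idx, integer(1), n = h)
    for (j in seq_len(w)) {
      ci <- vapply(j + d, reflect_idx, integer(1), n = w)
      patch <- m[ri, ci]
      for (k in seq_len(spec$nb)) {
        R[i, j, k] <- 1 - sum(pnorm(patch - spec$bin_centers[k],
                                    sd = spec$sigma_k) * W2)
      }
    }
  }
  R
}

# scalar-loop 4-neighbor Laplacian, normalized by the stencil bound 4
loop_laplacian <- function(img) {
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    nb <- m[reflect_idx(i - 1L, h), j] + m[reflect_idx(i + 1L, h), j] +
          m[i, reflect_idx(j - 1L, w)] + m[i, reflect_idx(j + 1L, w)]
    out[i, j] <- max(-1, min(1, (nb - 4 * m[i, j]) / 4))
  }
  out
}

# scalar-loop classic shock step over the 3x3 square element
loop_classic_shock <- function(img) {
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  lap <- loop_laplacian(img)
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (lap[i, j] == 0) next
    win <- numeric(0)
    for (di in -1:1) for (dj in -1:1) {
      win <- c(win, m[reflect_idx(i + di, h), reflect_idx(j + dj, w)])
    }
    out[i, j] <- if (lap[i, j] < 0) max(win) else min(win)
  }
  out
}

# sort-based windowed order statistic (lower median / min / max)
loop_window_stat <- function(img, radius, stat = c("median", "min", "max")) {
  stat <- match.arg(stat)
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- numeric(0)
    for (di in -radius:radius) for (dj in -radius:radius) {
      win <- c(win, m[reflect_idx(i + di, h), reflect_idx(j + dj, w)])
    }
    srt <- sort(win)
    out[i, j] <- switch(stat,
      median = srt[(length(srt) + 1L) %/% 2L],
      min = srt[1L],
      max = srt[length(srt)]
    )
  }
  out
}

# degenerate spec: unweighted 3x3 rank filter with near-delta intensity kernel
degenerate_spec <- function(nb = 256L) {
  histogram_spec(nb = nb, sigma_k = 0, sigma_w = 0, window_radius = 1L)
}
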