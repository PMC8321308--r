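# Internal convolution / padding helpers.
#
# All window-based operators in the package use mirror ("symmetric")
# boundary padding: the image is reflected at each border with the edge
# pixel repeated. Index folding makes the reflection periodic, so the
# padding radius may exceed the image size.

# fold index i (possibly outside 1..n) back into 1..n by symmetric reflection
mirror_index <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# pad a matrix by r pixels on each side with symmetric reflection
pad_mirror <- function(m, r) {
  if (r == 0L) return(m)
  ri <- mirror_index(seq.int(1L - r, nrow(m) + r), nrow(m))
  ci <- mirror_index(seq.int(1L - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 1D kernel taps of the spatial weight W on offsets -r..r:
# truncated Gaussian of std sigma, or a flat box when sigma == 0
spatial_taps <- function(sigma, r) {
  d <- seq.int(-r, r)
  if (sigma <= 0) rep.int(1, 2L * r + 1L) else exp(-d^2 / (2 * sigma^2))
}

# correlate a padded matrix with a separable symmetric kernel, returning the
# "valid" region (the original image support). `pad` must have been padded
# by r = (length(k) - 1) / 2 on each side.
sep_conv_valid <- function(pad, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(pad) - 2L * r
  w <- ncol(pad) - 2L * r
  # rows pass: collapse columns
  tmp <- matrix(0, nrow(pad), w)
  for (a in seq_along(k)) {
    tmp <- tmp + k[a] * pad[, a:(a + w - 1L), drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (a in seq_along(k)) {
    out <- out + k[a] * tmp[a:(a + h - 1L), , drop = FALSE]
  }
  out
}

# full separable filtering with mirror padding
sep_filter_mirror <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  sep_conv_valid(pad_mirror(m, r), k)
}

# Gaussian blur with mirror padding (used by fixtures); kernel normalized
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  sep_filter_mirror(m, k / sum(k))
}

# stack of all shifted copies of m over the (2r+1)^2 square window (or the
# 5-site cross), mirror padded; returns h x w x n array. Used by the exact
# min / max / median window filters.
window_stack <- function(m, r, element = c("square", "cross")) {
  element <- match.arg(element)
  h <- nrow(m)
  w <- ncol(m)
  pad <- pad_mirror(m, r)
  offs <- expand.grid(dy = seq.int(-r, r), dx = seq.int(-r, r))
  if (element == "cross") {
    offs <- offs[abs(offs$dy) + abs(offs$dx) <= r, , drop = FALSE]
  }
  out <- array(0, c(h, w, nrow(offs)))
  for (i in seq_len(nrow(offs))) {
    out[, , i] <- pad[(1L + r + offs$dy[i]):(h + r + offs$dy[i]),
                      (1L + r + offs$dx[i]):(w + r + offs$dx[i])]
  }
  out
}
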