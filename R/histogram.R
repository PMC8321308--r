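#' Smoothed local histogram specification
#'
#' Bundles the bin layout and kernel bandwidths that define the smoothed
#' local histogram of a pixel neighborhood: each neighbor `p'` contributes a
#' Gaussian bump `K(I(p') - s_k)` in intensity, weighted by a Gaussian
#' spatial factor `W(||p - p'||)` — rather than the unit count of an
#' ordinary histogram. The running integral of this histogram over the bins
#' is a smoothed local CDF whose inversion yields smoothed rank-order
#' (quantile) filters; see [smoothed_cdf_field()] and
#' [smoothed_rank_filter()].
#'
#' `sigma_w = 0` is the degenerate spatial kernel: `W` is constant over the
#' window, so the operator reduces to an unweighted rank filter on the
#' square window (the regime in which the smoothed median collapses to the
#' classic median filter). `sigma_k` requests below `1e-4` (including
#' exactly 0) are floored at `1e-4` so the intensity CDF stays an error
#' function; at that bandwidth the smoothed quantile agrees with the exact
#' sample quantile to well within one bin of a 256-bin layout.
#'
#' @param nb Number of histogram bins. Default 256, aligning bin centers
#'   with 8-bit representable intensities.
#' @param sigma_k Standard deviation of the intensity kernel `K`, in
#'   intensity units on the \[0, 1\] scale. Default 0.05.
#' @param sigma_w Standard deviation of the spatial kernel `W`, in pixels.
#'   Default 3 (the standard setup).
#' @param window_radius Half-width, in pixels, of the square neighborhood
#'   over which `W` is truncated. Defaults to `max(1, ceiling(3 * sigma_w))`
#'   and must be at least that when `sigma_w > 0`.
#' @param bin_centers Strictly increasing bin centers spanning exactly
#'   \[0, 1\]. Defaults to `nb` equally spaced values.
#'
#' @return An object of class `histogram_spec`.
#' @examples
#' histogram_spec()                      # the standard setup
#' histogram_spec(sigma_w = 0, nb = 256) # degenerate spec: unweighted ranks
#' @export
histogram_spec <- function(nb = 256L, sigma_k = 0.05, sigma_w = 3,
                           window_radius = NULL, bin_centers = NULL) {
  nb <- as.integer(nb)
  if (nb < 2L) stop("`nb` must be at least 2", call. = FALSE)
  if (sigma_k < 0 || sigma_w < 0) {
    stop("kernel bandwidths must be nonnegative", call. = FALSE)
  }
  sigma_k <- max(sigma_k, 1e-4)
  if (is.null(bin_centers)) bin_centers <- seq(0, 1, length.out = nb)
  if (length(bin_centers) != nb || any(diff(bin_centers) <= 0) ||
      bin_centers[1L] != 0 || bin_centers[nb] != 1) {
    stop("`bin_centers` must be ", nb, " strictly increasing values with ",
         "first 0 and last 1", call. = FALSE)
  }
  min_r <- if (sigma_w > 0) max(1L, as.integer(ceiling(3 * sigma_w))) else 1L
  if (is.null(window_radius)) window_radius <- min_r
  window_radius <- as.integer(window_radius)
  if (window_radius < min_r) {
    stop("`window_radius` must be at least ", min_r,
         " for sigma_w = ", sigma_w, call. = FALSE)
  }
  structure(
    list(nb = nb, bin_centers = bin_centers, sigma_k = sigma_k,
         sigma_w = sigma_w, window_radius = window_radius),
    class = "histogram_spec"
  )
}

#' @export
print.histogram_spec <- function(x, ...) {
  cat(sprintf(
    "<histogram_spec> nb = %d, sigma_k = %g, sigma_w = %g, window_radius = %d\n",
    x$nb, x$sigma_k, x$sigma_w, x$window_radius
  ))
  invisible(x)
}

#' Smoothed local histogram at one pixel (reference implementation)
#'
#' Direct double-sum evaluation of the smoothed local histogram
#' `f(s_k) = sum over p' in V(p) of K(I(p') - s_k) * W(||p - p'||)`
#' at a single pixel, with Gaussian `K` (density, std `sigma_k`), Gaussian
#' `W` (unnormalized, std `sigma_w`; identically 1 when `sigma_w = 0`),
#' `V(p)` the square window of half-width `window_radius`, and mirror
#' padding at the borders. This is the scalar reference path; whole-image
#' filtering goes through the convolutional [smoothed_cdf_field()].
#'
#' @param img A [gray_image].
#' @param p Integer vector `c(row, col)`, 1-based, inside the image.
#' @param spec A [histogram_spec].
#' @return Numeric vector of length `spec$nb`: the histogram ordinates at
#'   the bin centers.
#' @export
smoothed_local_histogram <- function(img, p, spec) {
  img <- as_gray_image(img)
  stopifnot(inherits(spec, "histogram_spec"))
  p <- as.integer(p)
  if (length(p) != 2L || p[1L] < 1L || p[1L] > nrow(img) ||
      p[2L] < 1L || p[2L] > ncol(img)) {
    stop("`p` must be a (row, col) coordinate inside the image", call. = FALSE)
  }
  r <- spec$window_radius
  ri <- mirror_index(seq.int(p[1L] - r, p[1L] + r), nrow(img))
  ci <- mirror_index(seq.int(p[2L] - r, p[2L] + r), ncol(img))
  patch <- img_values(img)[ri, ci, drop = FALSE]
  d2 <- outer(seq.int(-r, r)^2, seq.int(-r, r)^2, `+`)
  wgt <- if (spec$sigma_w > 0) exp(-d2 / (2 * spec$sigma_w^2)) else d2 * 0 + 1
  vapply(spec$bin_centers, function(s) {
    sum(stats::dnorm(patch - s, sd = spec$sigma_k) * wgt)
  }, numeric(1))
}

#' Smoothed local CDF field of an image
#'
#' Computes, for every pixel `p` and bin `k`, the spatially smoothed
#' cumulative integral `R_k(p) = 1 - (C(I(.) - s_k) * W)(p)` of the
#' smoothed local histogram, where `C` is the Gaussian CDF of the intensity
#' kernel `K` (an error function) and `*` is 2D convolution with the
#' truncated, unit-sum-normalized spatial kernel `W`, mirror padded.
#' `R_k(p)` is the kernel-smoothed fraction of the neighborhood's intensity
#' mass lying below bin `s_k`; it is nondecreasing in `k` and lies in
#' \[0, 1\], so inverting it at a level `t` yields the smoothed quantile of
#' the neighborhood.
#'
#' The computation is separable-convolutional (one 2D Gaussian filtering
#' per bin) and agrees with the per-pixel direct sum of the integral of
#' [smoothed_local_histogram()] to within `1e-6`.
#'
#' @inheritParams smoothed_local_histogram
#' @return An object of class `smoothed_cdf_field`: a list with `R` (an
#'   `h x w x nb` array), and `spec`.
#' @export
smoothed_cdf_field <- function(img, spec) {
  img <- as_gray_image(img)
  stopifnot(inherits(spec, "histogram_spec"))
  m <- img_values(img)
  r <- spec$window_radius
  taps <- spatial_taps(spec$sigma_w, r)
  # separable 1D taps whose outer product is the unit-sum 2D kernel
  taps <- taps / sum(taps)
  pad <- pad_mirror(m, r)
  R <- array(0, c(nrow(m), ncol(m), spec$nb))
  for (k in seq_len(spec$nb)) {
    Ck <- stats::pnorm(pad - spec$bin_centers[k], sd = spec$sigma_k)
    R[, , k] <- 1 - sep_conv_valid(Ck, taps)
  }
  # numerical hygiene at tolerance 1e-9: clip into [0, 1] and snap the
  # zero-mass tails flat, so the extreme quantile levels see exact plateaus
  R[R < 1e-9] <- 0
  R[R > 1 - 1e-9] <- 1
  structure(list(R = R, spec = spec), class = "smoothed_cdf_field")
}

#' @export
print.smoothed_cdf_field <- function(x, ...) {
  d <- dim(x$R)
  cat(sprintf("<smoothed_cdf_field> %d x %d pixels, %d bins\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Invert a smoothed local CDF at a quantile level
#'
#' Given the nondecreasing per-pixel CDF values `R_1..R_nb` over the bin
#' centers, finds the bracketing bins `s_k`, `s_{k+1}` with
#' `R_k <= v <= R_{k+1}` and returns the linearly interpolated intensity
#' `s_k + (v - R_k) / (R_{k+1} - R_k) * (s_{k+1} - s_k)`. Levels below
#' `R_1` clamp to `s_1`, levels above `R_nb` clamp to `s_nb`, and a
#' degenerate bracket (`R_{k+1} = R_k`) resolves to the lower bin `s_k`.
#'
#' @param R Nondecreasing numeric vector of CDF values, one per bin.
#' @param bin_centers Ascending bin centers, same length as `R`.
#' @param v Quantile level(s) in \[0, 1\].
#'
#' @section Extreme levels:
#' `v = 0` and `v = 1` request the essential infimum / supremum of the
#' smoothed neighborhood distribution. The CDF is exactly flat on its
#' zero-mass tails (values within `1e-9` of 0 or 1 are treated as 0 or 1),
#' so the inverse is set-valued there; the lookup returns the edge of the
#' flat tail, offset half a bin inward to center the quantization error.
#'
#' @return Interpolated intensity value(s), always within
#'   `[bin_centers[1], bin_centers[nb]]`.
#' @examples
#' quantile_lookup(c(0, 0.25, 0.5, 0.75, 1), seq(0, 1, 0.25), 0.375)
#' @export
quantile_lookup <- function(R, bin_centers, v) {
  if (length(R) != length(bin_centers)) {
    stop("`R` and `bin_centers` must have equal length", call. = FALSE)
  }
  if (any(diff(R) < -1e-12)) {
    stop("`R` must be nondecreasing", call. = FALSE)
  }
  if (any(v < 0 | v > 1)) stop("`v` must lie in [0, 1]", call. = FALSE)
  s <- bin_centers
  nb <- length(R)
  vapply(v, function(vi) {
    if (vi == 0) {
      z <- sum(R <= 1e-9)              # right end of the zero tail
      if (z == 0L) return(s[1L])
      if (z >= nb) return(s[nb])
      return(s[z] + (s[z + 1L] - s[z]) / 2)
    }
    if (vi == 1) {
      o <- match(TRUE, R >= 1 - 1e-9)  # left end of the saturated tail
      if (is.na(o)) return(s[nb])
      if (o == 1L) return(s[1L])
      return(s[o] - (s[o] - s[o - 1L]) / 2)
    }
    a <- sum(R < vi)                   # last bin strictly below the level
    b <- sum(R <= vi)
    if (b == 0L) return(s[1L])
    if (a == nb) return(s[nb])
    if (b > a) return(s[a + 1L])       # exact hit (lower edge of a plateau)
    dR <- R[a + 1L] - R[a]
    s[a] + (vi - R[a]) / dR * (s[a + 1L] - s[a])
  }, numeric(1))
}

# vectorized CDF inversion over a whole field: cdf is a smoothed_cdf_field,
# t a matrix of levels (h x w). Same bracketing rules as quantile_lookup.
cdf_field_invert <- function(cdf, t) {
  R <- cdf$R
  s <- cdf$spec$bin_centers
  nb <- cdf$spec$nb
  h <- dim(R)[1L]; w <- dim(R)[2L]
  cnt_lt <- matrix(0L, h, w)   # bins strictly below the level
  cnt_le <- matrix(0L, h, w)   # bins at or below the level
  cnt_z <- matrix(0L, h, w)    # zero-tail bins
  first_one <- matrix(NA_integer_, h, w) # left end of the saturated tail
  for (k in seq_len(nb)) {
    Rk <- R[, , k]
    cnt_lt <- cnt_lt + (Rk < t)
    cnt_le <- cnt_le + (Rk <= t)
    cnt_z <- cnt_z + (Rk <= 1e-9)
    hit <- is.na(first_one) & Rk >= 1 - 1e-9
    first_one[hit] <- k
  }
  out <- matrix(s[1L], h, w)

  at0 <- t == 0
  if (any(at0)) {
    z <- pmin(pmax(cnt_z[at0], 1L), nb)
    mid <- ifelse(cnt_z[at0] == 0L, s[1L],
           ifelse(cnt_z[at0] >= nb, s[nb],
                  s[z] + (s[pmin(z + 1L, nb)] - s[z]) / 2))
    out[at0] <- mid
  }
  at1 <- t == 1
  if (any(at1)) {
    o <- first_one[at1]
    o_safe <- pmin(pmax(ifelse(is.na(o), nb, o), 2L), nb)
    out[at1] <- ifelse(is.na(o), s[nb],
                ifelse(o == 1L, s[1L],
                       s[o_safe] - (s[o_safe] - s[o_safe - 1L]) / 2))
  }

  gen <- !at0 & !at1
  out[gen & cnt_le == 0L] <- s[1L]
  out[gen & cnt_lt == nb] <- s[nb]
  plateau <- gen & cnt_le > cnt_lt & cnt_le > 0L & cnt_lt < nb
  out[plateau] <- s[pmin(cnt_lt[plateau] + 1L, nb)]
  mid <- which(gen & cnt_le == cnt_lt & cnt_le >= 1L & cnt_lt < nb)
  if (length(mid)) {
    rc <- arrayInd(mid, c(h, w))
    k0 <- cnt_lt[mid]
    Rk <- R[cbind(rc, k0)]
    Rk1 <- R[cbind(rc, k0 + 1L)]
    out[mid] <- s[k0] + (t[mid] - Rk) / (Rk1 - Rk) * (s[k0 + 1L] - s[k0])
  }
  out
}
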