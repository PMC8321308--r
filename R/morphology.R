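#' Smoothed rank-order filter
#'
#' The workhorse of the package: for each pixel, inverts the smoothed local
#' CDF of its neighborhood (see [smoothed_cdf_field()]) at a quantile level
#' `t`, returning the smoothed `t`-quantile of the window. `t = 1/2` is the
#' smoothed median; `t < 1/2` a smoothed erosion; `t > 1/2` a smoothed
#' dilation. `t` may be a scalar or a per-pixel matrix of levels — the
#' per-pixel form is what the shock filter uses, coupling the level to the
#' local Laplacian.
#'
#' In the degenerate regime `sigma_w = 0`, `sigma_k` at its floor, the
#' filter reproduces the exact windowed median / minimum / maximum (at
#' `t = 1/2, 0, 1`) to within one bin width `1/nb`.
#'
#' @param img A [gray_image].
#' @param t Quantile level in \[0, 1\]: scalar, or a matrix matching
#'   `dim(img)`.
#' @param spec A [histogram_spec].
#' @return A [gray_image].
#' @examples
#' img <- make_texture(32, 32, frequencies = 4, amplitudes = 0.3,
#'                     noise_sd = 0.1, seed = 7)
#' smoothed_rank_filter(img, 0.5, histogram_spec(sigma_w = 1))
#' @export
smoothed_rank_filter <- function(img, t, spec) {
  img <- as_gray_image(img)
  stopifnot(inherits(spec, "histogram_spec"))
  if (is.matrix(t)) {
    if (!identical(dim(t), dim(img))) {
      stop("per-pixel `t` must match the image dimensions", call. = FALSE)
    }
  } else {
    if (length(t) != 1L) stop("`t` must be a scalar or a matrix", call. = FALSE)
    t <- matrix(t, nrow(img), ncol(img))
  }
  if (any(t < 0 | t > 1)) stop("`t` must lie in [0, 1]", call. = FALSE)
  cdf <- smoothed_cdf_field(img, spec)
  out <- cdf_field_invert(cdf, t)
  # rank-order operators do not create new extrema: the intensity kernel
  # can spread quantile mass slightly beyond the sample range at extreme
  # levels, so outputs are clamped to the input's intensity range
  out <- pmin(pmax(out, min(img)), max(img))
  gray_image(out)
}

#' Smoothed median, erosion and dilation
#'
#' Thin wrappers over [smoothed_rank_filter()]: the smoothed median is the
#' level-`1/2` quantile filter; a smoothed erosion of strength `level` uses
#' `t = 1/2 - level` and a smoothed dilation `t = 1/2 + level`, with
#' `level` in `(0, 1/2]`. At `level = 1/2` they reach the full (smoothed)
#' windowed minimum and maximum.
#'
#' @inheritParams smoothed_rank_filter
#' @param level Operator strength in `(0, 1/2]`.
#' @return A [gray_image].
#' @export
smoothed_median <- function(img, spec) {
  smoothed_rank_filter(img, 0.5, spec)
}

#' @rdname smoothed_median
#' @export
smoothed_erode <- function(img, level, spec) {
  check_level(level)
  smoothed_rank_filter(img, 0.5 - level, spec)
}

#' @rdname smoothed_median
#' @export
smoothed_dilate <- function(img, level, spec) {
  check_level(level)
  smoothed_rank_filter(img, 0.5 + level, spec)
}

check_level <- function(level) {
  if (length(level) != 1L || level <= 0 || level > 0.5) {
    stop("`level` must lie in (0, 1/2]", call. = FALSE)
  }
}
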