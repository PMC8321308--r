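#' One classic shock filtering iteration
#'
#' The original morphological shock switch: where the discrete Laplacian is
#' negative the pixel takes the window maximum (dilation by the structuring
#' element), where positive the window minimum (erosion), and where exactly
#' zero it passes through unchanged. Iterating creates ruptures between
#' local maxima and minima. The structuring element of 1-pixel width is the
#' 3x3 square by default; a 4-connected cross is available behind the
#' `element` flag.
#'
#' @param img A [gray_image].
#' @param element `"square"` (3x3) or `"cross"` (center + 4 neighbors).
#' @return A [gray_image].
#' @export
classic_shock_step <- function(img, element = c("square", "cross")) {
  element <- match.arg(element)
  img <- as_gray_image(img)
  m <- img_values(img)
  lap <- normalized_laplacian(img)
  stk <- window_stack(m, 1L, element)
  wmax <- apply(stk, c(1L, 2L), max)
  wmin <- apply(stk, c(1L, 2L), min)
  out <- m
  out[lap < 0] <- wmax[lap < 0]
  out[lap > 0] <- wmin[lap > 0]
  gray_image(out)
}

#' Iterated classic shock filter
#'
#' Iterates [classic_shock_step()] and records the scale space, under the
#' same contract as [smoothed_shock_filter()]. Because each step takes
#' exact window minima/maxima, every iterate stays exactly within the
#' input's \[min, max\] range, and binary piecewise-constant images are
#' fixed points.
#'
#' @inheritParams classic_shock_step
#' @param nit Number of iterations, at least 1.
#' @return A `scale_space` object.
#' @export
classic_shock_filter <- function(img, nit, element = c("square", "cross")) {
  element <- match.arg(element)
  img <- as_gray_image(img)
  nit <- as.integer(nit)
  if (nit < 1L) stop("`nit` must be at least 1", call. = FALSE)
  iterates <- vector("list", nit + 1L)
  iterates[[1L]] <- img
  for (i in seq_len(nit)) {
    iterates[[i + 1L]] <- classic_shock_step(iterates[[i]], element)
  }
  new_scale_space(iterates, img,
                  list(filter = "classic_shock", nit = nit, element = element))
}

#' Exact windowed median filter
#'
#' Plain median filtering over the `(2 * radius + 1)` square window with
#' mirror padding; the lower median is taken when the window count is even
#' (it is odd for all square windows, but the rule fixes the contract).
#' This is the limiting case of the smoothed median as both kernel
#' bandwidths degenerate, and serves as the oracle in the reduction tests.
#'
#' @param img A [gray_image].
#' @param radius Window half-width in pixels, at least 1.
#' @return A [gray_image].
#' @export
median_filter <- function(img, radius = 1L) {
  img <- as_gray_image(img)
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be at least 1", call. = FALSE)
  stk <- window_stack(img_values(img), radius)
  n <- dim(stk)[3L]
  lower_mid <- (n + 1L) %/% 2L
  out <- apply(stk, c(1L, 2L), function(v) sort.int(v)[lower_mid])
  gray_image(out)
}
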