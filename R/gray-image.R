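#' Grayscale image objects
#'
#' A `gray_image` is a numeric matrix of intensities on the canonical
#' \[0, 1\] scale. It is the universal currency of every filter in the
#' package: all operators take a `gray_image` (or plain matrix, coerced on
#' entry) and return a `gray_image`. Working on a fixed normalized scale
#' decouples the filter mathematics from the bit depth of the source file;
#' 8-bit and 16-bit rasters are rescaled by their maximum representable
#' value at load time.
#'
#' @param values Numeric matrix of intensities. All entries must be finite
#'   and lie in \[0, 1\]; both dimensions must be at least 1.
#'
#' @return A `gray_image`: a numeric matrix with class
#'   `c("gray_image", "matrix")`.
#'
#' @examples
#' img <- gray_image(matrix(seq(0, 1, length.out = 12), 3, 4))
#' dim(img)
#' range(img)
#' @export
gray_image <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (min(values) < 0 || max(values) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(unname(values), class = c("gray_image", "matrix"))
}

#' Coerce to a grayscale image
#'
#' @param x A numeric matrix or `gray_image`.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(as.matrix(x))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, intensities in [%.4f, %.4f], mean %.4f\n",
    nrow(x), ncol(x), min(x), max(x), mean(x)
  ))
  invisible(x)
}

# strip the class so plain-matrix arithmetic cannot escape validation
img_values <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

#' Signed residual between two images
#'
#' Per-pixel signed difference `original - filtered`, the residual map used
#' to visualize what an iterative filter removed from the input. The result
#' is a plain matrix (values in \[-1, 1\]), not a `gray_image`, because it
#' is signed.
#'
#' @param original,filtered `gray_image` objects (or matrices) of equal
#'   dimensions.
#' @return A numeric matrix of signed differences in \[-1, 1\].
#' @examples
#' a <- make_constant(4, 4, 1)
#' b <- make_constant(4, 4, 0)
#' residual(a, b)[1, 1]
#' @export
residual <- function(original, filtered) {
  original <- as_gray_image(original)
  filtered <- as_gray_image(filtered)
  if (!identical(dim(original), dim(filtered))) {
    stop("`original` and `filtered` must have identical dimensions", call. = FALSE)
  }
  img_values(original) - img_values(filtered)
}

#' Total variation of an image
#'
#' Anisotropic (L1) total variation: the sum of absolute differences between
#' horizontally and vertically adjacent pixels. Used throughout the test
#' suite as a scalar summary of roughness/smoothness.
#'
#' @param img A `gray_image` or numeric matrix.
#' @return A single nonnegative number.
#' @export
total_variation <- function(img) {
  m <- img_values(as_gray_image(img))
  tv <- 0
  if (nrow(m) > 1L) tv <- tv + sum(abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]))
  if (ncol(m) > 1L) tv <- tv + sum(abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]))
  tv
}
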