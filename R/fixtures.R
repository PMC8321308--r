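#' Synthetic test images
#'
#' Generators for the synthetic images used throughout the package's tests
#' and robustness experiments: constant fields, sharp and blurred vertical
#' step edges, disks on a background, and pseudo-random sinusoidal
#' textures. Together they exercise the behaviors the filters are built
#' for — homogeneous regions, contours, inflection zones, and texture —
#' with no external data.
#'
#' @param h,w Image height and width in pixels.
#' @param value Constant intensity in \[0, 1\].
#' @return A [gray_image].
#' @name fixtures
#' @examples
#' make_step(64, 64, 32, blur_sigma = 2)
#' make_disk(64, 64, radius = 20)
NULL

#' @rdname fixtures
#' @export
make_constant <- function(h, w, value) {
  if (value < 0 || value > 1) stop("`value` must lie in [0, 1]", call. = FALSE)
  gray_image(matrix(value, h, w))
}

#' @rdname fixtures
#' @param edge_column Column index of the step; columns up to
#'   `edge_column` take `low`, the rest `high`. Must satisfy
#'   `0 < edge_column < w`.
#' @param low,high Intensities on either side of the step,
#'   `0 <= low < high <= 1`.
#' @param blur_sigma Gaussian blur std in pixels; 0 leaves the step sharp.
#' @export
make_step <- function(h, w, edge_column, low = 0, high = 1, blur_sigma = 0) {
  if (!(low >= 0 && low < high && high <= 1)) {
    stop("need 0 <= low < high <= 1", call. = FALSE)
  }
  if (edge_column <= 0 || edge_column >= w) {
    stop("`edge_column` must lie strictly inside (0, w)", call. = FALSE)
  }
  m <- matrix(ifelse(seq_len(w) <= edge_column, low, high), h, w, byrow = TRUE)
  if (blur_sigma > 0) m <- gaussian_blur(m, blur_sigma)
  gray_image(pmin(pmax(m, 0), 1))
}

#' @rdname fixtures
#' @param center `c(row, col)` of the disk center; defaults to the image
#'   center.
#' @param radius Disk radius in pixels, positive.
#' @param fg,bg Foreground (inside) and background intensities in \[0, 1\].
#' @export
make_disk <- function(h, w, center = c((h + 1) / 2, (w + 1) / 2), radius,
                      fg = 1, bg = 0) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  d2 <- outer((seq_len(h) - center[1L])^2, (seq_len(w) - center[2L])^2, `+`)
  gray_image(matrix(ifelse(d2 <= radius^2, fg, bg), h, w))
}

#' @rdname fixtures
#' @param frequencies Cycles across the image for each sinusoidal
#'   component; components alternate horizontal / vertical / diagonal
#'   orientation.
#' @param amplitudes Amplitude of each component (recycled against
#'   `frequencies`).
#' @param noise_sd Std of the additive seeded Gaussian field.
#' @param seed Integer seed; identical seeds give bit-identical textures.
#' @export
make_texture <- function(h, w, frequencies = c(3, 7), amplitudes = c(0.5, 0.25),
                         noise_sd = 0.1, seed = 1L) {
  amplitudes <- rep_len(amplitudes, length(frequencies))
  x <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  y <- matrix(seq_len(h) / h, h, w)
  m <- matrix(0, h, w)
  for (i in seq_along(frequencies)) {
    phase <- switch((i - 1L) %% 3L + 1L, x, y, (x + y) / 2)
    m <- m + amplitudes[i] * sin(2 * pi * frequencies[i] * phase)
  }
  if (noise_sd > 0) {
    m <- m + with_seed(seed, matrix(stats::rnorm(h * w, sd = noise_sd), h, w))
  }
  rng <- range(m)
  if (rng[2L] - rng[1L] < .Machine$double.eps) {
    return(make_constant(h, w, 0.5))
  }
  gray_image((m - rng[1L]) / (rng[2L] - rng[1L]))
}

#' Standard fixture set
#'
#' The fixed collection of synthetic images (constant, sharp step, blurred
#' step, disk, texture) used by the robustness experiments and acceptance
#' tests, at a fixed size and fixed texture seed. It plays the role of a
#' small benchmark image set for the scaled-down denoising-robustness
#' protocol.
#'
#' @param size Side length in pixels (square images). Default 64.
#' @return A named list of [gray_image] objects.
#' @export
fixture_set <- function(size = 64L) {
  size <- as.integer(size)
  list(
    constant = make_constant(size, size, 0.5),
    step = make_step(size, size, size %/% 2L, low = 0.1, high = 0.9),
    blurred_step = make_step(size, size, size %/% 2L, low = 0.1, high = 0.9,
                             blur_sigma = 2),
    disk = make_disk(size, size, radius = size / 4, fg = 0.85, bg = 0.15),
    texture = make_texture(size, size, frequencies = c(3, 7, 13),
                           amplitudes = c(0.5, 0.3, 0.15),
                           noise_sd = 0.15, seed = 20210315L)
  )
}

# run code with a private RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
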