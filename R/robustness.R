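#' Additive-Gaussian noise ladder
#'
#' A strictly increasing sequence of noise standard deviations, expressed
#' on the 0-255 intensity scale as is conventional for denoising
#' benchmarks, together with the master seed from which every per-(scale,
#' image) corruption seed is derived. The default ladder
#' `{5, 10, 15, 20, 25}` is the classic benchmark ladder for
#' additive-white-Gaussian-noise denoising evaluation.
#'
#' @param scales Strictly increasing nonnegative noise stds (0-255 scale),
#'   at least two.
#' @param seed Integer master seed.
#' @return An object of class `noise_ladder`.
#' @export
noise_ladder <- function(scales = c(5, 10, 15, 20, 25), seed = 1L) {
  if (length(scales) < 2L || any(scales < 0) || any(diff(scales) <= 0)) {
    stop("`scales` must be at least two strictly increasing nonnegative values",
         call. = FALSE)
  }
  structure(list(scales = scales, seed = as.integer(seed)),
            class = "noise_ladder")
}

#' Add white Gaussian noise to an image
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation
#' `sigma255 / 255` on the \[0, 1\] scale, then clamps to \[0, 1\]
#' (matching 8-bit image semantics). Deterministic for a given seed; the
#' caller's RNG state is untouched.
#'
#' @param img A [gray_image].
#' @param sigma255 Noise std on the 0-255 scale, nonnegative.
#' @param seed Integer seed.
#' @return A [gray_image].
#' @export
add_gaussian_noise <- function(img, sigma255, seed) {
  img <- as_gray_image(img)
  if (sigma255 < 0) stop("`sigma255` must be nonnegative", call. = FALSE)
  if (sigma255 == 0) return(img)
  m <- img_values(img)
  noise <- with_seed(seed,
                     matrix(stats::rnorm(length(m), sd = sigma255 / 255),
                            nrow(m), ncol(m)))
  gray_image(pmin(pmax(m + noise, 0), 1))
}

#' Structural similarity index (SSIM)
#'
#' Mean structural similarity between two images: local luminance,
#' contrast and structure comparisons under an 11x11 Gaussian window of
#' std 1.5, with the standard stabilizers `K1 = 0.01`, `K2 = 0.03` and
#' dynamic range 1 (the canonical constants of the index). Local
#' statistics are taken over windows fully inside the image (valid
#' convolution), and the map is averaged.
#'
#' @param a,b [gray_image] objects of equal dimensions, each at least
#'   11x11.
#' @return A single number in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(a, b) {
  a <- as_gray_image(a)
  b <- as_gray_image(b)
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  win <- 11L
  if (nrow(a) < win || ncol(a) < win) {
    stop("images must be at least ", win, "x", win, call. = FALSE)
  }
  k <- exp(-(seq.int(-5L, 5L))^2 / (2 * 1.5^2))
  k <- k / sum(k)
  A <- img_values(a); B <- img_values(b)
  mu_a <- sep_conv_valid(A, k)
  mu_b <- sep_conv_valid(B, k)
  var_a <- sep_conv_valid(A * A, k) - mu_a^2
  var_b <- sep_conv_valid(B * B, k) - mu_b^2
  cov_ab <- sep_conv_valid(A * B, k) - mu_a * mu_b
  C1 <- 0.01^2
  C2 <- 0.03^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s)
}

#' SSIM quality curve of a denoiser over a noise ladder
#'
#' For each scale of the ladder, corrupts every clean image with additive
#' Gaussian noise (seed derived deterministically from the ladder seed,
#' the scale index and the image index), denoises with `filter`, computes
#' the SSIM against the clean original, and averages across images.
#'
#' @param filter A function `gray_image -> gray_image` (use `identity` for
#'   the unfiltered baseline).
#' @param clean_images A list of [gray_image] objects (a single image is
#'   wrapped).
#' @param ladder A [noise_ladder()].
#' @param filter_name Label recorded in the output.
#' @return A tibble of class `quality_curve` with columns `filter`,
#'   `sigma` and `mean_ssim`, one row per ladder scale.
#' @seealso [alpha_sigma()], [autoplot.quality_curve()]
#' @export
quality_curve <- function(filter, clean_images, ladder,
                          filter_name = deparse(substitute(filter))) {
  stopifnot(inherits(ladder, "noise_ladder"))
  if (inherits(clean_images, "gray_image")) clean_images <- list(clean_images)
  if (length(clean_images) < 1L) {
    stop("need at least one clean image", call. = FALSE)
  }
  q <- vapply(seq_along(ladder$scales), function(k) {
    mean(vapply(seq_along(clean_images), function(i) {
      clean <- as_gray_image(clean_images[[i]])
      noisy <- add_gaussian_noise(clean, ladder$scales[k],
                                  seed = corruption_seed(ladder$seed, k, i))
      ssim(clean, as_gray_image(filter(noisy)))
    }, numeric(1)))
  }, numeric(1))
  out <- tibble::tibble(filter = filter_name, sigma = ladder$scales,
                        mean_ssim = q)
  class(out) <- c("quality_curve", class(out))
  out
}

# deterministic per-(scale, image) seed, kept well inside 32-bit range
corruption_seed <- function(master, k, i) {
  (as.integer(master) %% 1000003L) * 1009L + 7919L * as.integer(k) +
    as.integer(i)
}

#' Worst quality drop over a noise ladder: (alpha, sigma)-robustness
#'
#' Summarizes a quality curve by its worst per-unit-scale quality drop:
#' `alpha = max over consecutive scales of (Q_k - Q_{k+1}) / (sigma_{k+1}
#' - sigma_k)` — positive when quality falls — and `sigma`, the scale
#' `sigma_k` at which that worst drop begins (ties broken toward the
#' smallest scale). An algorithm is the more robust the lower its `alpha`
#' and the higher its `sigma`: its worst degradation is mild and only sets
#' in under aggressive noise.
#'
#' @param curve A [quality_curve()], or any data frame with `sigma` and
#'   `mean_ssim` columns (at least two rows).
#' @return An object of class `robustness_result`: a list with `alpha`,
#'   `sigma` and `filter`.
#' @examples
#' curve <- tibble::tibble(filter = "toy", sigma = c(5, 10, 15, 20),
#'                         mean_ssim = c(0.9, 0.8, 0.6, 0.55))
#' alpha_sigma(curve)
#' @export
alpha_sigma <- function(curve) {
  if (nrow(curve) < 2L) {
    stop("a quality curve needs at least two points", call. = FALSE)
  }
  sg <- curve$sigma
  q <- curve$mean_ssim
  m <- length(sg)
  rates <- (q[-m] - q[-1L]) / (sg[-1L] - sg[-m])
  j <- which.max(rates) # which.max takes the first (smallest-sigma) tie
  structure(
    list(alpha = rates[j], sigma = sg[j],
         filter = if ("filter" %in% names(curve)) curve$filter[1L] else NA_character_),
    class = "robustness_result"
  )
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> %s: alpha = %.6f at sigma = %g\n",
              x$filter, x$alpha, x$sigma))
  invisible(x)
}

#' Run a multi-filter robustness experiment
#'
#' The full evaluation harness: computes a [quality_curve()] for every
#' named filter over the same clean images and noise ladder (so all
#' filters see identical corruptions), then the (alpha, sigma) summary of
#' each. Filters are ranked by ascending `alpha`.
#'
#' @param filters Named list of functions `gray_image -> gray_image`.
#' @param clean_images List of [gray_image] objects.
#' @param ladder A [noise_ladder()].
#' @return An object of class `robustness_experiment`: a list with
#'   `curves` (tibble: filter, sigma, mean_ssim) and `summary` (tibble:
#'   filter, alpha, sigma_at_alpha, sorted by alpha).
#' @seealso [write_robustness_csv()]
#' @export
run_robustness_experiment <- function(filters, clean_images, ladder) {
  if (is.null(names(filters)) || any(names(filters) == "")) {
    stop("`filters` must be a fully named list", call. = FALSE)
  }
  curves <- lapply(names(filters), function(nm) {
    quality_curve(filters[[nm]], clean_images, ladder, filter_name = nm)
  })
  summaries <- lapply(curves, alpha_sigma)
  summary <- tibble::tibble(
    filter = vapply(summaries, `[[`, character(1), "filter"),
    alpha = vapply(summaries, `[[`, numeric(1), "alpha"),
    sigma_at_alpha = vapply(summaries, `[[`, numeric(1), "sigma")
  )
  summary <- summary[order(summary$alpha), ]
  structure(
    list(curves = do.call(rbind, curves), summary = summary),
    class = "robustness_experiment"
  )
}

#' @export
print.robustness_experiment <- function(x, ...) {
  cat("<robustness_experiment> ranking by ascending alpha:\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Write robustness experiment results as CSV
#'
#' Writes the per-scale quality table (`curves.csv`: filter, sigma,
#' mean_ssim) and the `(alpha, sigma)` summary (`summary.csv`: filter,
#' alpha, sigma_at_alpha) into a directory.
#'
#' @param experiment A [run_robustness_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_robustness_csv <- function(experiment, dir) {
  stopifnot(inherits(experiment, "robustness_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  curves_path <- file.path(dir, "curves.csv")
  summary_path <- file.path(dir, "summary.csv")
  utils::write.csv(as.data.frame(experiment$curves), curves_path,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(experiment$summary), summary_path,
                   row.names = FALSE)
  invisible(c(curves_path, summary_path))
}

#' Standard filter bank for robustness experiments
#'
#' The four reference denoisers compared by the harness: identity (no
#' filtering), classic 3x3 median, classic shock, and the smoothed shock
#' filter under the standard setup (`rho = 0.1`, `sigma_w = 3`).
#'
#' @param nit Iterations for the two shock filters. Default 3.
#' @param spec [histogram_spec()] for the smoothed shock filter.
#' @return A named list of filter functions suitable for
#'   [run_robustness_experiment()].
#' @export
standard_filter_bank <- function(nit = 3L, spec = histogram_spec()) {
  sp <- shock_params(rho = 0.1, nit = nit, spec = spec)
  list(
    identity = function(img) img,
    median = function(img) median_filter(img, 1L),
    classic_shock = function(img) {
      ss <- classic_shock_filter(img, nit)
      ss$iterates[[length(ss$iterates)]]
    },
    smoothed_shock = function(img) {
      ss <- smoothed_shock_filter(img, sp)
      ss$iterates[[length(ss$iterates)]]
    }
  )
}
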