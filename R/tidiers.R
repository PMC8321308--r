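#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scale space into per-iteration summaries
#'
#' One row per iterate (iteration 0 is the input) with scalar summaries of
#' how the filter reshapes the image: intensity range and mean, total
#' variation, root-mean-square residual against the input, and the count
#' of "intermediate" pixels with intensity in (0.25, 0.75) — a proxy for
#' unsharpened transition zones.
#'
#' @param x A `scale_space` from [smoothed_shock_filter()] or
#'   [classic_shock_filter()].
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `min`, `max`, `mean`,
#'   `total_variation`, `rms_residual`, `n_intermediate`.
#' @method tidy scale_space
#' @export
tidy.scale_space <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$iterates) - 1L,
    min = vapply(x$iterates, min, numeric(1)),
    max = vapply(x$iterates, max, numeric(1)),
    mean = vapply(x$iterates, mean, numeric(1)),
    total_variation = vapply(x$iterates, total_variation, numeric(1)),
    rms_residual = vapply(x$residuals, function(r) sqrt(mean(r^2)), numeric(1)),
    n_intermediate = vapply(x$iterates, function(im) {
      sum(img_values(im) > 0.25 & img_values(im) < 0.75)
    }, integer(1))
  )
}

#' @rdname tidy.scale_space
#' @method glance scale_space
#' @export
glance.scale_space <- function(x, ...) {
  p <- x$params
  if (inherits(p, "shock_params")) {
    tibble::tibble(
      filter = "smoothed_shock", nit = p$nit, rho = p$rho,
      sigma_w = p$spec$sigma_w, sigma_k = p$spec$sigma_k, nb = p$spec$nb
    )
  } else {
    tibble::tibble(
      filter = p$filter, nit = p$nit, rho = NA_real_,
      sigma_w = NA_real_, sigma_k = NA_real_, nb = NA_integer_
    )
  }
}

#' Tidy robustness results
#'
#' @param x A `robustness_result` or `robustness_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per filter: `filter`, `alpha`,
#'   `sigma_at_alpha`.
#' @method tidy robustness_result
#' @export
tidy.robustness_result <- function(x, ...) {
  tibble::tibble(filter = x$filter, alpha = x$alpha, sigma_at_alpha = x$sigma)
}

#' @rdname tidy.robustness_result
#' @method tidy robustness_experiment
#' @export
tidy.robustness_experiment <- function(x, ...) x$summary

#' @rdname tidy.robustness_result
#' @method glance robustness_experiment
#' @export
glance.robustness_experiment <- function(x, ...) {
  tibble::tibble(
    n_filters = nrow(x$summary),
    n_scales = length(unique(x$curves$sigma)),
    best_filter = x$summary$filter[1L],
    best_alpha = x$summary$alpha[1L]
  )
}

#' Plot methods
#'
#' `autoplot.gray_image()` renders an image as a grayscale raster;
#' `autoplot.scale_space()` facets the iterates of a shock filtering run;
#' `autoplot.quality_curve()` draws SSIM-versus-noise curves (one line per
#' filter when curves are row-bound together).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-shockfilter
NULL

image_df <- function(img, label = NULL) {
  m <- img_values(as_gray_image(img))
  d <- data.frame(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  if (!is.null(label)) d$label <- label
  d
}

#' @rdname autoplot-shockfilter
#' @method autoplot gray_image
#' @export
autoplot.gray_image <- function(object, ...) {
  ggplot2::ggplot(image_df(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-shockfilter
#' @method autoplot scale_space
#' @export
autoplot.scale_space <- function(object, ...) {
  dfs <- mapply(function(img, i) image_df(img, sprintf("iteration %d", i - 1L)),
                object$iterates, seq_along(object$iterates), SIMPLIFY = FALSE)
  d <- do.call(rbind, dfs)
  d$label <- factor(d$label, levels = unique(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-shockfilter
#' @method autoplot quality_curve
#' @export
autoplot.quality_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$mean_ssim,
                                       colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "noise std (0-255 scale)", y = "mean SSIM",
                  colour = "filter") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
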