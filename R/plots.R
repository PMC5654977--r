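#' @method autoplot icm_fit
#' @export
autoplot.icm_fit <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n, y = .data$moment)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_function(
      fun = function(n) exp(-(n - object$n0) / object$r_lambda_t),
      colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone size n", y = "first incomplete moment",
                  title = sprintf("rλt = %.3g, n0 = %.3g, R² = %.3f",
                                  object$r_lambda_t, object$n0,
                                  object$r_squared))
}

#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone size", y = "density",
                  title = sprintf("log-log slope = %.2f", object$exponent))
}

#' @method autoplot clone_size_sample
#' @export
autoplot.clone_size_sample <- function(object, ...) {
  col <- if ("cells" %in% names(object)) "cells" else "size"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[col]])) +
    ggplot2::stat_ecdf(ggplot2::aes(y = 1 - ggplot2::after_stat(ecdf))) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone size", y = "fraction of clones ≥ size")
}

#' Render a lattice state as a clone-label mosaic
#'
#' Colours each site by clone label (or cell kind), the usual way to inspect
#' clonal patchwork on the simulated basal layer.
#'
#' @param state A `lattice_state` or `lattice_sim`.
#' @param what `"label"` or `"kind"`.
#' @return A ggplot object.
#' @export
plot_lattice <- function(state, what = c("label", "kind")) {
  what <- match.arg(what)
  if (inherits(state, "lattice_sim")) state <- state$state
  m <- state[[what]]
  df <- tibble(row = as.vector(row(m)), col = as.vector(col(m)),
               value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}
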