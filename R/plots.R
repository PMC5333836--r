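#' Plot a box-count fit
#'
#' Log-log scatter of occupied-box counts against box size with the fitted
#' power law; the slope magnitude is the fractal dimension.
#'
#' @param object A `fractal_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fractal_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$box_size, y = .data$count)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_fit)) +
    ggplot2::geom_smooth(data = df[df$in_fit, ], method = "lm",
                         formula = y ~ x, se = FALSE, linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "box size x (um)", y = "occupied boxes N(x)",
                  title = sprintf("D_f = %.3f (r2 = %.3f)",
                                  object$d_f, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot segment size distributions
#'
#' Log-log frequency distributions of segment diameters and lengths,
#' absolute (`N`) or relative (`P`), one line per group.
#'
#' @param dist Output of [segment_distributions()].
#' @param which `"N"` (absolute) or `"P"` (relative).
#' @return A ggplot.
#' @export
plot_distributions <- function(dist, which = c("N", "P")) {
  which <- match.arg(which)
  y <- if (which == "N") "n_mean" else "p_mean"
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin_low + 0.5 * (.data$bin_high - .data$bin_low),
                                     y = .data[[y]], colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "bin midpoint (um)",
                  y = if (which == "N") "segments per bin" else "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot per-order profiles
#'
#' Mean segment diameter (with SD error bars), mean length, segment count
#' and resistance against the diameter-defined Strahler order.
#'
#' @param stats Output of [resistance_per_order()] (or [order_statistics()],
#'   in which case the resistance panel is omitted).
#' @return A ggplot.
#' @export
plot_order_profile <- function(stats) {
  long <- stats |>
    tidyr::pivot_longer(dplyr::any_of(c("diameter_mean", "length_mean",
                                        "n_count", "resistance")),
                        names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$order, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "DDSO", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a metrics report
#'
#' @param object A `vascular_metrics` report.
#' @param ... Unused.
#' @return A ggplot (per-order profile with the global summary as title).
#' @export
autoplot.vascular_metrics <- function(object, ...) {
  plot_order_profile(object$per_order) +
    ggplot2::ggtitle(sprintf("l = %.3g um, V = %.3g um^3, D_f = %.2f",
                             object$global$l_total, object$global$v_total,
                             object$global$d_f))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
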