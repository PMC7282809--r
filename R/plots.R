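#' Plot an anchor-centred meta-profile
#'
#' Calibrated occupancy against offset from the CDEIII/centromere anchor,
#' in kilobases.
#'
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset / 1e3,
                                   y = .data$mean_depth)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Offset from CDEIII anchor (kb)",
                  y = "Calibrated occupancy (reads/bp, per 1M reads x OR)") +
    ggplot2::theme_minimal()
}

#' Plot a competition fitness regression
#'
#' The `(cumulative generations, log ratio)` points with the fitted
#' least-squares line whose slope is the relative fitness.
#'
#' @param object A `fitness_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fitness_fit
#' @export
autoplot.fitness_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$g_cum, y = .data$log_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = coef(object$model)[1],
                         slope = coef(object$model)[2],
                         colour = "#d95f02") +
    ggplot2::labs(x = "Cumulative generations",
                  y = expression(log[e] ~ "(nonfluorescent / fluorescent)"),
                  subtitle = sprintf("relative fitness = %.4f (SE %.4f)",
                                     object$slope, object$stderr)) +
    ggplot2::theme_minimal()
}

#' Plot precocious-separation percentages
#'
#' Percentage of two-dot metaphase cells per strain with 95% Wilson
#' intervals.
#'
#' @param object A `separation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot separation_result
#' @export
autoplot.separation_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain,
                                   y = .data$percent_two_dot)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Cells with two GFP dots (%)") +
    ggplot2::theme_minimal()
}
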