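#' Plot a windowed G+C profile
#'
#' Window G+C along the replicon with the whole-genome value as a dashed
#' reference line.
#'
#' @param object A `gc_profile` from [windowed_gc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gc_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$window_start / 1000, y = 100 * .data$gc)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 100 * attr(object, "whole_genome_gc"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Position (kb)", y = "G+C (mol%)",
                  title = attr(object, "genome_id"),
                  subtitle = sprintf("%d-bp windows; genome-wide %.1f mol%%",
                                     attr(object, "window"),
                                     100 * attr(object, "whole_genome_gc"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one metric against optimum growth temperature
#'
#' Scatter of species with the fitted OLS line, off-line species labelled,
#' and any supplied literature line dashed.
#'
#' @param comparison A `thermal_comparison` from [compare_profiles()].
#' @param metric Metric name to plot.
#' @param literature Optional [literature_model()] to overlay.
#' @return A ggplot.
#' @export
plot_ogt_fit <- function(comparison, metric, literature = NULL) {
  stopifnot(inherits(comparison, "thermal_comparison"))
  res <- filter(comparison$residuals, .data$metric == !!metric)
  fit <- comparison$fits[[metric]]
  if (is.null(fit)) abort(paste0("metric not in comparison: ", metric))
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$ogt_observed, y = .data$value)) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$off_line)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::geom_text(data = filter(res, .data$off_line),
                       ggplot2::aes(label = .data$genome_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Optimum growth temperature (°C)", y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(literature))
    p <- p + ggplot2::geom_abline(slope = literature$slope,
                                  intercept = literature$intercept,
                                  linetype = "dashed", colour = "grey50")
  p
}

#' @export
autoplot.thermal_comparison <- function(object, ...) {
  metrics <- names(object$fits)
  long <- object$residuals
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ogt_observed, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$off_line), size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Optimum growth temperature (°C)", y = NULL) +
    ggplot2::theme_minimal()
}
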