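# ggplot2 displays for paired onsets, cumulative frequencies and fits.

#' Observed vs predicted onset scatter
#'
#' Scatter of predicted against observed onset day-of-year with the 1:1
#' line (solid) and the least-squares regression line (dashed).
#'
#' @param pairs Paired tibble from [pair_bgs()].
#' @return A ggplot object.
#' @export
plot_bgs_scatter <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$observed,
                                      y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey30") +
    ggplot2::labs(x = "Observed BGS (DOY)", y = "Predicted BGS (DOY)") +
    ggplot2::theme_minimal()
}

#' Cumulative frequency curve of absolute onset differences
#'
#' @param cumfreq Tibble from [cumulative_within()], optionally with extra
#'   grouping columns (e.g. `model`) mapped to colour.
#' @param colour Optional name of a grouping column.
#' @return A ggplot object.
#' @export
plot_cumulative_frequency <- function(cumfreq, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$threshold, y = .data$pct)
  } else {
    ggplot2::aes(x = .data$threshold, y = .data$pct,
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(cumfreq, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Absolute difference threshold (days)",
                  y = "Pixels within threshold (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @describeIn calibrate_model Refinement trace (best SSE per sweep).
#' @param object A `pheno_fit`.
#' @param ... Unused.
#' @method autoplot pheno_fit
#' @export
autoplot.pheno_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$sweep, y = .data$sse)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Refinement sweep", y = "Best SSE (days²)",
                  title = paste("Calibration trace:", object$model)) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_model Observed-vs-predicted scatter of the
#'   evaluation pairs.
#' @param object A `pheno_eval`.
#' @param ... Unused.
#' @method autoplot pheno_eval
#' @export
autoplot.pheno_eval <- function(object, ...) {
  plot_bgs_scatter(object$pairs)
}
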