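#' Plot daily window durations against a threshold model
#'
#' One point per day, coloured by classification, with the learned
#' normal range and mean drawn as horizontal lines — the standard
#' at-a-glance view of a resident's routine over a trial period.
#'
#' @param results classified window tibble ([classify_windows()]).
#' @return A ggplot object.
#' @export
plot_window_durations <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$date, y = .data$duration_minutes,
                               colour = .data$label)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$mu),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "duration (min)", colour = NULL,
                  title = unique(results$activity)[1]) +
    ggplot2::theme_minimal()
}

#' Histogram of fitting durations with the fitted normal range
#'
#' @param object a `threshold_model`.
#' @param history optional window-feature tibble the model was fit on;
#'   when supplied its durations are drawn as a histogram behind the
#'   range.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.threshold_model <- function(object, history = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(history)) {
    p <- p + ggplot2::geom_histogram(
      data = history,
      ggplot2::aes(x = .data$duration_minutes),
      bins = 30, fill = "grey70", colour = "white")
  }
  p +
    ggplot2::geom_vline(xintercept = c(object$lower, object$upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$mu,
                        linetype = "dotted", colour = "grey30") +
    ggplot2::labs(
      x = "duration (min)", y = "days",
      title = sprintf("%s: normal range [%.1f, %.1f] min (k = %g)",
                      object$activity %||% "activity",
                      object$lower, object$upper, object$k)) +
    ggplot2::theme_minimal()
}
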