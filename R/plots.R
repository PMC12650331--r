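#' Plot ROC curves of a classifier evaluation
#'
#' One curve per reported class (one-vs-rest), with the chance diagonal.
#'
#' @param object A `cie_eval` from [train_and_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cie_eval
#' @export
autoplot.cie_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = paste0(object$family, " (accuracy ",
                                 sprintf("%.2f", object$accuracy), ")")) +
    ggplot2::theme_minimal()
}

#' Plot windowed alarms in the pre-event plane
#'
#' Scatter of alarm value against time before the event, faceted by
#' signal, with segment boundaries marked — the temporal-distribution
#' view of the 8 h pre-event window.
#'
#' @param windowed Windowed episodes from [window_alarms()].
#' @param window_hours,n_segments Window geometry, for the boundary lines.
#' @return A ggplot object.
#' @export
plot_alarm_window <- function(windowed, window_hours = 8, n_segments = 4) {
  edges <- seq(0, window_hours, length.out = n_segments + 1)
  ggplot2::ggplot(windowed,
                  ggplot2::aes(x = -.data$lead_time_s / 3600,
                               y = .data$rep_value, colour = .data$bound)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = -edges, linetype = 3,
                        colour = "grey50") +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "Hours before event", y = "Alarm value") +
    ggplot2::theme_minimal()
}

#' Plot alarm-pattern clusters in the value-duration plane
#'
#' The plane in which patterns are clustered: representative alarm value
#' against episode duration, faceted by signal and bound, coloured by CIE
#' status.
#'
#' @param windowed Windowed episodes from [window_alarms()] (with
#'   `cie_type`).
#' @return A ggplot object.
#' @export
plot_pattern_plane <- function(windowed) {
  ggplot2::ggplot(windowed,
                  ggplot2::aes(x = .data$rep_value, y = .data$duration_s,
                               colour = .data$cie_type)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_grid(bound ~ signal, scales = "free_x") +
    ggplot2::labs(x = "Alarm value", y = "Duration (s)") +
    ggplot2::theme_minimal()
}
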