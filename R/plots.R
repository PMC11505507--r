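#' Plot a gait recording
#'
#' A faceted channel view with activity segments shaded; by default one
#' channel per sensor group to keep the panel readable.
#'
#' @param object a `gait_recording`.
#' @param channels channel names to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gait_recording <- function(object,
                                    channels = c("acc1_x", "gyro1_x",
                                                 "cf1_pitch", "ma1"),
                                    ...) {
  fs <- sampling_rate(object)
  eps <- episodes_from_labels(object$label)
  long <- object |>
    dplyr::select(dplyr::all_of(c("t", channels))) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "value") |>
    dplyr::mutate(time_s = .data$t / fs)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value))
  if (nrow(eps) > 0)
    p <- p + ggplot2::geom_rect(
      data = dplyr::mutate(eps, start_s = .data$start / fs,
                           end_s = .data$end / fs),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15)
  p +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = "Synthetic gait recording (FoG episodes shaded)") +
    ggplot2::theme_minimal()
}

#' Plot a detection trace
#'
#' Model score with the detection threshold, plus the cue countdown state.
#'
#' @param object a `detection_trace`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.detection_trace <- function(object, ...) {
  fs <- attr(object, "sampling_rate_hz")
  if (is.null(fs)) fs <- 40
  thr <- attr(object, "threshold")
  long <- object |>
    dplyr::mutate(time_s = .data$t / fs) |>
    dplyr::select(dplyr::all_of(c("time_s", "score", "fog_condition"))) |>
    tidyr::pivot_longer(-"time_s", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(
      data = tibble::tibble(series = "score", value = thr),
      ggplot2::aes(yintercept = .data$value),
      linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = "Streaming FoG detection trace") +
    ggplot2::theme_minimal()
}

#' Plot the training loss history
#'
#' @param model a trained `fog_model`.
#' @return a ggplot object.
#' @export
plot_training_history <- function(model) {
  hist <- tidy(model)
  ggplot2::ggplot(hist, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean training loss",
                  title = "FoG classifier training history") +
    ggplot2::theme_minimal()
}
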