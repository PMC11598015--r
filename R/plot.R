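# ggplot2 visualizations of trajectories, dispersion and waveforms.

#' Plot an I/Q trajectory
#'
#' Draws the fitted CSI-ratio trajectory on the I/Q plane, colored by time,
#' with observed sample points underneath.
#'
#' @param object A `fitted_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fitted_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = Re(.data$fitted),
                                        y = Im(.data$fitted),
                                        color = .data$time))
  if ("observed" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(x = Re(.data$observed), y = Im(.data$observed)),
      color = "grey80", size = 0.4)
  }
  p +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "In-phase (I)", y = "Quadrature (Q)",
                  color = "time (s)",
                  title = "CSI-ratio trajectory on the I/Q plane") +
    ggplot2::theme_minimal()
}

#' Plot a breathing result
#'
#' Shows the reconstructed arc-length waveform with detected breath
#' transitions marked.
#'
#' @param object A `breath_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breath_result <- function(object, ...) {
  wav <- object$waveform
  ggplot2::ggplot(wav, ggplot2::aes(x = .data$time, y = .data$S,
                                    group = .data$segment)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(data = object$transitions,
                        ggplot2::aes(xintercept = .data$time),
                        linetype = "dashed", color = "firebrick",
                        alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "signed arc length S",
                  title = sprintf("Breathing waveform (%.1f breaths/min)",
                                  object$rate_bpm)) +
    ggplot2::theme_minimal()
}

#' Plot windowed dispersion with the motion threshold
#'
#' @param dispersion Output of [window_dispersion()].
#' @param threshold Threshold to mark (default 0.001).
#' @return A ggplot.
#' @export
plot_dispersion <- function(dispersion, threshold = 0.001) {
  ggplot2::ggplot(dispersion,
                  ggplot2::aes(x = .data$window_start, y = .data$D)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window start (s)", y = "dispersion D (log scale)",
                  title = "CSI-ratio dispersion vs. motion threshold") +
    ggplot2::theme_minimal()
}
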