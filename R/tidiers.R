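# broom-style tidiers for fitted objects.

#' Tidy a fitted trajectory
#'
#' One row per basis coefficient: segment, channel (re/im), basis index and
#' estimate.
#'
#' @param x A `fitted_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fitted_trajectory <- function(x, ...) {
  segs <- attr(x, "segments")
  purrr::map_dfr(segs, function(s) {
    tibble::tibble(
      segment = s$segment,
      channel = rep(c("re", "im"), each = s$p),
      basis = rep(seq_len(s$p), 2L),
      estimate = c(s$beta_re, s$beta_im)
    )
  })
}

#' Glance at a fitted trajectory
#'
#' One row per segment: window, basis order and width, sample count,
#' residual RMS.
#'
#' @inheritParams tidy.fitted_trajectory
#' @return A tibble.
#' @export
glance.fitted_trajectory <- function(x, ...) {
  purrr::map_dfr(attr(x, "segments"), function(sg) {
    tibble::tibble(
      segment = sg$segment, t_start = sg$window[1], t_end = sg$window[2],
      p = sg$p, s = sg$s, n = sg$n, residual_rms = sg$residual_rms
    )
  })
}

#' Tidy a breathing result
#'
#' Returns the detected breath transitions (time, segment, turning angle).
#'
#' @param x A `breath_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.breath_result <- function(x, ...) {
  tibble::as_tibble(x$transitions)
}

#' Glance at a breathing result
#'
#' One-row summary: breathing rate, transition and segment counts, waveform
#' span, and the metrics columns when ground truth was scored.
#'
#' @inheritParams tidy.breath_result
#' @return A one-row tibble.
#' @export
glance.breath_result <- function(x, ...) {
  out <- tibble::tibble(
    rate_bpm = x$rate_bpm,
    n_transitions = nrow(x$transitions),
    n_segments = length(unique(x$waveform$segment)),
    duration_s = diff(range(x$waveform$time)),
    n_intervals = nrow(x$intervals)
  )
  if (!is.null(x$metrics)) {
    out <- dplyr::bind_cols(out, dplyr::select(x$metrics, "acc", "mae",
                                               "aer"))
  }
  out
}
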