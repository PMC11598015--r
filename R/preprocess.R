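# Static-path estimation/removal and the two-link CSI ratio.

#' Estimate the static path component of each CSI stream
#'
#' The static component (line-of-sight plus fixed reflectors) is constant in
#' time, so averaging CSI samples over a window leaves the static vector
#' while the zero-mean dynamic contribution averages out. Two modes are
#' offered: `"prefix"` averages a calibration window at the start of the
#' recording and returns one complex estimate per stream; `"rolling"`
#' returns a per-sample moving average (edges use shrunken windows, so the
#' output has the input length).
#'
#' @param csi CSI tibble (`time`, `tx`, `rx`, `subcarrier`, `freq_hz`,
#'   `csi`).
#' @param window_s Averaging window in seconds (default 10 s).
#' @param mode `"prefix"` or `"rolling"`.
#' @return For `"prefix"`: a tibble with one row per stream and a complex
#'   `static` column. For `"rolling"`: the input tibble with a per-row
#'   `static` column appended.
#' @export
estimate_static <- function(csi, window_s = 10,
                            mode = c("prefix", "rolling")) {
  mode <- match.arg(mode)
  if (window_s <= 0) abort("`window_s` must be positive.")
  if (mode == "prefix") {
    out <- csi |>
      dplyr::group_by(.data$tx, .data$rx, .data$subcarrier) |>
      dplyr::summarise(
        static = {
          in_win <- .data$time <= .data$time[1] + window_s
          if (sum(in_win) < 2L) {
            abort("Static calibration window must cover at least 2 samples.")
          }
          mean(.data$csi[in_win])
        },
        .groups = "drop"
      )
    out
  } else {
    csi |>
      dplyr::group_by(.data$tx, .data$rx, .data$subcarrier) |>
      dplyr::mutate(static = rolling_mean_complex(.data$csi, .data$time,
                                                  window_s)) |>
      dplyr::ungroup()
  }
}

# Centered moving average over a time window; edge windows shrink.
rolling_mean_complex <- function(x, t, window_s) {
  n <- length(x)
  if (n < 2L) abort("Static estimation needs at least 2 samples.")
  half <- window_s / 2
  cs <- c(0 + 0i, cumsum(x))
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove the static component from a CSI table
#'
#' Subtracts the static estimate elementwise, leaving the dynamic (moving
#' reflector) component. Accepts either output form of [estimate_static()].
#'
#' @param csi CSI tibble.
#' @param static Per-stream static tibble (prefix mode) or a rolling-mode
#'   tibble carrying a `static` column aligned with `csi`.
#' @return The CSI tibble with `csi` replaced by `csi - static`.
#' @export
remove_static <- function(csi, static) {
  if (nrow(static) == nrow(csi) && "static" %in% names(static) &&
      "time" %in% names(static)) {
    csi$csi <- csi$csi - static$static
    return(csi)
  }
  joined <- dplyr::left_join(csi, static,
                             by = c("tx", "rx", "subcarrier"))
  if (anyNA(joined$static)) {
    abort("No static estimate available for some (tx, rx, subcarrier) stream.")
  }
  joined$csi <- joined$csi - joined$static
  dplyr::select(joined, -"static")
}

#' Two-link CSI ratio
#'
#' Divides the CSI of one receive chain by that of another, per subcarrier,
#' on a shared uniform time grid. Because carrier frequency offset and packet
#' detection delay enter all receive chains of one device as a common
#' multiplicative phase, they cancel exactly in this ratio; what remains is
#' the relative amplitude and phase of the two links' channels, whose I/Q
#' trajectory tracks the breathing motion. Samples where the denominator
#' magnitude falls below `amp_floor_factor` times its median are marked
#' invalid (`valid = FALSE`) and are excluded downstream.
#'
#' @param csi CSI tibble on a uniform grid (see [interpolate_csi()]).
#' @param numerator,denominator Length-2 vectors `c(tx, rx)` naming the two
#'   links; they must differ.
#' @param amp_floor_factor Fraction of the median denominator magnitude
#'   below which samples are invalidated.
#' @return A ratio tibble: `time`, `subcarrier`, `freq_hz`, `ratio`
#'   (complex), `valid`, plus the link indices (`num_tx`, `num_rx`,
#'   `den_tx`, `den_rx`).
#' @export
csi_ratio <- function(csi, numerator = c(1, 1), denominator = c(1, 2),
                      amp_floor_factor = 1e-3) {
  if (all(numerator == denominator)) {
    abort("Numerator and denominator links must differ.")
  }
  num <- dplyr::filter(csi, .data$tx == numerator[1], .data$rx == numerator[2])
  den <- dplyr::filter(csi, .data$tx == denominator[1],
                       .data$rx == denominator[2])
  if (nrow(num) == 0L || nrow(den) == 0L) {
    abort("Requested links are absent from the CSI table.")
  }
  num <- dplyr::arrange(num, .data$subcarrier, .data$time)
  den <- dplyr::arrange(den, .data$subcarrier, .data$time)
  if (nrow(num) != nrow(den) ||
      any(abs(num$time - den$time) > 1e-9) ||
      any(num$subcarrier != den$subcarrier)) {
    abort("Numerator and denominator streams must share the same time grid and subcarriers.")
  }
  floor_amp <- amp_floor_factor * median(Mod(den$csi))
  tibble::tibble(
    time = num$time, subcarrier = num$subcarrier, freq_hz = num$freq_hz,
    ratio = num$csi / den$csi,
    valid = Mod(den$csi) >= floor_amp,
    num_tx = numerator[1], num_rx = numerator[2],
    den_tx = denominator[1], den_rx = denominator[2]
  )
}
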