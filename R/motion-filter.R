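# Dispersion-based rejection of gross-motion samples.

#' Windowed dispersion of CSI-ratio sample points
#'
#' For each sliding window, computes the dispersion statistic
#' \deqn{D = \sum_{\mathrm{pairs}} \frac{1}{N_f} \sum_{m=1}^{N_f}
#'       \frac{1}{W-1} \sum_{r=1}^{W} |Q(f_m, t_{n+r}) - \bar Q(f_m, t_n)|^2}
#' where the outer sum runs over the admitted ordered pairs of distinct
#' links present in `ratio`, the middle mean runs over subcarriers, and
#' \eqn{\bar Q} is the within-window sample mean. Quiet breathing moves the
#' ratio slowly, giving small D; gross body motion scatters the sample
#' points across the I/Q plane, inflating D by orders of magnitude.
#'
#' @param ratio Ratio tibble from [csi_ratio()]; multiple link pairs may be
#'   stacked (rows distinguished by `num_tx`/`num_rx`/`den_tx`/`den_rx`).
#'   All series must share one uniform time grid.
#' @param window_s Window length in seconds (default 1 s).
#' @param stride_s Window stride in seconds (default `window_s / 2`,
#'    50% overlap).
#' @return Tibble with `window_start`, `window_end`, `n` (samples per
#'   window) and `D`.
#' @export
window_dispersion <- function(ratio, window_s = 1, stride_s = window_s / 2) {
  times <- sort(unique(ratio$time))
  if (!is_uniform_grid(times)) {
    abort("Dispersion requires ratio series on a single uniform grid.")
  }
  dt <- if (length(times) > 1L) times[2] - times[1] else window_s
  if (window_s / dt < 2) {
    abort("Dispersion window must cover at least 2 samples (W >= 2).")
  }
  t0 <- times[1]
  t_end <- times[length(times)]
  last_start <- t_end - window_s + dt / 2
  starts <- if (last_start <= t0) t0 else seq(t0, last_start, by = stride_s)

  pairs <- dplyr::distinct(ratio, .data$num_tx, .data$num_rx,
                           .data$den_tx, .data$den_rx)
  D <- numeric(length(starts))
  n_win <- integer(length(starts))
  for (w in seq_along(starts)) {
    lo <- starts[w]; hi <- starts[w] + window_s
    win <- ratio[ratio$time >= lo & ratio$time < hi & ratio$valid, ]
    n_win[w] <- length(unique(win$time))
    d_pairs <- 0
    for (p in seq_len(nrow(pairs))) {
      wp <- win[win$num_tx == pairs$num_tx[p] & win$num_rx == pairs$num_rx[p] &
                  win$den_tx == pairs$den_tx[p] & win$den_rx == pairs$den_rx[p], ]
      if (nrow(wp) == 0L) next
      per_sub <- vapply(split(wp$ratio, wp$subcarrier), function(q) {
        if (length(q) < 2L) return(NA_real_)
        sum(Mod(q - mean(q))^2) / (length(q) - 1)
      }, numeric(1))
      per_sub <- per_sub[!is.na(per_sub)]
      if (length(per_sub)) d_pairs <- d_pairs + mean(per_sub)
    }
    D[w] <- d_pairs
  }
  tibble::tibble(window_start = starts, window_end = starts + window_s,
                 n = n_win, D = D)
}

#' Label motion-contaminated samples by thresholding dispersion
#'
#' Flags every sample covered by any window whose dispersion exceeds the
#' threshold (0.001 by default, the fixed reference level for quiet
#' breathing). With overlapping windows this is the conservative choice:
#' motion contamination spreads through any fit that uses the sample.
#' Flagged samples are excluded from trajectory fitting and breathing
#' extraction rather than repaired.
#'
#' @param ratio Ratio tibble (see [csi_ratio()]).
#' @param dispersion Output of [window_dispersion()].
#' @param threshold Dispersion threshold (default 0.001).
#' @return The ratio tibble with logical columns `motion` (inside an
#'   over-threshold window) and `clean` (`valid & !motion`).
#' @export
label_interference <- function(ratio, dispersion, threshold = 0.001) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  bad <- dispersion[dispersion$D > threshold, , drop = FALSE]
  motion <- rep(FALSE, nrow(ratio))
  for (w in seq_len(nrow(bad))) {
    motion <- motion |
      (ratio$time >= bad$window_start[w] & ratio$time < bad$window_end[w])
  }
  ratio$motion <- motion
  ratio$clean <- ratio$valid & !motion
  ratio
}
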