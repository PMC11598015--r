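# Synthetic CSI generation with known breathing ground truth.

# Closed-form chest displacement: one cycle = trough pause, half-cosine
# inhale ramp, peak pause, half-cosine exhale ramp. Units: meters.
displacement_fun <- function(cfg) {
  period <- 60 / cfg$breathing_rate_bpm
  p_ei <- cfg$pause_exhale_to_inhale
  p_ie <- cfg$pause_inhale_to_exhale
  ramp <- (period - p_ei - p_ie) / 2
  a <- cfg$chest_amplitude
  function(t) {
    u <- t %% period
    d <- numeric(length(u))
    inhale <- u >= p_ei & u < p_ei + ramp
    peak <- u >= p_ei + ramp & u < p_ei + ramp + p_ie
    exhale <- u >= p_ei + ramp + p_ie
    d[inhale] <- a * (1 - cos(pi * (u[inhale] - p_ei) / ramp)) / 2
    d[peak] <- a
    d[exhale] <- a * (1 + cos(pi * (u[exhale] - p_ei - ramp - p_ie) / ramp)) / 2
    d
  }
}

# Transition times = centers of the pauses (the instants of direction
# reversal): two per cycle, trough first.
transition_times_for <- function(cfg) {
  period <- 60 / cfg$breathing_rate_bpm
  ramp <- (period - cfg$pause_exhale_to_inhale - cfg$pause_inhale_to_exhale) / 2
  trough <- cfg$pause_exhale_to_inhale / 2
  peak <- cfg$pause_exhale_to_inhale + ramp + cfg$pause_inhale_to_exhale / 2
  n_cyc <- ceiling(cfg$duration / period) + 1L
  tt <- sort(c(trough + period * (0:n_cyc), peak + period * (0:n_cyc)))
  tt[tt < cfg$duration]
}

#' Simulate chest displacement with ground truth
#'
#' Samples the breathing displacement model at the (optionally jittered)
#' timestamps and returns the ground truth carrier used by the parameter
#' recovery tests and the metrics: displacement d(t), the breath transition
#' times (centers of the trough and peak pauses), the true rate, and a
#' per-sample motion mask.
#'
#' @param config A [sim_config()].
#' @param times Optional sampling times (seconds). When `NULL`, a jittered
#'   uniform grid is drawn from the configured seed.
#' @return A list of class `breath_truth` with elements `displacement`
#'   (tibble: `time`, `displacement`, `motion`), `transition_times`,
#'   `rate_bpm`, `n_cycles`, `motion_bursts`, and `seed`.
#' @export
simulate_displacement <- function(config, times = NULL) {
  validate_sim_config(config)
  if (is.null(times)) {
    times <- withr::with_seed(config$seed, sample_times(config))
  }
  d <- displacement_fun(config)(times)
  motion <- motion_mask_for(config, times)
  structure(list(
    displacement = tibble::tibble(time = times, displacement = d,
                                  motion = motion),
    transition_times = transition_times_for(config),
    rate_bpm = config$breathing_rate_bpm,
    n_cycles = floor(config$breathing_rate_bpm * config$duration / 60),
    motion_bursts = config$motion_bursts,
    seed = config$seed
  ), class = "breath_truth")
}

sample_times <- function(cfg) {
  n <- floor(cfg$duration * cfg$nominal_rate_hz)
  grid <- (seq_len(n) - 1) / cfg$nominal_rate_hz
  enforce_increasing(grid + rnorm(n) * cfg$timestamp_jitter_sd)
}

motion_mask_for <- function(cfg, times) {
  motion <- rep(FALSE, length(times))
  if (!is.null(cfg$motion_bursts)) {
    for (b in seq_len(nrow(cfg$motion_bursts))) {
      motion <- motion |
        (times >= cfg$motion_bursts$start[b] & times < cfg$motion_bursts$end[b])
    }
  }
  motion
}

#' Simulate multi-antenna CSI streams for a breathing scene
#'
#' Generates time-stamped complex CSI per (transmit antenna, receive antenna,
#' subcarrier) link following the static-plus-dynamic channel model: each
#' sample is \eqn{H = (H_s + A e^{-j 2\pi d(t)/\lambda} + n) e^{-j\psi(t)}},
#' where d(t) is the breathing displacement (plus an extra random walk during
#' motion bursts), n is complex Gaussian receiver noise, and \eqn{\psi(t)} is
#' the random-walk phase shared by all links at the same instant (the
#' carrier-frequency-offset / packet-detection-delay term). Because
#' \eqn{\psi(t)} multiplies the whole measured channel, the two-link ratio is
#' algebraically invariant to it, which is the property the downstream ratio
#' stage relies on.
#'
#' Motion bursts multiply the dynamic gain by the burst amplitude and add an
#' independent random-walk displacement over the burst window.
#'
#' @inheritParams simulate_displacement
#' @return A list of class `csi_sim`: `csi` (tibble with columns `time`,
#'   `tx`, `rx`, `subcarrier`, `freq_hz`, `csi` (complex)) and `truth`
#'   (a `breath_truth`).
#' @export
#' @examples
#' sim <- simulate_csi(sim_config(duration = 20, seed = 3))
#' dplyr::count(sim$csi, tx, rx, subcarrier)
simulate_csi <- function(config) {
  validate_sim_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    times <- sample_times(cfg)
    n <- length(times)
    # Extra displacement during motion bursts (shared across links).
    motion <- motion_mask_for(cfg, times)
    d_motion <- numeric(n)
    amp_mult <- rep(1, n)
    if (!is.null(cfg$motion_bursts)) {
      for (b in seq_len(nrow(cfg$motion_bursts))) {
        idx <- which(times >= cfg$motion_bursts$start[b] &
                       times < cfg$motion_bursts$end[b])
        d_motion[idx] <- d_motion[idx] +
          cumsum(rnorm(length(idx))) * cfg$motion_walk_sd
        amp_mult[idx] <- amp_mult[idx] * cfg$motion_bursts$amplitude[b]
      }
    }
    # Shared CFO/PDD phase: random walk, identical across all links. The
    # steps are always drawn (then scaled) so that runs differing only in
    # `phase_noise_sd` share every other random draw.
    psi <- cumsum(rnorm(n)) * cfg$phase_noise_sd

    d_breath <- displacement_fun(cfg)(times)
    d_total <- d_breath + d_motion

    links <- expand.grid(rx = seq_len(cfg$n_rx), tx = seq_len(cfg$n_tx))
    links <- links[order(links$tx, links$rx), , drop = FALSE]
    n_link <- nrow(links)
    statics <- rep_len(cfg$static_component_per_link, n_link)
    gains <- rep_len(cfg$dynamic_gain_per_link, n_link)
    offsets <- rep_len(cfg$path_offset_per_link, n_link)

    f_c <- 299792458 / cfg$wavelength
    sub_idx <- seq_len(cfg$n_subcarriers)
    freqs <- f_c + (sub_idx - (cfg$n_subcarriers + 1) / 2) * 312.5e3
    tau_static <- 20e-9  # small static delay, rotates Hs across subcarriers

    out <- vector("list", n_link * cfg$n_subcarriers)
    k <- 0L
    for (li in seq_len(n_link)) {
      for (m in sub_idx) {
        noise <- (rnorm(n) + 1i * rnorm(n)) * cfg$noise_sd
        hs <- statics[li] * exp(-2i * pi * (freqs[m] - f_c) * tau_static)
        phase <- -2 * pi * freqs[m] * (d_total + offsets[li]) / 299792458
        hd <- gains[li] * amp_mult * exp(1i * phase)
        h <- (hs + hd + noise) * exp(-1i * psi)
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          time = times, tx = links$tx[li], rx = links$rx[li],
          subcarrier = m, freq_hz = freqs[m], csi = h
        )
      }
    }
    csi <- dplyr::bind_rows(out)

    truth <- structure(list(
      displacement = tibble::tibble(time = times, displacement = d_breath,
                                    motion = motion),
      transition_times = transition_times_for(cfg),
      rate_bpm = cfg$breathing_rate_bpm,
      n_cycles = floor(cfg$breathing_rate_bpm * cfg$duration / 60),
      motion_bursts = cfg$motion_bursts,
      seed = cfg$seed
    ), class = "breath_truth")

    structure(list(csi = csi, truth = truth, config = cfg),
              class = "csi_sim")
  })
}

#' @export
print.csi_sim <- function(x, ...) {
  cat("<csi_sim>", nrow(x$csi), "samples,",
      x$config$n_tx, "tx x", x$config$n_rx, "rx x",
      x$config$n_subcarriers, "subcarriers,",
      x$config$duration, "s at", x$config$nominal_rate_hz, "Hz nominal\n")
  cat("  true rate:", x$truth$rate_bpm, "bpm;",
      length(x$truth$transition_times), "breath transitions\n")
  invisible(x)
}

#' @export
print.breath_truth <- function(x, ...) {
  cat("<breath_truth>", x$rate_bpm, "bpm,", x$n_cycles, "full cycles,",
      length(x$transition_times), "transitions\n")
  invisible(x)
}
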