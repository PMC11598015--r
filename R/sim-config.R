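#' Configuration for the synthetic CSI generator
#'
#' Builds a validated configuration describing one simulated breathing
#' recording. The generator emulates the standard two-component channel model
#' for respiration sensing: a constant static path vector per link plus a
#' dynamic path reflected off the chest whose length follows quasi-sinusoidal
#' chest displacement with short pauses at the breath transitions (the
#' exhale-to-inhale pause being slightly longer than the inhale-to-exhale
#' one), a shared random-walk phase common to all receive chains (carrier
#' frequency offset and packet detection delay), additive complex Gaussian
#' receiver noise, non-uniform sampling timestamps, and optional large-motion
#' bursts.
#'
#' @param duration Recording length in seconds.
#' @param nominal_rate_hz Nominal CSI sampling rate (samples per second).
#' @param timestamp_jitter_sd Standard deviation (seconds) of the Gaussian
#'   perturbation applied to the uniform sampling grid; perturbed timestamps
#'   are sorted and made strictly increasing.
#' @param breathing_rate_bpm True breathing rate in breaths per minute.
#' @param chest_amplitude Peak-to-peak chest displacement in meters.
#' @param pause_exhale_to_inhale,pause_inhale_to_exhale Durations (seconds)
#'   of the flat pauses at the trough (exhale to inhale) and peak (inhale to
#'   exhale) of the displacement cycle. The trough pause must be the longer
#'   of the two.
#' @param wavelength Carrier wavelength in meters (default 0.0579 m,
#'   mid-channel of the 5.18 GHz band).
#' @param static_component_per_link Complex static path vector per link,
#'   recycled across links (ordered by transmit then receive antenna).
#' @param dynamic_gain_per_link Positive real dynamic path gain per link.
#' @param path_offset_per_link Constant extra path length (meters) per link.
#'   The default (~2/3 of a wavelength between the two receive chains)
#'   places the links' dynamic components near-antiphase in the ratio, the
#'   geometry in which the I/Q trajectory is most sensitive to breathing —
#'   the regime a practitioner arranges by antenna placement.
#' @param noise_sd Standard deviation of the additive receiver noise, per
#'   quadrature component.
#' @param phase_noise_sd Per-sample step standard deviation (radians) of the
#'   shared random-walk phase applied identically to all links at the same
#'   instant.
#' @param motion_bursts Data frame with columns `start`, `end`, `amplitude`
#'   (seconds, seconds, unitless multiplier) describing large-motion windows,
#'   or `NULL` for none.
#' @param motion_walk_sd Per-sample step standard deviation (meters) of the
#'   extra random-walk displacement added during motion bursts.
#' @param n_tx,n_rx Number of transmit and receive antennas (`n_rx >= 2`,
#'   since the ratio needs two receive chains).
#' @param n_subcarriers Number of OFDM subcarriers to emit.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_csi()], [simulate_displacement()]
#' @export
#' @examples
#' cfg <- sim_config(duration = 30, breathing_rate_bpm = 15, seed = 7)
#' sim <- simulate_csi(cfg)
#' head(sim$csi)
sim_config <- function(duration = 120,
                       nominal_rate_hz = 20,
                       timestamp_jitter_sd = 0.010,
                       breathing_rate_bpm = 15,
                       chest_amplitude = 0.005,
                       pause_exhale_to_inhale = 0.5,
                       pause_inhale_to_exhale = 0.3,
                       wavelength = 0.0579,
                       static_component_per_link = c(0.95 * exp(0.6i),
                                                     1.05 * exp(-0.4i)),
                       dynamic_gain_per_link = c(0.050, 0.042),
                       path_offset_per_link = c(0, 0.0382),
                       noise_sd = 0.005,
                       phase_noise_sd = 0.02,
                       motion_bursts = NULL,
                       motion_walk_sd = 0.004,
                       n_tx = 1,
                       n_rx = 2,
                       n_subcarriers = 3,
                       seed = 1L) {
  cfg <- list(
    duration = duration, nominal_rate_hz = nominal_rate_hz,
    timestamp_jitter_sd = timestamp_jitter_sd,
    breathing_rate_bpm = breathing_rate_bpm,
    chest_amplitude = chest_amplitude,
    pause_exhale_to_inhale = pause_exhale_to_inhale,
    pause_inhale_to_exhale = pause_inhale_to_exhale,
    wavelength = wavelength,
    static_component_per_link = static_component_per_link,
    dynamic_gain_per_link = dynamic_gain_per_link,
    path_offset_per_link = path_offset_per_link,
    noise_sd = noise_sd, phase_noise_sd = phase_noise_sd,
    motion_bursts = motion_bursts, motion_walk_sd = motion_walk_sd,
    n_tx = as.integer(n_tx), n_rx = as.integer(n_rx),
    n_subcarriers = as.integer(n_subcarriers), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$duration) || cfg$duration <= 0) {
    abort("`duration` must be a positive number of seconds.")
  }
  if (cfg$nominal_rate_hz <= 0) abort("`nominal_rate_hz` must be positive.")
  if (cfg$breathing_rate_bpm <= 0) {
    abort("`breathing_rate_bpm` must be positive.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (cfg$chest_amplitude < 0) abort("`chest_amplitude` must be nonnegative.")
  if (cfg$n_rx < 2) {
    abort("`n_rx` must be at least 2: the CSI ratio needs two receive chains.")
  }
  if (cfg$pause_exhale_to_inhale <= cfg$pause_inhale_to_exhale) {
    abort(paste(
      "`pause_exhale_to_inhale` must exceed `pause_inhale_to_exhale`:",
      "the trough pause of the breathing cycle is the longer one."
    ))
  }
  period <- 60 / cfg$breathing_rate_bpm
  ramp <- (period - cfg$pause_exhale_to_inhale - cfg$pause_inhale_to_exhale) / 2
  if (ramp <= 0) {
    abort("Breathing period leaves no room for inhale/exhale ramps; reduce the pauses or the rate.")
  }
  if (!is.null(cfg$motion_bursts)) {
    mb <- cfg$motion_bursts
    if (!is.data.frame(mb) || !all(c("start", "end", "amplitude") %in% names(mb))) {
      abort("`motion_bursts` must be a data frame with columns start, end, amplitude.")
    }
    if (any(mb$end <= mb$start)) abort("Motion bursts must have end > start.")
  }
  invisible(cfg)
}

#' Scenario presets for the simulated experiments
#'
#' `scenario_orientation()` encodes three chest orientations (90, 60 and 30
#' degrees from vertical) as different dynamic-gain / static-vector settings:
#' the 60-degree orientation presents the largest chest reflection area
#' (largest dynamic gain), the 30-degree one is partially occluded (smallest).
#' `scenario_distance()` encodes three monitoring distances (1, 2, 3 m) by
#' scaling the dynamic gain by 1, 1/2, 1/3 and the receiver noise SD by
#' 1, 1.5, 2.
#'
#' @param angle One of 90, 60, 30 (degrees from vertical).
#' @param position One of 1, 2, 3 (meters of horizontal offset).
#' @param ... Passed on to [sim_config()] (e.g. `breathing_rate_bpm`, `seed`).
#' @return A `sim_config`.
#' @export
scenario_orientation <- function(angle = c(90, 60, 30), ...) {
  angle <- match.arg(as.character(angle[1]), c("90", "60", "30"))
  gain <- switch(angle,
    "90" = c(0.050, 0.042),
    "60" = c(0.058, 0.049),
    "30" = c(0.036, 0.030)
  )
  static <- switch(angle,
    "90" = c(0.95 * exp(0.6i), 1.05 * exp(-0.4i)),
    "60" = c(1.00 * exp(0.2i), 0.98 * exp(-0.7i)),
    "30" = c(0.90 * exp(1.1i), 1.10 * exp(0.3i))
  )
  sim_config(dynamic_gain_per_link = gain,
             static_component_per_link = static, ...)
}

#' @rdname scenario_orientation
#' @export
scenario_distance <- function(position = c(1, 2, 3), ...) {
  position <- match.arg(as.character(position[1]), c("1", "2", "3"))
  gain_scale <- c("1" = 1, "2" = 1 / 2, "3" = 1 / 3)[[position]]
  noise_scale <- c("1" = 1, "2" = 1.5, "3" = 2)[[position]]
  sim_config(dynamic_gain_per_link = c(0.050, 0.042) * gain_scale,
             noise_sd = 0.005 * noise_scale, ...)
}
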