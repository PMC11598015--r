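# Shared fixtures: small, fast configurations used across test files.

quick_cfg <- function(duration = 40, bpm = 15, seed = 1L, ...) {
  sim_config(duration = duration, breathing_rate_bpm = bpm, seed = seed, ...)
}

# A short noise-free, jitter-free, phase-noise-free configuration for exact
# algebraic checks.
exact_cfg <- function(duration = 20, bpm = 15, seed = 1L, ...) {
  sim_config(duration = duration, breathing_rate_bpm = bpm, seed = seed,
             noise_sd = 0, phase_noise_sd = 0, timestamp_jitter_sd = 0, ...)
}

# Ratio of two receive chains computed directly on raw simulator output
# (same subcarrier), bypassing the pipeline.
raw_ratio <- function(sim, sub = 1L) {
  a <- sim$csi[sim$csi$rx == 1 & sim$csi$subcarrier == sub, ]
  b <- sim$csi[sim$csi$rx == 2 & sim$csi$subcarrier == sub, ]
  a$csi / b$csi
}

# Brute-force dispersion oracle: naive loops straight from the definition
# (sum over link pairs, mean over subcarriers, (W-1)-normalized squared
# deviation from the window mean).
dispersion_oracle <- function(ratio, window_s, stride_s) {
  times <- sort(unique(ratio$time))
  dt <- times[2] - times[1]
  starts <- seq(times[1], times[length(times)] - window_s + dt / 2,
                by = stride_s)
  pairs <- unique(ratio[, c("num_tx", "num_rx", "den_tx", "den_rx")])
  D <- numeric(length(starts))
  for (w in seq_along(starts)) {
    tot <- 0
    for (p in seq_len(nrow(pairs))) {
      subs <- unique(ratio$subcarrier)
      acc <- c()
      for (m in subs) {
        q <- ratio$ratio[ratio$time >= starts[w] &
                           ratio$time < starts[w] + window_s &
                           ratio$valid &
                           ratio$subcarrier == m &
                           ratio$num_tx == pairs$num_tx[p] &
                           ratio$num_rx == pairs$num_rx[p] &
                           ratio$den_tx == pairs$den_tx[p] &
                           ratio$den_rx == pairs$den_rx[p]]
        if (length(q) < 2) next
        qbar <- mean(q)
        s <- 0
        for (r in seq_along(q)) s <- s + Mod(q[r] - qbar)^2
        acc <- c(acc, s / (length(q) - 1))
      }
      if (length(acc)) tot <- tot + mean(acc)
    }
    D[w] <- tot
  }
  D
}
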