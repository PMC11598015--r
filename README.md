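# csibreathe

Non-contact breathing monitoring from WiFi Channel State Information (CSI).

Commodity WiFi hardware reports a complex channel estimate per OFDM
subcarrier for every received packet. When a person breathes near the link,
the chest acts as a moving reflector: the channel is a constant static
vector plus a dynamic component `A·exp(-j·2π·d(t)/λ)` whose path length
`d(t)` rises and falls with the chest. Raw CSI phase is unusable — both
receive chains share a time-varying carrier-frequency-offset /
packet-detection-delay phase — but the **ratio of the CSI between two
receive chains cancels that phase exactly**, leaving a clean trajectory on
the I/Q plane that sweeps back and forth once per breath. `csibreathe`
reconstructs respiration from that trajectory:

1. **Gaussian-process interpolation** (RBF kernel, marginal-likelihood
   hyperparameters) puts non-uniformly sampled CSI on a uniform grid.
2. **Two-link CSI ratio** removes the shared random phase; an optional
   calibration-window mean removes the static path.
3. **Dispersion filtering**: the windowed statistic
   `D = Σ_pairs (1/N_f) Σ_m (1/(W−1)) Σ_r |Q − Q̄|²` flags gross body
   motion (threshold 0.001); flagged samples are excluded, not repaired.
4. **Gaussian-basis least squares** (`φ_d(t) = exp(−(t−c_d)²/2s²)`, plus an
   intercept) smooths the trajectory per contiguous clean segment.
5. **Turning-point extraction**: breath transitions are turns of the
   fitted trajectory larger than `2π/3`; the breathing waveform is the
   signed arc length `S[i] = S[i−1] + flag·ΔL`, with the flag flipping at
   each transition; the rate comes from counting transition pairs.
6. **Metrics**: interval accuracy `ACC = mean((t_ref − |t_ref −
   t_det|)/t_ref)`, mean absolute error of min-max-normalized waveforms
   (MAE), and absolute rate error `AER = |R_ref − R_det|` in breaths/min.

A synthetic CSI generator with known ground truth (chest displacement with
asymmetric inter-breath pauses, shared random-walk phase noise, receiver
noise, timestamp jitter, motion bursts) makes every stage testable without
hardware.

## Worked example

```r
library(csibreathe)

cfg <- sim_config(duration = 60, breathing_rate_bpm = 15, seed = 2)
sim <- simulate_csi(cfg)
res <- run_pipeline(sim, quiet = TRUE)

glance(res)
#> # A tibble: 1 × 8
#>   rate_bpm n_transitions n_segments duration_s n_intervals   acc    mae     aer
#>      <dbl>         <int>      <int>      <dbl>       <int> <dbl>  <dbl>   <dbl>
#> 1     15.0            29          1       60.0          27 0.949 0.0720 0.00335
```

The run recovered the 15 breaths/min rate to within 0.003 bpm, detected
29 of the 30 breath transitions with interval accuracy 0.95, and the
reconstructed waveform matches the true chest displacement to MAE 0.072
after normalization. `autoplot(res)` draws the waveform with transitions
marked; `autoplot(res$trajectory)` shows the I/Q-plane trajectory;
`plot_dispersion(res$dispersion)` shows the motion statistic against its
threshold.

Results also round-trip through files:

```r
write_csi_table(sim$csi, "csi.csv")          # plain-CSV CSI table
write_sim_truth(sim$truth, "truth.json")     # ground-truth sidecar
res2 <- run_pipeline(read_csi_table("csi.csv"))
write_breath_result(res2, "result/")         # waveform.csv, transitions.json, rate.json
```

A thin command-line wrapper with `simulate`, `extract`, `evaluate` and
`demo` subcommands is installed under `inst/cli/csibreathe`.

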