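---
title: "Breathing extraction from CSI-ratio trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing extraction from CSI-ratio trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The sensing model

A WiFi receiver reports, per packet and per OFDM subcarrier, a complex
channel estimate $H(f, t)$. With a person breathing in the scene,

$$H(f,t) = H_s(f) + A(f)\,e^{-j 2\pi d(t)/\lambda},$$

where $H_s$ is the constant vector sum of the line-of-sight and fixed
reflector paths, $A$ the (small) gain of the chest-reflected path, $d(t)$
its length, and $\lambda$ the carrier wavelength. As the chest rises and
falls, the dynamic phasor sweeps an angle $2\pi \Delta d/\lambda$ — about
0.54 rad for a 5 mm peak-to-peak displacement at 5.18 GHz — so $H$ traces
an arc on the I/Q plane, forward during inhalation and back during
exhalation.

Raw CSI is unusable directly: transmitter and receiver run on different
oscillators, so every packet carries a time-varying carrier-frequency
offset and packet-detection delay that rotate the whole measured channel
by a phase $\psi(t)$ common to all receive chains of the device. The
package's central primitive is the **two-link CSI ratio**
$Q(f,t) = H_{rx1}(f,t)\,/\,H_{rx2}(f,t)$: the common factor
$e^{-j\psi(t)}$ cancels algebraically, while the breathing modulation
survives because the two chains see the chest at different path offsets.
$Q(t)$ is a Möbius image of the dynamic phasor — an arc that is retraced
once per breath, with a large-angle turn at each transition between
inhalation and exhalation.

# Pipeline

## Gaussian-process interpolation

Packet arrivals are not equally spaced, so each stream is interpolated
onto a uniform grid with the posterior mean of a Gaussian process using
the radial-basis-function kernel
$k(x,x') = \exp(-\lVert x-x'\rVert^2/2\ell^2)$. Real and imaginary parts
are treated as independent channels sharing one length scale $\ell$ and
one observation-noise variance, both chosen by maximizing the log
marginal likelihood (bounded L-BFGS from three fixed starts, best
likelihood kept; $\ell$ is constrained to $[0.05, 5]$ s to keep the
optimizer off degenerate flats).

Two numerical choices matter here:

* **Shared smoothing weights across streams.** All streams of one
  receiver come from the same packet arrivals. The hyperparameters are
  therefore fitted once on the pooled standardized channels and a single
  smoother matrix is applied to every stream. This is not only faster: a
  linear smoother applied identically to numerator and denominator lets
  the common oscillator phase cancel in the subsequent ratio to first
  order, whereas stream-specific smoothers would re-introduce it.
* **Block evaluation.** The posterior mean is evaluated over time blocks
  with a $4\ell$ margin of training points, and the hyperparameter fit
  uses contiguous chunks (not an even thinning, which would stretch the
  effective sample spacing and hide short-length-scale structure from the
  likelihood). Cost is linear in record length; a 120 s record at 20 Hz
  with six streams interpolates in about a second.

## Static path and ratio

Because the static component is constant, it can be estimated as the mean
over a calibration window (default: the first 10 s) or as a per-sample
moving average, and subtracted. The pipeline's default leaves the static
component in place and forms the ratio from the full channel, which is
the configuration in which the ratio trajectory is an arc; a flag enables
static removal before the ratio for scenes where a dominant static path
drowns the dynamics. Samples whose denominator magnitude falls below
$10^{-3}\times$ its median are marked invalid.

## Motion rejection

Gross body motion (arm waving, posture shifts) scatters the ratio samples
across the plane. Over sliding windows (1 s, 50% overlap) the package
computes the dispersion

$$D \;=\; \sum_{\text{link pairs}} \frac{1}{N_f}\sum_{m=1}^{N_f}
  \frac{1}{W-1}\sum_{r=1}^{W}\bigl|Q(f_m,t_{n+r}) - \bar Q(f_m,t_n)\bigr|^2,$$

with $\bar Q$ the within-window mean. Quiet breathing moves the ratio
slowly and coherently, keeping $D$ of order $10^{-5}$–$10^{-4}$ under the
simulator's default conditions; motion inflates it by one to two orders
of magnitude. Samples covered by any window with $D > 0.001$ (a fixed
reference level) are excluded — not repaired — and the later stages
operate per contiguous clean segment. A sample in any over-threshold
window is flagged (the conservative choice: contamination spreads through
any fit that uses the sample).

The scale of $D$ depends on the ratio normalization, which is set here by
static magnitudes near 1; the threshold is configurable for hardware with
a different gain convention.

## Trajectory fitting

Per clean segment, both channels of $Q$ are regressed onto an intercept
plus $p$ Gaussian bumps

$$\phi_d(t) = \exp\!\Bigl(-\tfrac{(t - c_d)^2}{2s^2}\Bigr), \qquad
  c_d = t_0 + \tfrac{d}{p+1}\,(t_1 - t_0),$$

by least squares with a ridge term ($10^{-8}$, bump block only) on the
normal equations. The two channels share the design matrix, which is
exactly the complex least-squares problem. Design notes:

* The bump centers are spread at fractional positions $d/(p+1)$ of the
  segment window, making the fit invariant to time translation.
* The **intercept** carries the ratio's large constant offset. The
  interior-centered bump basis alone approximates a constant poorly near
  the window edges (errors of a few percent of the offset — larger than
  the entire breathing excursion), so without the intercept the fit noise
  floor would swamp the signal.
* Default density is $p = \lceil 8\,T/\text{expected period}\rceil$
  bumps (about eight per breath at the 4 s default period) with width
  $s = T/(p+1)$. Sparser bases smear each breath-transition turn over
  about a second, which dilutes the turning angle below the detection
  threshold; denser bases track fit noise. Both $p$ and $s$ are
  configurable.

## Transition detection and waveform

A breath transition is a point where the fitted trajectory turns by more
than $2\pi/3$. The turning angle between successive displacement vectors
is computed with the four-quadrant arctangent of
$(\lvert\text{cross}\rvert, \text{dot})$, giving values in $[0,\pi]$: 0
for straight motion, $\pi$ for a full reversal. (A plain arctangent of a
single component ratio cannot exceed $\pi/2$ and could never reach the
$2\pi/3$ threshold; the cross/dot form is the reading under which the
threshold is meaningful.)

Where the angles are evaluated matters more than how. Near a transition
the trajectory *stalls* — breathing pauses briefly at each turn, slightly
longer after exhalation than after inhalation — so displacement vectors
taken on the time grid shrink toward the fit's noise floor and the
reversal dilutes across many small, noisy steps. The package therefore
evaluates turning angles on an **arc-length-uniform resampling** of the
fitted curve: chords of fixed length (half the estimated half-breath arc;
the half-breath arc is estimated from the trajectory's spatial diameter,
which makes the scale independent of the breathing rate). Two
refinements close the remaining corner cases:

* a reversal that lands mid-chord collapses that chord's net
  displacement; a *skip-one* angle across the collapsed chord (applied
  only when the chord's net displacement falls below 0.6 of its arc
  length) restores the turn;
* each detection is refined to the midpoint of the dense curve's stall
  region (the interval of near-minimal speed), recovering timing
  precision of a few tens of milliseconds at good SNR, after which
  detections closer than 0.8 s collapse to the largest-angle one.

The breathing waveform is the signed arc length
$S_i = S_{i-1} + \text{flag}\times\Delta L_i$ with $S_1 = 0$ and the flag
(initialized to $+1$) flipping at each transition. The sign convention is
arbitrary: inhalation and exhalation are not distinguishable from arc
length alone. The rate counts transitions: each inter-transition gap is a
whole number of half-cycles, estimated as the gap over the median gap and
rounded, and the rate is the resulting half-cycle count between the first
and last transition divided by twice that span (partial edge half-cycles
are excluded by construction; a flag includes them). This reduces to
plain transition-pair counting when no turn is missed and tolerates an
occasional missed turn. Per clean segment, rates combine weighted by
segment span.

# Metrics

Against a reference (the simulator's ground truth, or a wearable-belt
trace supplied as a two-column table):

* **ACC** — per-breath intervals are aligned by greedy nearest-onset
  matching, gated at half the median reference interval (unmatched
  reference breaths score 0), and averaged as
  $(t_{\mathrm{ref}} - |t_{\mathrm{ref}} - t_{\mathrm{det}}|)/t_{\mathrm{ref}}$.
  The global mean is reported, with a per-minute breakdown available.
* **MAE** — both signals are resampled to the extracted waveform's grid,
  min-max normalized to $[0,1]$, and compared by mean absolute
  difference. Because the waveform's sign is arbitrary, the evaluation
  reports the better of the two orientations.
* **AER** — the absolute difference of the two rates, in breaths/min.

# The synthetic generator

No public CSI corpus with breathing ground truth exists, so the package
ships a generator that embodies the sensing model:
$H = (H_s + A\,e^{-j2\pi d(t)/\lambda} + n)\,e^{-j\psi(t)}$ per link and
subcarrier, sampled at jittered timestamps. Choices and defaults, fixed
at design time:

* **Displacement** $d(t)$: half-cosine inhale/exhale ramps separated by
  flat pauses, the exhale-to-inhale pause (0.5 s) longer than the
  inhale-to-exhale one (0.3 s); peak-to-peak amplitude 5 mm. Half-cosine
  ramps are smooth at their endpoints, so no artificial trajectory
  corners alias as transitions. Ground truth records the pause centers
  as transition times, two per cycle.
* **Phase noise** $\psi(t)$: a random walk with 0.02 rad per-sample
  steps, applied to the whole measured channel (oscillator error rotates
  everything the receiver estimates, which is also what makes the ratio
  invariant to it). Over a two-minute record the drift (~1 rad) exceeds
  the breathing phase excursion (±0.27 rad) — raw-phase methods fail —
  while remaining locally smooth at the 50 ms packet spacing, as
  fractional-ppm oscillator drift is.
* **Geometry**: static vectors of magnitude ≈ 1 with distinct phases per
  receive chain; dynamic gains ≈ 0.05; an inter-chain path offset of
  0.0382 m (≈ 2/3 wavelength) placing the two links' dynamic responses
  near-antiphase in the ratio — the sensitive geometry a practitioner
  arranges by antenna placement.
* **Noise**: complex Gaussian with SD 0.005 per quadrature (≈ 46 dB
  relative to the static path), drawn before the phase rotation so the
  phase-cancellation property holds exactly under a fixed seed.
* **Sampling**: 20 Hz nominal with 10 ms Gaussian timestamp jitter,
  sorted and made strictly increasing.
* **Motion bursts**: configured windows multiply the dynamic gain and add
  an independent random-walk displacement (4 mm per-sample steps),
  producing dispersion one to two orders above the quiet-breathing level.

With these defaults, quiet-breathing dispersion sits comfortably below
the 0.001 threshold across 10–25 breaths/min while bursts exceed it —
the ordering the motion filter requires.

What the generator does **not** emulate: Fresnel-zone geometry and
position-dependent sensitivity nulls, multi-person scenes, subcarrier-
dependent fading (subcarriers differ only by small static rotations and
their center frequencies), hardware quantization, and non-stationary
breathing (rate drift, apnea). Passing tests on this generator shows the
algorithm chain is correct under the stated model, not that every real
deployment geometry will reach the same accuracy.

# Problem sizes and accuracy envelope

The test-suite simulations use 40–90 s records and the experiment analogs
120 s records at 20 Hz — sizes at which a full pipeline run takes a few
seconds. Under default (quiet) conditions the pipeline recovers rates of
10–25 breaths/min to within a few hundredths of a breath per minute and
interval accuracy ≈ 0.95; with 2 s motion bursts and dispersion filtering
the rate error stays well under half a breath per minute.

The distance experiment is the hard regime: with the dynamic gain scaled
by 1/3 and noise SD doubled, the fitted trajectory's position uncertainty
near a stall (~2–3×10⁻³ I/Q units) against a slow approach speed gives an
irreducible transition-timing spread of ≈ 0.3 s, which caps interval
accuracy near 0.91–0.92 regardless of detection quality. Rate estimation,
which only counts turns, is unaffected. This is the main known
limitation: interval-level accuracy degrades with range noticeably faster
than rate-level accuracy.

# Degenerate inputs and tie-breaks

Constant CSI interpolates to itself (the GP short-circuits when the
signal variance vanishes). Segments with fewer clean samples than basis
functions are skipped with a warning. Zero-length displacements carry a
turning angle of 0 (no turn). Arc-length queries are confined to one
segment. Min-max normalization of a constant signal is an error rather
than a silent NaN. Ties in transition thinning resolve to the
largest-angle detection.
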