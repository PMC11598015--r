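# Turning angles, transitions, arc length, waveform reconstruction.

test_that("turning angles: perpendicular, reversal, straight", {
  # displacements (1,0) then (0,1) -> pi/2
  q <- c(0 + 0i, 1 + 0i, 1 + 1i)
  expect_equal(turning_angles(q)$angle, pi / 2)
  # (1,0) then (-1,0) -> pi
  q <- c(0 + 0i, 1 + 0i, 0 + 0i)
  expect_equal(turning_angles(q)$angle, pi)
  # (1,0) then (1,0) -> 0
  q <- c(0 + 0i, 1 + 0i, 2 + 0i)
  expect_equal(turning_angles(q)$angle, 0)
})

test_that("zero-length displacements carry an angle of 0", {
  q <- c(0 + 0i, 1 + 0i, 1 + 0i, 2 + 0i)
  ang <- turning_angles(q)
  expect_equal(ang$angle, c(0, 0))
})

test_that("a constant-speed circle with enough points has no transitions", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  traj <- as_trajectory(seq_along(th),
                        complex(real = cos(th), imaginary = sin(th)))
  ang <- turning_angles(traj)
  expect_lt(max(ang$angle), 2 * pi / 3)
  expect_equal(nrow(detect_transitions(ang)), 0)
})

test_that("an out-and-back line yields exactly one transition at the reversal", {
  pos <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))
  traj <- as_trajectory(1:21, complex(real = pos))
  det <- detect_transitions(turning_angles(traj), min_separation = 0)
  expect_equal(nrow(det), 1)
  expect_equal(det$time, 11)
  expect_equal(det$angle, pi)
})

test_that("transition thinning keeps the largest angle within min_separation", {
  ang <- tibble::tibble(time = c(1, 1.2, 1.4, 5), segment = 1L,
                        angle = c(2.5, 3.0, 2.6, 2.8))
  det <- detect_transitions(ang, threshold = 2, min_separation = 1)
  expect_equal(det$time, c(1.2, 5))
  expect_error(detect_transitions(ang, threshold = 4), "pi")
})

test_that("arc length matches straight-chord and semicircle oracles", {
  # straight: 0 to 3+4i -> 5
  traj <- as_trajectory(c(0, 1), c(0 + 0i, 3 + 4i))
  expect_equal(arc_length(traj, 0, 1), 5)
  # dense unit semicircle -> pi
  th <- seq(0, pi, length.out = 500)
  semi <- as_trajectory(seq(0, 1, length.out = 500),
                        complex(real = cos(th), imaginary = sin(th)))
  expect_lt(abs(arc_length(semi, 0, 1) - pi), 1e-3)
  # degenerate interval
  expect_equal(arc_length(semi, 0.5, 0.5), 0)
  expect_error(arc_length(semi, 0.7, 0.2), "exceed")
})

test_that("waveform without transitions is the monotone cumulative arc length", {
  pos <- complex(real = seq(0, 2, length.out = 21))
  traj <- as_trajectory(1:21, pos)
  bw <- build_waveform(traj, numeric(0))
  expect_equal(bw$waveform$S[1], 0)
  expect_true(all(diff(bw$waveform$S) >= 0))
  expect_equal(max(bw$waveform$S), 2)
})

test_that("out-and-back path gives a triangle waveform peaking at |AB|", {
  pos <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))
  traj <- as_trajectory(1:21, complex(real = pos))
  det <- detect_transitions(turning_angles(traj), min_separation = 0)
  bw <- build_waveform(traj, det)
  S <- bw$waveform$S
  expect_equal(S[1], 0)
  expect_equal(max(S), 1)
  expect_equal(which.max(S), 11)
  expect_true(all(diff(S[1:11]) > 0))
  expect_true(all(diff(S[11:21]) < 0))
  # |S increments| equal the chord lengths and the sign flips at T
  expect_equal(abs(diff(S)), Mod(diff(complex(real = pos))),
               tolerance = 1e-12)
})

test_that("waveform is invariant under rigid motions of the trajectory", {
  set.seed(5)
  t <- seq(0, 10, by = 0.1)
  q <- complex(real = sin(t), imaginary = 0.5 * cos(2 * t))
  rot <- exp(1i * 0.9)
  shift <- 5 - 3i
  tr0 <- as_trajectory(t, q)
  tr1 <- as_trajectory(t, q * rot + shift)
  det0 <- detect_transitions(turning_angles(tr0))
  det1 <- detect_transitions(turning_angles(tr1))
  expect_equal(det1$time, det0$time)
  w0 <- build_waveform(tr0, det0)$waveform$S
  w1 <- build_waveform(tr1, det1)$waveform$S
  expect_equal(w1, w0, tolerance = 1e-10)
})

test_that("time reversal negates and reverses the waveform up to constants", {
  pos <- c(seq(0, 1, length.out = 11), seq(0.9, 0.1, length.out = 9))
  traj <- as_trajectory(1:20, complex(real = pos))
  trev <- as_trajectory(1:20, rev(complex(real = pos)))
  w <- build_waveform(traj,
                      detect_transitions(turning_angles(traj),
                                         min_separation = 0))$waveform$S
  wr <- build_waveform(trev,
                       detect_transitions(turning_angles(trev),
                                          min_separation = 0))$waveform$S
  # reversed negation up to an additive constant and a global sign (the
  # flag convention always starts at +1, so the reversed walk may come out
  # with either orientation)
  spread <- min(diff(range(wr + rev(w))), diff(range(wr - rev(w))))
  expect_lt(spread, 1e-10)
})

test_that("breathing rate is recovered on noise-free simulator output", {
  cfg <- exact_cfg(duration = 60, bpm = 15)
  res <- run_pipeline(simulate_csi(cfg), quiet = TRUE)
  expect_equal(nrow(res$transitions),
               length(simulate_displacement(cfg)$transition_times),
               tolerance = 1)
  expect_lt(abs(res$rate_bpm - 15), 0.2)
  # transitions align with the truth within 3 grid steps
  tr <- simulate_displacement(cfg)$transition_times
  nd <- vapply(res$transitions$time, function(x) min(abs(tr - x)),
               numeric(1))
  expect_lt(max(nd), 3 * 0.05 + 0.15)
})

test_that("trough dwell exceeds peak dwell under asymmetric pauses", {
  # the longer exhale-to-inhale pause clusters more fitted points near the
  # waveform troughs than near its peaks
  cfg <- quick_cfg(duration = 60, seed = 31L)
  res <- run_pipeline(simulate_csi(cfg), quiet = TRUE)
  wav <- res$waveform
  s_norm <- (wav$S - min(wav$S)) / diff(range(wav$S))
  # The waveform's sign is an arbitrary convention, so the physical trough
  # may sit at either extreme of S; the asymmetry shows as one extreme
  # hosting clearly more dwell than the other (pause ratio 0.5 s / 0.3 s).
  dwell_lo <- mean(s_norm < 0.1)
  dwell_hi <- mean(s_norm > 0.9)
  expect_gt(min(dwell_lo, dwell_hi), 0)
  expect_gt(max(dwell_lo, dwell_hi) / min(dwell_lo, dwell_hi), 1.1)
})
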