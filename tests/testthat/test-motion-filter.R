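# Dispersion statistic and motion labeling.

mk_ratio <- function(time, values, subcarrier = 1L) {
  tibble::tibble(time = time, subcarrier = subcarrier, freq_hz = 5e9,
                 ratio = values, valid = TRUE,
                 num_tx = 1, num_rx = 1, den_tx = 1, den_rx = 2)
}

test_that("identical samples give zero dispersion", {
  r <- mk_ratio(seq(0, 1.9, by = 0.1), rep(1 + 1i, 20))
  d <- window_dispersion(r, window_s = 1, stride_s = 0.5)
  expect_true(all(d$D == 0))
})

test_that("hand-evaluated two-sample window gives D = 2", {
  r <- mk_ratio(c(0, 0.5), c(0 + 0i, 2 + 0i))
  d <- window_dispersion(r, window_s = 1, stride_s = 1)
  expect_equal(d$D[1], 2)
})

test_that("dispersion is invariant to rotation by a unit-modulus constant", {
  set.seed(10)
  t <- seq(0, 3.9, by = 0.1)
  q <- complex(real = rnorm(40), imaginary = rnorm(40))
  d0 <- window_dispersion(mk_ratio(t, q), 1, 0.5)
  d1 <- window_dispersion(mk_ratio(t, q * exp(1i * 1.1)), 1, 0.5)
  expect_equal(d1$D, d0$D, tolerance = 1e-12)
})

test_that("dispersion scales quadratically in the deviations", {
  set.seed(11)
  t <- seq(0, 1.9, by = 0.1)
  dev <- complex(real = rnorm(20), imaginary = rnorm(20))
  dev <- dev - mean(dev)
  d1 <- window_dispersion(mk_ratio(t, 1 + dev), 2, 2)
  d3 <- window_dispersion(mk_ratio(t, 1 + 3 * dev), 2, 2)
  expect_equal(d3$D, 9 * d1$D, tolerance = 1e-10)
})

test_that("an added displacement outlier cannot decrease a window's D", {
  set.seed(12)
  t <- seq(0, 0.9, by = 0.1)
  q <- complex(real = rnorm(10, sd = 0.01), imaginary = rnorm(10, sd = 0.01))
  d0 <- window_dispersion(mk_ratio(t, q), 1, 1)$D[1]
  q_out <- q
  q_out[5] <- q_out[5] + 5 + 5i
  d1 <- window_dispersion(mk_ratio(t, q_out), 1, 1)$D[1]
  expect_gte(d1, d0)
})

test_that("implementation matches the brute-force oracle on random data", {
  set.seed(13)
  for (rep in 1:3) {
    t <- seq(0, 2.95, by = 0.05)
    r <- dplyr::bind_rows(lapply(1:3, function(m) {
      mk_ratio(t, complex(real = rnorm(60), imaginary = rnorm(60)),
               subcarrier = m)
    }))
    fast <- window_dispersion(r, window_s = 0.8, stride_s = 0.4)$D
    slow <- dispersion_oracle(r, window_s = 0.8, stride_s = 0.4)
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
})

test_that("windows above threshold label their samples as interference", {
  t <- seq(0, 1.9, by = 0.1)
  r <- mk_ratio(t, rep(1 + 0i, 20))
  disp <- tibble::tibble(window_start = c(0, 1), window_end = c(1, 2),
                         n = 10L, D = c(0.0005, 0.002))
  lab <- label_interference(r, disp, threshold = 0.001)
  expect_false(any(lab$motion[lab$time < 1]))
  expect_true(all(lab$motion[lab$time >= 1]))
  # infinite threshold: all clean
  lab2 <- label_interference(r, disp, threshold = Inf)
  expect_false(any(lab2$motion))
  expect_error(label_interference(r, disp, threshold = 0), "positive")
})

test_that("a motion burst is flagged while quiet breathing is not", {
  mb <- data.frame(start = 30, end = 32, amplitude = 3)
  sim <- simulate_csi(quick_cfg(duration = 60, seed = 21L,
                                motion_bursts = mb))
  uni <- interpolate_csi(sim$csi, 20)
  ratio <- csi_ratio(uni)
  disp <- window_dispersion(ratio, 1, 0.5)
  lab <- label_interference(ratio, disp, 0.001)
  one <- lab[lab$subcarrier == 1, ]
  in_burst <- one$time >= 30 & one$time < 32
  expect_gte(mean(one$motion[in_burst]), 0.9)
  expect_lte(mean(one$motion[!in_burst]), 0.05)
  # Figure-6-style ordering: motion dispersion dominates quiet dispersion
  mid <- (disp$window_start + disp$window_end) / 2
  expect_gt(median(disp$D[mid >= 30 & mid <= 32]),
            median(disp$D[mid < 28 | mid > 34]))
})
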