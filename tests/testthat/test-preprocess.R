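# GP interpolation, static estimation/removal, and the two-link ratio.

test_that("RBF kernel equals 1 at zero distance", {
  expect_equal(csibreathe:::rbf_kernel(0.3, 0.3, ell = 0.7)[1, 1], 1)
})

test_that("GP interpolation of a constant series returns the constant", {
  set.seed(1)
  t <- sort(runif(50, 0, 10))
  gp <- gp_interpolate(t, rep(2 - 1i, 50), grid_rate = 5)
  expect_lt(max(Mod(gp$values - (2 - 1i))), 1e-6)
  expect_true(csibreathe:::is_uniform_grid(gp$time))
})

test_that("GP recovers a noise-free sinusoid from jittered samples", {
  set.seed(42)
  t <- sort((0:399) / 20 + rnorm(400, 0, 0.02))
  t <- t - min(t)
  y <- complex(real = sin(2 * pi * t / 4), imaginary = cos(2 * pi * t / 4))
  gp <- gp_interpolate(t, y, grid_rate = 20)
  truth <- complex(real = sin(2 * pi * gp$time / 4),
                   imaginary = cos(2 * pi * gp$time / 4))
  expect_lt(max(Mod(gp$values - truth)), 1e-2)
})

test_that("GP posterior mean reproduces observations as noise vanishes", {
  set.seed(3)
  t <- sort(runif(60, 0, 6))
  y <- complex(real = sin(t), imaginary = cos(t))
  gp <- gp_interpolate(t, y, grid_rate = 10,
                       noise_bounds = c(1e-12, 1e-10), grid = t)
  expect_lt(max(Mod(gp$values - y)), 1e-4)
})

test_that("GP interpolation validates its inputs", {
  expect_error(gp_interpolate(1:3, complex(real = 1:3), 10), "4 samples")
  expect_error(gp_interpolate(c(1, 3, 2, 4), complex(real = 1:4), 10),
               "increasing")
  expect_error(gp_interpolate(1:4, complex(real = c(1, NaN, 3, 4)), 10),
               "finite")
})

test_that("interpolate_csi puts all streams on one shared grid", {
  sim <- simulate_csi(quick_cfg(duration = 12, seed = 2L))
  uni <- interpolate_csi(sim$csi, grid_rate = 20)
  grids <- split(uni$time, csibreathe:::stream_id(uni$tx, uni$rx,
                                                  uni$subcarrier))
  expect_true(all(vapply(grids, identical, logical(1), grids[[1]])))
  expect_s3_class(attr(uni, "gp_models"), "tbl_df")
})

test_that("static estimate is the windowed mean and is exact on static scenes", {
  # arithmetic mean oracle
  csi <- tibble::tibble(time = c(0, 1), tx = 1L, rx = 1L, subcarrier = 1L,
                        freq_hz = 5e9, csi = c(1 + 0i, 3 + 0i))
  est <- estimate_static(csi, window_s = 2)
  expect_equal(est$static, 2 + 0i)
  # static-only simulator output
  cfg <- exact_cfg(chest_amplitude = 0, dynamic_gain_per_link = c(0, 0))
  sim <- simulate_csi(cfg)
  est2 <- estimate_static(sim$csi, window_s = 10)
  s11 <- est2$static[est2$rx == 1 & est2$subcarrier == 2]
  truth <- cfg$static_component_per_link[1]
  # the simulator rotates the static vector slightly per subcarrier
  expect_equal(Mod(s11), Mod(truth), tolerance = 1e-10)
})

test_that("rolling static estimate preserves length and follows the mean", {
  sim <- simulate_csi(quick_cfg(duration = 15, seed = 4L))
  roll <- estimate_static(sim$csi, window_s = 4, mode = "rolling")
  expect_equal(nrow(roll), nrow(sim$csi))
  expect_true(all(is.finite(Mod(roll$static))))
})

test_that("static estimation is translation-equivariant", {
  sim <- simulate_csi(quick_cfg(duration = 15, seed = 6L))
  shift <- 3 - 2i
  shifted <- sim$csi
  shifted$csi <- shifted$csi + shift
  e0 <- estimate_static(sim$csi, window_s = 8)
  e1 <- estimate_static(shifted, window_s = 8)
  expect_equal(e1$static, e0$static + shift, tolerance = 1e-12)
})

test_that("remove_static subtracts elementwise and inverts exactly", {
  sim <- simulate_csi(quick_cfg(duration = 10, seed = 8L))
  est <- estimate_static(sim$csi, window_s = 5)
  dyn <- remove_static(sim$csi, est)
  back <- dyn
  joined <- dplyr::left_join(back, est, by = c("tx", "rx", "subcarrier"))
  expect_equal(joined$csi + joined$static, sim$csi$csi, tolerance = 1e-12)
  # input equal to static -> all-zero output
  const <- sim$csi
  joined2 <- dplyr::left_join(const, est, by = c("tx", "rx", "subcarrier"))
  const$csi <- joined2$static
  expect_true(all(Mod(remove_static(const, est)$csi) < 1e-12))
})

test_that("residual dynamic magnitude matches the configured gain", {
  cfg <- exact_cfg(duration = 30)
  sim <- simulate_csi(cfg)
  # center subcarrier: the simulator's static vector is unrotated there
  s <- sim$csi[sim$csi$rx == 1 & sim$csi$subcarrier == 2, ]
  hs <- cfg$static_component_per_link[1]
  expect_equal(Mod(s$csi - hs), rep(cfg$dynamic_gain_per_link[1], nrow(s)),
               tolerance = 1e-9)
})

test_that("csi_ratio performs complex division with amplitude guarding", {
  grid <- seq(0, 1, by = 0.25)
  mk <- function(rx, vals) tibble::tibble(time = grid, tx = 1L, rx = rx,
                                          subcarrier = 1L, freq_hz = 5e9,
                                          csi = vals)
  num <- mk(1L, rep(2 * exp(1i * pi / 2), 5))
  den <- mk(2L, rep(1 * exp(1i * pi / 4), 5))
  r <- csi_ratio(dplyr::bind_rows(num, den))
  expect_equal(r$ratio, rep(2 * exp(1i * pi / 4), 5), tolerance = 1e-12)
  # identical links rejected
  expect_error(csi_ratio(dplyr::bind_rows(num, den), c(1, 1), c(1, 1)),
               "differ")
  # mismatched grids rejected
  den2 <- den
  den2$time <- den2$time + 0.01
  expect_error(csi_ratio(dplyr::bind_rows(num, den2)), "grid")
  # amplitude floor marks small denominators invalid
  den3 <- den
  den3$csi[3] <- 1e-9 + 0i
  r3 <- csi_ratio(dplyr::bind_rows(num, den3), amp_floor_factor = 1e-3)
  expect_false(r3$valid[3])
  expect_true(all(r3$valid[-3]))
})

test_that("common multiplicative phase cancels in the ratio", {
  grid <- seq(0, 2, by = 0.1)
  set.seed(9)
  psi <- cumsum(rnorm(length(grid), 0, 0.4))
  h1 <- complex(real = 1 + 0.1 * sin(grid), imaginary = 0.3 * cos(grid))
  h2 <- complex(real = 0.8, imaginary = -0.2 + 0.05 * sin(grid))
  mk <- function(rx, vals) tibble::tibble(time = grid, tx = 1L, rx = rx,
                                          subcarrier = 1L, freq_hz = 5e9,
                                          csi = vals)
  r0 <- csi_ratio(dplyr::bind_rows(mk(1L, h1), mk(2L, h2)))
  r1 <- csi_ratio(dplyr::bind_rows(mk(1L, h1 * exp(1i * psi)),
                                   mk(2L, h2 * exp(1i * psi))))
  expect_lt(max(Mod(r1$ratio - r0$ratio) / Mod(r0$ratio)), 1e-9)
})

test_that("ratio modulus and phase follow the single-path algebra", {
  f <- 5.18e9
  tau1 <- 1.0e-9; tau2 <- 1.3e-9
  a1 <- 0.8; a2 <- 0.5
  grid <- seq(0, 1, by = 0.5)
  mk <- function(rx, a, tau) tibble::tibble(
    time = grid, tx = 1L, rx = rx, subcarrier = 1L, freq_hz = f,
    csi = rep(a * exp(-2i * pi * f * tau), length(grid))
  )
  r <- csi_ratio(dplyr::bind_rows(mk(1L, a1, tau1), mk(2L, a2, tau2)))
  expect_equal(Mod(r$ratio), rep(a1 / a2, 3), tolerance = 1e-12)
  expected_phase <- Arg(exp(-2i * pi * f * (tau1 - tau2)))
  expect_equal(Arg(r$ratio), rep(expected_phase, 3), tolerance = 1e-12)
})
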