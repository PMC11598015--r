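# Gaussian-basis trajectory fitting.

mk_ratio_tbl <- function(time, values) {
  tibble::tibble(time = time, subcarrier = 1L, ratio = values, clean = TRUE)
}

test_that("gaussian basis has unit peak, exp(-1/2) at one s, and symmetry", {
  win <- c(0, 10)
  p <- 4; s <- 1.3
  center <- win[1] + 2 / (p + 1) * diff(win)
  expect_equal(gaussian_basis(center, 2, p, s, win), 1)
  expect_equal(gaussian_basis(center + s, 2, p, s, win), exp(-0.5))
  expect_equal(gaussian_basis(center + 0.7, 2, p, s, win),
               gaussian_basis(center - 0.7, 2, p, s, win))
  expect_error(gaussian_basis(1, 5, p, s, win), "1 <= d <= p")
  expect_error(gaussian_basis(1, 2, p, -1, win), "positive")
})

test_that("fit recovers coefficients of data synthesized from the basis", {
  t <- seq(0, 20, by = 0.05)
  p <- 10; s <- 2; win <- range(t)
  Phi <- sapply(1:p, function(d) gaussian_basis(t, d, p, s, win))
  set.seed(1)
  br <- rnorm(p); bi <- rnorm(p)
  q <- as.vector(Phi %*% br) + 1i * as.vector(Phi %*% bi)
  ft <- fit_trajectory(mk_ratio_tbl(t, q), p = p, s = s)
  seg <- attr(ft, "segments")[[1]]
  expect_lt(max(abs(seg$beta_re - br)), 1e-6)
  expect_lt(max(abs(seg$beta_im - bi)), 1e-6)
  expect_lt(seg$residual_rms, 1e-8)
})

test_that("constant input is reproduced", {
  t <- seq(0, 10, by = 0.05)
  c0 <- 2 + 1i
  ft <- fit_trajectory(mk_ratio_tbl(t, rep(c0, length(t))), p = 6)
  expect_lt(max(Mod(ft$fitted - c0)), 1e-6)
  expect_lt(attr(ft, "segments")[[1]]$residual_rms, 1e-3 * Mod(c0))
})

test_that("increasing p never increases the residual", {
  set.seed(2)
  t <- seq(0, 12, by = 0.05)
  q <- complex(real = sin(2 * pi * t / 4) + 0.05 * rnorm(length(t)),
               imaginary = cos(2 * pi * t / 4))
  res <- sapply(c(6, 12, 24, 48), function(p) {
    attr(fit_trajectory(mk_ratio_tbl(t, q), p = p),
         "segments")[[1]]$residual_rms
  })
  expect_true(all(diff(res) <= 1e-10))
})

test_that("fit is linear in the data for a fixed basis", {
  set.seed(3)
  t <- seq(0, 8, by = 0.05)
  q1 <- complex(real = rnorm(length(t)), imaginary = rnorm(length(t)))
  q2 <- complex(real = rnorm(length(t)), imaginary = rnorm(length(t)))
  f <- function(q) fit_trajectory(mk_ratio_tbl(t, q), p = 8, s = 1)$fitted
  expect_equal(f(2 * q1 - 3i * q2), 2 * f(q1) - 3i * f(q2),
               tolerance = 1e-8)
})

test_that("fit is invariant to global time translation", {
  set.seed(4)
  t <- seq(0, 8, by = 0.05)
  q <- complex(real = sin(t), imaginary = cos(t))
  f0 <- fit_trajectory(mk_ratio_tbl(t, q), p = 10, s = 0.8)$fitted
  f1 <- fit_trajectory(mk_ratio_tbl(t + 137.5, q), p = 10, s = 0.8)$fitted
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("underdetermined segments are skipped with a warning", {
  t <- seq(0, 1, by = 0.05)
  expect_warning(
    expect_error(fit_trajectory(mk_ratio_tbl(t, rep(1 + 0i, length(t))),
                                p = 50),
                 "underdetermined"),
    "skipped")
})

test_that("masked gaps split the fit into independent segments", {
  t <- seq(0, 20, by = 0.05)
  q <- complex(real = sin(t), imaginary = cos(t))
  tbl <- mk_ratio_tbl(t, q)
  tbl$clean <- !(t > 9 & t < 11)
  ft <- fit_trajectory(tbl, p = 10)
  segs <- attr(ft, "segments")
  expect_length(segs, 2)
  expect_lt(segs[[1]]$window[2], 9.01)
  expect_gt(segs[[2]]$window[1], 10.99)
})

test_that("tidy and glance expose coefficients and per-segment summaries", {
  t <- seq(0, 8, by = 0.05)
  ft <- fit_trajectory(mk_ratio_tbl(t, complex(real = sin(t),
                                               imaginary = cos(t))),
                       p = 6, s = 1)
  td <- tidy(ft)
  expect_equal(nrow(td), 12)  # 6 bumps x 2 channels
  gl <- glance(ft)
  expect_equal(gl$p, 6)
  expect_true(gl$residual_rms >= 0)
})
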