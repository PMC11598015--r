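# Gaussian-process interpolation of non-uniformly sampled complex CSI.
#
# Real and imaginary channels are modeled as independent GPs sharing one RBF
# length scale and one observation noise variance, fitted by maximizing the
# (joint) log marginal likelihood. Prediction uses the posterior mean. To
# keep the cost linear in series length, hyperparameters are fitted on an
# even subsample and the posterior mean is evaluated block-wise with a
# 4-length-scale margin of training points around each block.

rbf_kernel <- function(x, y, ell) {
  exp(-outer(x, y, function(a, b) (a - b)^2) / (2 * ell^2))
}

gp_negloglik <- function(par, t, Y) {
  ell <- exp(par[1]); sn2 <- exp(par[2])
  K <- rbf_kernel(t, t, ell)
  diag(K) <- diag(K) + sn2 + 1e-10
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  logdet <- sum(log(diag(L)))
  nll <- 0
  for (j in seq_len(ncol(Y))) {
    alpha <- backsolve(L, forwardsolve(t(L), Y[, j]))
    nll <- nll + 0.5 * sum(Y[, j] * alpha) + logdet
  }
  nll
}

fit_gp_hyper <- function(t, Y, length_scale_bounds = c(0.05, 5),
                         noise_bounds = c(1e-8, 1), max_fit_points = 250) {
  n <- length(t)
  if (n <= max_fit_points) {
    idx <- seq_len(n)
  } else {
    # contiguous chunks spread across the record: even thinning would
    # stretch the sample spacing and hide the short-length-scale structure
    # from the marginal likelihood
    k <- 3L
    len <- max_fit_points %/% k
    starts <- round(seq(1, n - len + 1, length.out = k))
    idx <- sort(unique(unlist(lapply(starts, function(s0) s0:(s0 + len - 1L)))))
  }
  ts <- t[idx]; Ys <- Y[idx, , drop = FALSE]
  lower <- c(log(length_scale_bounds[1]), log(noise_bounds[1]))
  upper <- c(log(length_scale_bounds[2]), log(noise_bounds[2]))
  starts <- list(c(log(0.1), log(1e-2)), c(log(0.5), log(1e-2)),
                 c(log(2.0), log(1e-3)))
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, gp_negloglik, t = ts, Y = Ys, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(list(length_scale = 0.5, noise_var = 1e-4, loglik = NA_real_))
  }
  list(length_scale = exp(best$par[1]), noise_var = exp(best$par[2]),
       loglik = -best$value)
}

gp_posterior_mean <- function(t, Y, grid, ell, sn2,
                              block_size = 600, max_train = 800) {
  n_grid <- length(grid)
  out <- matrix(NA_real_, n_grid, ncol(Y))
  blocks <- split(seq_len(n_grid), ceiling(seq_len(n_grid) / block_size))
  margin <- 4 * ell
  for (b in blocks) {
    lo <- grid[b[1]] - margin
    hi <- grid[b[length(b)]] + margin
    tr <- which(t >= lo & t <= hi)
    if (length(tr) < 2L) tr <- order(abs(t - mean(grid[b])))[1:4]
    if (length(tr) > max_train) {
      tr <- tr[unique(round(seq(1, length(tr), length.out = max_train)))]
    }
    K <- rbf_kernel(t[tr], t[tr], ell)
    diag(K) <- diag(K) + sn2 + 1e-10
    L <- chol(K)
    Ks <- rbf_kernel(grid[b], t[tr], ell)
    for (j in seq_len(ncol(Y))) {
      alpha <- backsolve(L, forwardsolve(t(L), Y[tr, j]))
      out[b, j] <- Ks %*% alpha
    }
  }
  out
}

#' Gaussian-process interpolation of one complex series
#'
#' Interpolates a non-uniformly sampled complex series onto a uniform grid
#' using the posterior mean of a Gaussian process with a radial basis
#' function (squared exponential) kernel,
#' \eqn{k(x, x') = \exp(-\|x - x'\|^2 / 2\ell^2)}. Real and imaginary parts
#' are fitted independently with a shared length scale \eqn{\ell} and noise
#' variance, both chosen by maximizing the marginal likelihood (bounded
#' L-BFGS from three fixed starts; best likelihood kept).
#'
#' @param time Strictly increasing sample times (seconds), at least 4.
#' @param values Complex (or numeric) observations, same length as `time`.
#' @param grid_rate Output sampling rate (samples per second).
#' @param length_scale_bounds Lower/upper bounds (seconds) for \eqn{\ell}.
#' @param noise_bounds Lower/upper bounds for the observation noise variance.
#' @param grid Optional explicit output grid (overrides `grid_rate` spacing
#'   derived from the input range).
#' @return A list: `time` (uniform grid spanning the input range), `values`
#'   (complex posterior mean), and `model` (length scale, noise variance,
#'   marginal log-likelihood).
#' @export
gp_interpolate <- function(time, values, grid_rate,
                           length_scale_bounds = c(0.05, 5),
                           noise_bounds = c(1e-8, 1), grid = NULL) {
  if (length(time) < 4L) abort("GP interpolation needs at least 4 samples.")
  if (any(diff(time) <= 0)) abort("Timestamps must be strictly increasing.")
  if (length(time) != length(values)) {
    abort("`time` and `values` must have the same length.")
  }
  if (any(!is.finite(Re(values)) | !is.finite(Im(values)))) {
    abort("CSI values must be finite.")
  }
  if (is.null(grid)) {
    grid <- seq(time[1], time[length(time)], by = 1 / grid_rate)
  }

  mu <- mean(values)
  dev <- values - mu
  scale <- sd(c(Re(dev), Im(dev)))
  if (!is.finite(scale) || scale < 1e-12) {
    # Constant input: the posterior mean is the constant itself.
    return(list(time = grid, values = rep(mu, length(grid)),
                model = list(length_scale = NA_real_, noise_var = 0,
                             loglik = NA_real_)))
  }
  Y <- cbind(Re(dev), Im(dev)) / scale
  hyp <- fit_gp_hyper(time, Y, length_scale_bounds, noise_bounds)
  M <- gp_posterior_mean(time, Y, grid, hyp$length_scale, hyp$noise_var)
  list(time = grid,
       values = mu + (M[, 1] + 1i * M[, 2]) * scale,
       model = hyp)
}

#' Interpolate all CSI streams onto a shared uniform grid
#'
#' Interpolates every (tx, rx, subcarrier) stream of a CSI table onto one
#' common uniform grid (from the latest stream start to the earliest stream
#' end) so that downstream two-link ratios are sample-aligned.
#'
#' When all streams share one set of timestamps (the usual case: every
#' stream comes from the same packet arrivals at one receiver), the GP
#' hyperparameters are fitted once on the pooled standardized channels and
#' one posterior-mean smoother is applied to every stream. Identical
#' smoothing weights across streams matter beyond speed: the carrier
#' frequency offset / packet detection delay phase is common to all receive
#' chains at each instant, and a shared linear smoother lets that common
#' factor cancel in the subsequent two-link ratio (stream-specific
#' smoothers would re-introduce it). Streams with differing timestamps fall
#' back to independent [gp_interpolate()] calls.
#'
#' @param csi CSI tibble with columns `time`, `tx`, `rx`, `subcarrier`,
#'   `freq_hz`, `csi` (complex), as produced by [simulate_csi()] or
#'   [read_csi_table()].
#' @inheritParams gp_interpolate
#' @return A CSI tibble on the uniform grid, with a `gp_models` attribute
#'   (one row per stream: length scale, noise variance, log-likelihood).
#' @export
interpolate_csi <- function(csi, grid_rate = 20,
                            length_scale_bounds = c(0.05, 5),
                            noise_bounds = c(1e-8, 1)) {
  streams <- dplyr::group_split(dplyr::group_by(csi, .data$tx, .data$rx,
                                                .data$subcarrier))
  t0 <- max(vapply(streams, function(s) s$time[1], numeric(1)))
  t1 <- min(vapply(streams, function(s) s$time[nrow(s)], numeric(1)))
  grid <- seq(t0, t1, by = 1 / grid_rate)

  n1 <- nrow(streams[[1]])
  shared_ts <- all(vapply(streams, function(s) {
    nrow(s) == n1 && max(abs(s$time - streams[[1]]$time)) < 1e-12
  }, logical(1)))

  if (shared_ts && length(streams) > 1L) {
    tt <- streams[[1]]$time
    mus <- vapply(streams, function(s) mean(s$csi), complex(1))
    scales <- vapply(streams, function(s) {
      sd(c(Re(s$csi - mean(s$csi)), Im(s$csi - mean(s$csi))))
    }, numeric(1))
    scales[!is.finite(scales) | scales < 1e-12] <- 1
    Y <- do.call(cbind, lapply(seq_along(streams), function(i) {
      dev <- (streams[[i]]$csi - mus[i]) / scales[i]
      cbind(Re(dev), Im(dev))
    }))
    hyp <- fit_gp_hyper(tt, Y, length_scale_bounds, noise_bounds)
    M <- gp_posterior_mean(tt, Y, grid, hyp$length_scale, hyp$noise_var)
    out <- vector("list", length(streams))
    models <- vector("list", length(streams))
    for (i in seq_along(streams)) {
      s <- streams[[i]]
      vals <- mus[i] + (M[, 2 * i - 1] + 1i * M[, 2 * i]) * scales[i]
      out[[i]] <- tibble::tibble(
        time = grid, tx = s$tx[1], rx = s$rx[1],
        subcarrier = s$subcarrier[1], freq_hz = s$freq_hz[1], csi = vals
      )
      models[[i]] <- tibble::tibble(
        tx = s$tx[1], rx = s$rx[1], subcarrier = s$subcarrier[1],
        length_scale = hyp$length_scale, noise_var = hyp$noise_var,
        loglik = hyp$loglik
      )
    }
  } else {
    out <- vector("list", length(streams))
    models <- vector("list", length(streams))
    for (i in seq_along(streams)) {
      s <- streams[[i]]
      gp <- gp_interpolate(s$time, s$csi, grid_rate,
                           length_scale_bounds, noise_bounds, grid = grid)
      out[[i]] <- tibble::tibble(
        time = grid, tx = s$tx[1], rx = s$rx[1],
        subcarrier = s$subcarrier[1], freq_hz = s$freq_hz[1],
        csi = gp$values
      )
      models[[i]] <- tibble::tibble(
        tx = s$tx[1], rx = s$rx[1], subcarrier = s$subcarrier[1],
        length_scale = gp$model$length_scale, noise_var = gp$model$noise_var,
        loglik = gp$model$loglik
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "gp_models") <- dplyr::bind_rows(models)
  res
}

approx_complex <- function(x, y, xout) {
  re <- approx(x, Re(y), xout, rule = 2)$y
  im <- approx(x, Im(y), xout, rule = 2)$y
  re + 1i * im
}
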