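# Gaussian-basis least-squares fit of the I/Q ratio trajectory.

#' Gaussian basis function
#'
#' Evaluates the d-th of p Gaussian bumps whose centers are spread evenly
#' over a time window: \eqn{\phi_d(t) = \exp(-(t - c_d)^2 / 2 s^2)} with
#' \eqn{c_d = t_0 + \frac{d}{p+1} (t_1 - t_0)}. The center term d/(p+1) is
#' interpreted as the fractional position of the d-th center within the
#' window, so the fit is invariant to global time translation.
#'
#' @param t Time(s) at which to evaluate (seconds).
#' @param d Basis index, `1 <= d <= p`.
#' @param p Basis order (number of bumps).
#' @param s Smoothness (bump width, seconds); `s > 0`.
#' @param window Length-2 numeric: the segment's time window `c(t0, t1)`.
#' @return Numeric vector of basis values (unit peak height).
#' @export
gaussian_basis <- function(t, d, p, s, window) {
  if (d < 1 || d > p) abort("Basis index `d` must satisfy 1 <= d <= p.")
  if (s <= 0) abort("Smoothness `s` must be positive.")
  center <- window[1] + d / (p + 1) * (window[2] - window[1])
  exp(-(t - center)^2 / (2 * s^2))
}

basis_matrix <- function(t, p, s, window) {
  centers <- window[1] + seq_len(p) / (p + 1) * (window[2] - window[1])
  exp(-outer(t, centers, "-")^2 / (2 * s^2))
}

# Split clean samples of a single-pair, single-subcarrier ratio series into
# maximal contiguous runs on the grid.
clean_segments <- function(time, clean, max_gap) {
  idx <- which(clean)
  if (length(idx) == 0L) return(list())
  breaks <- which(diff(time[idx]) > max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  lapply(seq_along(starts), function(k) idx[starts[k]:ends[k]])
}

#' Fit a smooth trajectory through the clean CSI-ratio samples
#'
#' Per contiguous clean segment, the real and imaginary channels of the
#' ratio are regressed onto an intercept plus `p` Gaussian basis functions
#' by (ridge-stabilized) ordinary least squares; the two channels share the
#' design matrix, which is exactly equivalent to minimizing the summed
#' squared complex error. The intercept absorbs the ratio's constant
#' offset, so the bumps model only the breathing oscillation. Segments with
#' fewer clean samples than `p + 1` are skipped with a warning.
#'
#' Defaults when `p` or `s` is `NULL`: about four bumps per expected breath
#' (`p = ceiling(4 T / expected_period_s)`) and neighbor-overlapping bump
#' width `s = T / (p + 1)`, where T is the segment duration.
#'
#' @param ratio Ratio tibble for a single link pair and single subcarrier,
#'   with a `clean` column (see [label_interference()]); a `valid`-only
#'   tibble from [csi_ratio()] is also accepted.
#' @param p Basis order, or `NULL` for the default above.
#' @param s Bump width in seconds, or `NULL` for the default above.
#' @param ridge Ridge term added to the normal equations (default 1e-8),
#'   for numerical stability of near-collinear bases at large `p`.
#' @param expected_period_s Expected breath period used by the `p` default.
#' @return An object of class `fitted_trajectory`: a tibble (`time`,
#'   `segment`, `observed`, `fitted`) with a `segments` attribute holding
#'   per-segment basis parameters (window, p, s, coefficients, residual
#'   RMS).
#' @export
fit_trajectory <- function(ratio, p = NULL, s = NULL, ridge = 1e-8,
                           expected_period_s = 4) {
  stopifnot(is.data.frame(ratio), all(c("time", "ratio") %in% names(ratio)))
  if (length(unique(ratio$subcarrier %||% 1L)) > 1L) {
    abort("`fit_trajectory()` expects a single subcarrier; filter first.")
  }
  clean <- if ("clean" %in% names(ratio)) ratio$clean else
    if ("valid" %in% names(ratio)) ratio$valid else rep(TRUE, nrow(ratio))
  dt <- median(diff(ratio$time))
  segs <- clean_segments(ratio$time, clean, max_gap = 1.5 * dt)
  if (length(segs) == 0L) abort("No clean samples to fit.")

  seg_info <- list()
  rows <- list()
  for (k in seq_along(segs)) {
    idx <- segs[[k]]
    t_seg <- ratio$time[idx]
    q_seg <- ratio$ratio[idx]
    window <- range(t_seg)
    T_seg <- diff(window)
    p_k <- p %||% max(4L, ceiling(8 * T_seg / expected_period_s))
    s_k <- s %||% (T_seg / (p_k + 1))
    if (length(idx) < p_k) {
      warn(sprintf(
        "Segment %d: %d clean samples < p = %d basis functions; skipped.",
        k, length(idx), p_k
      ))
      next
    }
    # Design: intercept + p Gaussian bumps. The intercept carries the
    # ratio's constant offset so the bumps only model the oscillation;
    # ridge stabilizes the (near-collinear) bump block only.
    Phi <- cbind(1, basis_matrix(t_seg, p_k, s_k, window))
    G <- crossprod(Phi) + diag(c(0, rep(ridge, p_k)))
    L <- chol(G)
    beta_re <- backsolve(L, forwardsolve(t(L), crossprod(Phi, Re(q_seg))))
    beta_im <- backsolve(L, forwardsolve(t(L), crossprod(Phi, Im(q_seg))))
    fitted <- as.vector(Phi %*% beta_re) + 1i * as.vector(Phi %*% beta_im)
    rss <- Mod(q_seg - fitted)^2
    seg_info[[length(seg_info) + 1L]] <- list(
      segment = k, window = window, p = p_k, s = s_k,
      beta0_re = beta_re[1], beta0_im = beta_im[1],
      beta_re = as.vector(beta_re[-1]), beta_im = as.vector(beta_im[-1]),
      residual_rms = sqrt(mean(rss)), n = length(idx)
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = t_seg, segment = k, observed = q_seg, fitted = fitted
    )
  }
  if (length(rows) == 0L) abort("All segments were underdetermined; nothing fitted.")
  out <- dplyr::bind_rows(rows)
  structure(out, segments = seg_info,
            class = c("fitted_trajectory", class(out)))
}

# Evaluate the fitted basis of one segment at arbitrary times.
eval_segment <- function(seg, times) {
  Phi <- basis_matrix(times, seg$p, seg$s, seg$window)
  (seg$beta0_re + as.vector(Phi %*% seg$beta_re)) +
    1i * (seg$beta0_im + as.vector(Phi %*% seg$beta_im))
}

#' Wrap a precomputed complex path as a trajectory
#'
#' Builds a `trajectory_path` from explicit (time, position) samples so the
#' turning-angle and arc-length tools can be applied to analytically known
#' curves (lines, circles) as well as to fitted output.
#'
#' @param time Numeric times.
#' @param values Complex positions (or use `re` + `im`).
#' @param re,im Real and imaginary parts, alternative to `values`.
#' @return A tibble of class `trajectory_path` with columns `time`, `fitted`.
#' @export
as_trajectory <- function(time, values = NULL, re = NULL, im = NULL) {
  if (is.null(values)) values <- re + 1i * im
  out <- tibble::tibble(time = time, segment = 1L, fitted = values)
  structure(out, class = c("trajectory_path", class(out)))
}

#' @export
print.fitted_trajectory <- function(x, ...) {
  segs <- attr(x, "segments")
  cat("<fitted_trajectory>", nrow(x), "points in", length(segs),
      "segment(s)\n")
  for (s in segs) {
    cat(sprintf("  segment %d: [%.2f, %.2f] s, p = %d, s = %.3f s, residual RMS = %.2e\n",
                s$segment, s$window[1], s$window[2], s$p, s$s,
                s$residual_rms))
  }
  invisible(x)
}
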