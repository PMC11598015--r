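# Breath-transition detection and signed arc-length waveform reconstruction.

traj_points <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("time", "fitted") %in% names(traj)))
  traj
}

#' Turning angles along a trajectory
#'
#' For each interior point, returns the absolute turning angle between the
#' successive displacement vectors \eqn{\Delta Q_i = Q_{i+1} - Q_i} and
#' \eqn{\Delta Q_{i-1}}, computed with the four-quadrant arctangent of
#' (|cross product|, dot product), so the result lies in \eqn{[0, \pi]}:
#' 0 for straight motion, \eqn{\pi} for a full reversal. Displacements
#' shorter than `eps` give an undefined angle, carried as 0 (no turn).
#'
#' @param traj A `fitted_trajectory`, a `trajectory_path` (see
#'   [as_trajectory()]), or a complex vector (paired with `time`).
#' @param time Times when `traj` is a bare complex vector.
#' @param eps Displacement magnitude below which the angle is treated as
#'   undefined.
#' @return Tibble `time`, `segment`, `angle` for interior points (angles
#'   are attached to the central point of each vector pair).
#' @export
turning_angles <- function(traj, time = NULL, eps = 1e-12) {
  if (is.complex(traj)) {
    traj <- as_trajectory(time %||% seq_along(traj), traj)
  }
  pts <- traj_points(traj)
  out <- lapply(split(seq_len(nrow(pts)), pts$segment), function(idx) {
    if (length(idx) < 3L) return(NULL)
    q <- pts$fitted[idx]
    dq <- diff(q)
    a <- dq[-length(dq)]
    b <- dq[-1]
    dot <- Re(a) * Re(b) + Im(a) * Im(b)
    crs <- Re(a) * Im(b) - Im(a) * Re(b)
    ang <- atan2(abs(crs), dot)
    undef <- Mod(a) < eps | Mod(b) < eps
    ang[undef] <- 0
    tibble::tibble(time = pts$time[idx][-c(1L, length(idx))],
                   segment = pts$segment[idx][-c(1L, length(idx))],
                   angle = ang)
  })
  dplyr::bind_rows(out)
}

#' Detect breath transitions from turning angles
#'
#' Marks grid times whose turning angle exceeds the threshold (2\eqn{\pi}/3
#' by default): on the I/Q plane, the trajectory retraces its arc between
#' inhale and exhale, so breath transitions appear as near-\eqn{\pi} turns
#' while within-breath motion turns only gently. Detections closer together
#' than `min_separation` are collapsed to the single largest-angle time, to
#' suppress double flips from fit wiggle.
#'
#' @param angles Output of [turning_angles()].
#' @param threshold Turning-angle threshold in radians, in (0, pi].
#' @param min_separation Minimum spacing between reported transitions
#'   (seconds; default 0.8 s, shorter than any plausible half-breath).
#' @return Tibble `time`, `segment`, `angle` of the retained transitions,
#'   ordered in time.
#' @export
detect_transitions <- function(angles, threshold = 2 * pi / 3,
                               min_separation = 0.8) {
  if (threshold <= 0 || threshold > pi) {
    abort("`threshold` must lie in (0, pi].")
  }
  hits <- angles[angles$angle > threshold, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(time = numeric(), segment = integer(),
                          angle = numeric()))
  }
  out <- lapply(split(hits, hits$segment), function(h) {
    h <- h[order(h$time), , drop = FALSE]
    cluster <- cumsum(c(1, diff(h$time) >= min_separation))
    picked <- vapply(split(seq_len(nrow(h)), cluster), function(i) {
      i[which.max(h$angle[i])]
    }, integer(1))
    h[picked, , drop = FALSE]
  })
  out <- dplyr::bind_rows(out)
  out[order(out$time), , drop = FALSE]
}

#' Arc length of a trajectory between two times
#'
#' Numerical arc length of the (fitted) trajectory on the complex plane
#' between `t_a` and `t_b`: the basis representation is evaluated on a
#' refined grid and chord lengths are summed. For plain paths the stored
#' points within the interval are used.
#'
#' @param traj `fitted_trajectory` or `trajectory_path`.
#' @param t_a,t_b Interval endpoints (seconds), `t_a <= t_b`, within one
#'   segment.
#' @param refine Grid refinement factor for fitted trajectories.
#' @return Arc length (same units as the ratio, i.e. unitless I/Q distance).
#' @export
arc_length <- function(traj, t_a, t_b, refine = 4) {
  if (t_a > t_b) abort("`t_a` must not exceed `t_b`.")
  if (t_a == t_b) return(0)
  pts <- traj_points(traj)
  seg_ids <- unique(pts$segment[pts$time >= t_a - 1e-12 &
                                  pts$time <= t_b + 1e-12])
  if (length(seg_ids) != 1L) {
    abort("Arc-length interval must lie within a single trajectory segment.")
  }
  segs <- attr(traj, "segments")
  if (!is.null(segs)) {
    seg <- segs[[which(vapply(segs, `[[`, 0L, "segment") == seg_ids)]]
    if (t_a < seg$window[1] - 1e-9 || t_b > seg$window[2] + 1e-9) {
      abort("Requested times fall outside the fitted segment window.")
    }
    n_pts <- pts$time[pts$segment == seg_ids]
    dt <- median(diff(n_pts))
    m <- max(2L, ceiling((t_b - t_a) / dt * refine) + 1L)
    tt <- seq(t_a, t_b, length.out = m)
    q <- eval_segment(seg, tt)
  } else {
    sel <- pts$time >= t_a - 1e-12 & pts$time <= t_b + 1e-12
    q <- pts$fitted[sel]
    if (length(q) < 2L) return(0)
  }
  sum(Mod(diff(q)))
}

#' Reconstruct the breathing waveform by signed arc-length accumulation
#'
#' Walks the fitted trajectory grid accumulating chord arc length with a
#' sign flag (initialized to +1) that flips at every detected transition:
#' \eqn{S_i = S_{i-1} + \mathrm{flag} \times \Delta L_i}, \eqn{S_1 = 0}
#' per segment. The result is a respiration-like waveform whose peaks and
#' troughs fall at the breath transitions; the overall sign is an arbitrary
#' convention, since inhale/exhale identity is not observable from arc
#' length alone.
#'
#' The breathing rate is estimated per segment from the detected
#' transitions: the `(|T| - 1) / 2` full half-cycle pairs between the first
#' and last transition divided by that elapsed time (partial edge segments
#' excluded), then duration-weighted across segments. Per-cycle intervals
#' are gaps between alternate (same-direction) transitions.
#'
#' @param traj `fitted_trajectory` or `trajectory_path`.
#' @param transitions Output of [detect_transitions()] (or a numeric vector
#'   of transition times).
#' @param refine Refinement factor for per-step arc length on fitted
#'   trajectories.
#' @return Object of class `breath_result`: list with `waveform` (tibble
#'   `time`, `segment`, `S`, `flag`), `transitions`, `intervals` (tibble
#'   `onset`, `interval`, `segment`), `rate_bpm`, and `segment_rates`.
#' @export
build_waveform <- function(traj, transitions, refine = 4) {
  pts <- traj_points(traj)
  if (nrow(pts) == 0L) abort("Empty trajectory.")
  if (is.numeric(transitions)) {
    transitions <- tibble::tibble(time = sort(transitions),
                                  segment = NA_integer_,
                                  angle = NA_real_)
  }
  segs <- attr(traj, "segments")
  wave_rows <- list()
  int_rows <- list()
  seg_rates <- list()
  for (sid in unique(pts$segment)) {
    idx <- which(pts$segment == sid)
    t_seg <- pts$time[idx]
    q_seg <- pts$fitted[idx]
    n <- length(idx)
    # per-step arc length
    if (!is.null(segs)) {
      seg <- segs[[which(vapply(segs, `[[`, 0L, "segment") == sid)]]
      dl <- vapply(seq_len(n - 1L), function(i) {
        m <- refine + 1L
        tt <- seq(t_seg[i], t_seg[i + 1L], length.out = m)
        sum(Mod(diff(eval_segment(seg, tt))))
      }, numeric(1))
    } else {
      dl <- Mod(diff(q_seg))
    }
    tr <- transitions$time[transitions$time > t_seg[1] &
                             transitions$time <= t_seg[n]]
    flag <- numeric(n)
    flag[1] <- 1
    f <- 1
    S <- numeric(n)
    for (i in 2:n) {
      # the flip applies from the step that starts at the transition, so S
      # peaks exactly at the turning point
      if (any(tr >= t_seg[i - 1L] & tr < t_seg[i])) f <- -f
      flag[i] <- f
      S[i] <- S[i - 1L] + f * dl[i - 1L]
    }
    wave_rows[[length(wave_rows) + 1L]] <-
      tibble::tibble(time = t_seg, segment = sid, S = S, flag = flag)
    # intervals between alternate transitions (full cycles)
    if (length(tr) >= 3L) {
      onset <- tr[seq_len(length(tr) - 2L)]
      int_rows[[length(int_rows) + 1L]] <- tibble::tibble(
        onset = onset, interval = tr[-(1:2)] - onset, segment = sid
      )
    }
    if (length(tr) >= 2L) {
      span <- tr[length(tr)] - tr[1]
      # Robust half-cycle counting: each inter-transition gap is a whole
      # number of half-cycles (1 when no transition was missed); rounding
      # against the median half-gap restores the count when an occasional
      # turn fell below the detection threshold.
      gaps <- diff(tr)
      m_half <- median(gaps)
      halves <- sum(pmax(1, round(gaps / m_half)))
      seg_rates[[length(seg_rates) + 1L]] <- tibble::tibble(
        segment = sid, rate_bpm = 60 * (halves / 2) / span,
        span_s = span, n_transitions = length(tr)
      )
    }
  }
  segment_rates <- dplyr::bind_rows(seg_rates)
  rate <- if (nrow(segment_rates)) {
    sum(segment_rates$rate_bpm * segment_rates$span_s) /
      sum(segment_rates$span_s)
  } else {
    NA_real_
  }
  structure(list(
    waveform = dplyr::bind_rows(wave_rows),
    transitions = transitions,
    intervals = dplyr::bind_rows(int_rows),
    rate_bpm = rate,
    segment_rates = segment_rates
  ), class = "breath_result")
}

#' Extract breathing from a fitted trajectory
#'
#' Convenience wrapper chaining [turning_angles()], [detect_transitions()]
#' and [build_waveform()]. Turning angles are evaluated on a coarse grid
#' (`angle_step_s`) of the fitted basis: a step comparable to the shorter
#' inter-breath pause brackets each reversal with one approach and one
#' departure displacement, making the near-\eqn{\pi} turn robust to fit
#' wiggle, while the waveform itself is accumulated on the full grid.
#'
#' @param traj A `fitted_trajectory`.
#' @param threshold Turning-angle threshold (radians).
#' @param min_separation Transition thinning window (seconds).
#' @param chord_frac Chord length for turning-angle evaluation, as a
#'   fraction of the estimated half-breath arc length (see Details).
#' @param refine Arc-length refinement factor.
#'
#' @details Turning angles are evaluated on an arc-length-uniform
#'   resampling of the fitted curve rather than on the time grid. Near a
#'   breath transition the trajectory slows to a halt, so time-uniform
#'   displacements shrink toward the fit's noise floor and the reversal
#'   angle is diluted across many small, noisy steps; fixed-length chords
#'   keep every displacement large compared to that floor at any breathing
#'   rate. The chord is `chord_frac` times the half-breath arc estimated
#'   from the trajectory's own spatial extent (the breathing sweep
#'   traverses roughly the trajectory diameter each half-cycle), which
#'   makes the scale independent of the breathing rate: long enough to
#'   dominate fit noise, short enough that several chords fit in each
#'   half-cycle. Detected transition times are then refined to the local
#'   speed minimum of the densely evaluated curve (the stall point of the
#'   reversal), which restores timing precision lost to chord quantization.
#' @return A `breath_result`.
#' @export
extract_breathing <- function(traj, threshold = 2 * pi / 3,
                              min_separation = 0.8, chord_frac = 0.5,
                              refine = 4) {
  segs <- attr(traj, "segments")
  if (is.null(segs)) {
    ang <- turning_angles(traj)
    tr <- detect_transitions(ang, threshold, min_separation)
    return(build_waveform(traj, tr, refine = refine))
  }
  pts <- traj_points(traj)
  hits <- list()
  for (seg in segs) {
    idx <- which(pts$segment == seg$segment)
    dt <- median(diff(pts$time[idx]))
    dense_t <- seq(seg$window[1], seg$window[2], by = dt / 2)
    if (length(dense_t) < 5L) next
    q <- eval_segment(seg, dense_t)
    dl <- Mod(diff(q))
    cum <- c(0, cumsum(dl))
    L <- cum[length(cum)]
    if (L <= 0) next
    # half-breath arc from the trajectory's spatial extent: the sweep
    # covers ~ the diameter (2 x max deviation from the centroid) each
    # half-cycle, independent of breathing rate
    half_arc <- 1.7 * quantile(Mod(q - mean(q)), 0.98, names = FALSE)
    delta <- max(chord_frac * half_arc, 3 * max(dl))
    s_targets <- seq(0, L, by = delta)
    ai <- unique(pmin(findInterval(s_targets, cum), length(dense_t)))
    if (length(ai) < 3L) next
    ang <- turning_angles(as_trajectory(dense_t[ai], q[ai]))
    ang$segment <- seg$segment
    # A reversal landing mid-chord degenerates that chord (its net
    # displacement shrinks toward the fit noise floor), hiding the turn
    # from both adjacent angle pairs. The skip-one angle between the
    # chords on either side of each sample's outgoing chord bridges the
    # degenerate one, so one of the two readings always sees the turn.
    qa <- q[ai]
    d <- diff(qa)
    if (length(d) >= 3L) {
      a2 <- d[seq_len(length(d) - 2L)]
      b2 <- d[-(1:2)]
      mid <- d[seq(2L, length(d) - 1L)]
      dot2 <- Re(a2) * Re(b2) + Im(a2) * Im(b2)
      crs2 <- Re(a2) * Im(b2) - Im(a2) * Re(b2)
      # only bridge chords that really are degenerate: a straight chord of
      # arc length delta has net displacement ~ delta, a straddled
      # reversal much less
      skip <- ifelse(Mod(mid) < 0.6 * delta, atan2(abs(crs2), dot2), 0)
      ang$angle[seq_along(skip)] <- pmax(ang$angle[seq_along(skip)], skip)
    }
    # all over-threshold hits first (no thinning yet: hits from one turn
    # spread over neighboring arc samples, and thinning before refinement
    # can chain those clusters across adjacent turns at fast rates)
    det <- ang[ang$angle > threshold, , drop = FALSE]
    if (nrow(det) == 0L) next
    # refine each hit to the stall point: minimum speed of the dense curve
    # between the neighboring arc samples; hits from one turn collapse
    # onto the same stall time
    speed <- c(dl[1], (dl[-1] + dl[-length(dl)]) / 2, dl[length(dl)]) /
      (dt / 2)
    arc_times <- dense_t[ai]
    for (i in seq_len(nrow(det))) {
      k <- which.min(abs(arc_times - det$time[i]))
      lo <- arc_times[max(1L, k - 1L)]
      hi <- arc_times[min(length(arc_times), k + 1L)]
      win <- which(dense_t >= lo & dense_t <= hi)
      sp <- speed[win]
      j_min <- which.min(sp)
      # midpoint of the contiguous stall region around the minimum: more
      # stable under noise than the bare argmin
      stall <- sp <= min(sp) + 0.5 * (median(sp) - min(sp))
      j_lo <- j_min; while (j_lo > 1L && stall[j_lo - 1L]) j_lo <- j_lo - 1L
      j_hi <- j_min; while (j_hi < length(sp) && stall[j_hi + 1L]) j_hi <- j_hi + 1L
      det$time[i] <- (dense_t[win[j_lo]] + dense_t[win[j_hi]]) / 2
    }
    det <- det[order(det$time), , drop = FALSE]
    det <- detect_transitions(det, threshold = 1e-9,
                              min_separation = min_separation)
    hits[[length(hits) + 1L]] <- det
  }
  tr <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(time = numeric(), segment = integer(), angle = numeric())
  tr <- tr[order(tr$time), , drop = FALSE]
  build_waveform(traj, tr, refine = refine)
}

#' @export
print.breath_result <- function(x, ...) {
  cat("<breath_result>", sprintf("%.2f", x$rate_bpm), "breaths/min,",
      nrow(x$transitions), "transitions,",
      length(unique(x$waveform$segment)), "segment(s)\n")
  invisible(x)
}
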