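# Breathing-accuracy metrics: ACC, MAE, AER.

#' Breathing-interval accuracy (ACC)
#'
#' Scores detected breath intervals against reference intervals as the mean
#' over paired breaths of \eqn{(t_{ref} - |t_{ref} - t_{det}|)/t_{ref}}:
#' 1 for a perfect match, 0 when the detected interval is off by a full
#' reference interval, negative beyond that.
#'
#' Pairing: when both inputs carry onset times (data frames with `onset` and
#' `interval` columns), breaths are aligned by greedy nearest-onset one-to-one
#' matching gated at half the median reference interval; unmatched reference
#' breaths contribute an accuracy term of 0. Bare numeric vectors are paired
#' in order (and must then have compatible lengths, extra entries of either
#' side counting 0).
#'
#' @param reference,detected Numeric interval vectors (seconds), or data
#'   frames with columns `onset`, `interval` (e.g. the `intervals` element
#'   of a `breath_result`, or [truth_intervals()] output).
#' @param per_minute If `TRUE`, also attach a per-minute breakdown (mean
#'   term per minute of reference onset) as attribute `"per_minute"`.
#' @return The global mean accuracy (a scalar).
#' @export
breath_acc <- function(reference, detected, per_minute = FALSE) {
  pairs <- acc_pairs(reference, detected)
  if (nrow(pairs) == 0L) abort("No reference breaths to score.")
  acc <- mean(pairs$term)
  if (per_minute) {
    pm <- pairs |>
      dplyr::mutate(minute = floor(.data$onset / 60)) |>
      dplyr::group_by(.data$minute) |>
      dplyr::summarise(acc = mean(.data$term), n = dplyr::n(),
                       .groups = "drop")
    attr(acc, "per_minute") <- pm
  }
  acc
}

acc_pairs <- function(reference, detected) {
  ref <- normalize_intervals(reference)
  det <- normalize_intervals(detected)
  if (nrow(ref) == 0L) {
    return(tibble::tibble(onset = numeric(), term = numeric()))
  }
  if (is.null(ref$onset) || is.null(det$onset) ||
      anyNA(ref$onset) || anyNA(det$onset)) {
    # positional pairing
    n <- nrow(ref)
    term <- numeric(n)
    m <- min(n, nrow(det))
    if (m > 0) {
      tr <- ref$interval[seq_len(m)]
      td <- det$interval[seq_len(m)]
      term[seq_len(m)] <- (tr - abs(tr - td)) / tr
    }
    return(tibble::tibble(onset = ref$onset %||% seq_len(n) - 1, term = term))
  }
  gate <- 0.5 * median(ref$interval)
  used <- rep(FALSE, nrow(det))
  term <- numeric(nrow(ref))
  for (i in order(ref$onset)) {
    d <- abs(det$onset - ref$onset[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= gate) {
      used[j] <- TRUE
      term[i] <- (ref$interval[i] - abs(ref$interval[i] - det$interval[j])) /
        ref$interval[i]
    }  # else unmatched: contributes 0
  }
  tibble::tibble(onset = ref$onset, term = term)
}

normalize_intervals <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("interval" %in% names(x))
    tibble::tibble(onset = x$onset %||% rep(NA_real_, nrow(x)),
                   interval = x$interval)
  } else {
    tibble::tibble(onset = rep(NA_real_, length(x)),
                   interval = as.numeric(x))
  }
}

#' Mean absolute error of normalized waveforms (MAE)
#'
#' Resamples the reference waveform onto the extracted waveform's time base
#' (linear interpolation), min-max normalizes both signals to [0, 1], and
#' returns the mean absolute difference. Min-max normalization makes the
#' metric invariant to affine rescaling of either raw signal; a constant
#' signal has no normalization and is an error.
#'
#' @param extracted,reference Data frames with columns `time`, `value`, or
#'   bare numeric vectors (then assumed already on a common base).
#' @return Mean absolute error in [0, 1] for signals of matched support.
#' @export
breath_mae <- function(extracted, reference) {
  if (is.data.frame(extracted)) {
    tx <- extracted$time; x <- extracted$value
  } else {
    tx <- seq_along(extracted); x <- as.numeric(extracted)
  }
  if (is.data.frame(reference)) {
    g <- approx(reference$time, reference$value, tx, rule = 2)$y
  } else {
    g <- as.numeric(reference)
    if (length(g) != length(x)) {
      g <- approx(seq_along(g), g, seq(1, length(g), length.out = length(x)))$y
    }
  }
  mean(abs(minmax(x) - minmax(g)))
}

minmax <- function(v) {
  r <- range(v)
  if (diff(r) < .Machine$double.eps * max(1, abs(r[2]))) {
    abort("Min-max normalization undefined for a constant signal.")
  }
  (v - r[1]) / diff(r)
}

#' Absolute error rate of breathing frequency (AER)
#'
#' The absolute difference between the reference and detected breathing
#' rates, in breaths per minute.
#'
#' @param rate_reference,rate_detected Rates in breaths/minute (`>= 0`).
#' @return `|rate_reference - rate_detected|`, breaths/minute.
#' @export
breath_aer <- function(rate_reference, rate_detected) {
  abs(rate_reference - rate_detected)
}

#' Reference breath intervals from simulator ground truth
#'
#' Converts a `breath_truth`'s transition times (alternating trough/peak)
#' into per-breath cycle intervals: each transition is an onset and the
#' interval runs to the next transition of the same type (two transitions
#' later), mirroring how detected intervals are built.
#'
#' @param truth A `breath_truth` (see [simulate_displacement()]) or a
#'   numeric vector of transition times.
#' @return Tibble `onset`, `interval`.
#' @export
truth_intervals <- function(truth) {
  tt <- if (inherits(truth, "breath_truth")) truth$transition_times else
    sort(as.numeric(truth))
  if (length(tt) < 3L) {
    return(tibble::tibble(onset = numeric(), interval = numeric()))
  }
  onset <- tt[seq_len(length(tt) - 2L)]
  tibble::tibble(onset = onset, interval = tt[-(1:2)] - onset)
}

#' Score a breathing extraction against ground truth
#'
#' Computes the full metrics report for a `breath_result` against a
#' `breath_truth`: interval accuracy (ACC), mean absolute error of the
#' min-max-normalized waveforms (MAE), and the absolute rate error (AER).
#' Because the arc-length waveform's sign convention is arbitrary, MAE is
#' reported for the orientation (S or -S) that matches the reference better.
#'
#' @param result A `breath_result`.
#' @param truth A `breath_truth`.
#' @return One-row tibble: `acc`, `mae`, `aer`, `rate_detected_bpm`,
#'   `rate_reference_bpm`, `n_breaths_detected`.
#' @export
evaluate_breathing <- function(result, truth) {
  stopifnot(inherits(result, "breath_result"),
            inherits(truth, "breath_truth"))
  acc <- breath_acc(truth_intervals(truth), result$intervals)
  ref_wave <- tibble::tibble(time = truth$displacement$time,
                             value = truth$displacement$displacement)
  mae <- NA_real_
  wav <- result$waveform
  if (nrow(wav) >= 2L) {
    per_seg <- lapply(split(wav, wav$segment), function(w) {
      if (nrow(w) < 2L) return(NULL)
      ext <- tibble::tibble(time = w$time, value = w$S)
      ext_neg <- tibble::tibble(time = w$time, value = -w$S)
      tibble::tibble(
        mae = min(breath_mae(ext, ref_wave), breath_mae(ext_neg, ref_wave)),
        w = diff(range(w$time))
      )
    })
    per_seg <- dplyr::bind_rows(per_seg)
    if (nrow(per_seg)) mae <- sum(per_seg$mae * per_seg$w) / sum(per_seg$w)
  }
  tibble::tibble(
    acc = acc, mae = mae, aer = breath_aer(truth$rate_bpm, result$rate_bpm),
    rate_detected_bpm = result$rate_bpm,
    rate_reference_bpm = truth$rate_bpm,
    n_breaths_detected = nrow(result$intervals)
  )
}
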