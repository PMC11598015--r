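# CSI table and ground-truth serialization.
#
# The CSI table is a plain CSV with a mandatory header and normative column
# order: timestamp_s, tx, rx, subcarrier, freq_hz, re, im. There is no
# public standard for CSI dumps; vendor binary formats are out of scope.

csi_table_cols <- c("timestamp_s", "tx", "rx", "subcarrier", "freq_hz",
                    "re", "im")

#' Write a CSI table to CSV
#'
#' @param csi CSI tibble with columns `time`, `tx`, `rx`, `subcarrier`,
#'   `freq_hz`, `csi` (complex).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csi_table <- function(csi, path) {
  out <- tibble::tibble(
    timestamp_s = csi$time, tx = csi$tx, rx = csi$rx,
    subcarrier = csi$subcarrier, freq_hz = csi$freq_hz,
    re = Re(csi$csi), im = Im(csi$csi)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a CSI table from CSV
#'
#' Validates the schema (all columns present and numeric) and enforces
#' strictly increasing timestamps within every (tx, rx, subcarrier) stream,
#' naming the offending stream and row on violation.
#'
#' @param path Input file path.
#' @return CSI tibble (`time`, `tx`, `rx`, `subcarrier`, `freq_hz`, `csi`).
#' @export
read_csi_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("CSI table not found: ", path), class = "input_error")
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot parse CSI table: ",
                                     conditionMessage(e)),
                              class = "input_error")
  )
  missing <- setdiff(csi_table_cols, names(raw))
  if (length(missing)) {
    abort(paste0("CSI table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "input_error")
  }
  if (nrow(raw) == 0L) {
    return(tibble::tibble(time = numeric(), tx = integer(), rx = integer(),
                          subcarrier = integer(), freq_hz = numeric(),
                          csi = complex()))
  }
  for (col in csi_table_cols) {
    if (!is.numeric(raw[[col]])) {
      abort(paste0("CSI table column '", col, "' must be numeric."),
            class = "input_error")
    }
  }
  csi <- tibble::tibble(
    time = raw$timestamp_s, tx = as.integer(raw$tx),
    rx = as.integer(raw$rx), subcarrier = as.integer(raw$subcarrier),
    freq_hz = raw$freq_hz, csi = raw$re + 1i * raw$im
  )
  check <- csi |>
    dplyr::group_by(.data$tx, .data$rx, .data$subcarrier) |>
    dplyr::summarise(bad = {
      d <- diff(.data$time)
      if (any(d <= 0)) which(d <= 0)[1] + 1L else NA_integer_
    }, .groups = "drop")
  bad <- check[!is.na(check$bad), , drop = FALSE]
  if (nrow(bad)) {
    abort(sprintf(
      "Non-monotone timestamps in stream tx=%d rx=%d subcarrier=%d at row %d of that stream.",
      bad$tx[1], bad$rx[1], bad$subcarrier[1], bad$bad[1]
    ), class = "input_error")
  }
  csi
}

#' Write / read the simulator ground truth sidecar (JSON)
#'
#' The sidecar records the transition times, true rate, motion windows,
#' seed, and the sampled displacement, so that extraction results can be
#' scored without rerunning the simulator.
#'
#' @param truth A `breath_truth`.
#' @param path File path.
#' @return `path` invisibly (write); a `breath_truth` (read).
#' @export
write_sim_truth <- function(truth, path) {
  payload <- list(
    rate_bpm = truth$rate_bpm,
    n_cycles = truth$n_cycles,
    transition_times = truth$transition_times,
    seed = truth$seed,
    motion_bursts = truth$motion_bursts,
    displacement = list(
      time = truth$displacement$time,
      displacement = truth$displacement$displacement,
      motion = truth$displacement$motion
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Truth sidecar not found: ", path), class = "input_error")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  mb <- p$motion_bursts
  if (!is.null(mb) && !is.data.frame(mb)) mb <- as.data.frame(mb)
  structure(list(
    displacement = tibble::tibble(
      time = p$displacement$time,
      displacement = p$displacement$displacement,
      motion = p$displacement$motion %||% rep(FALSE, length(p$displacement$time))
    ),
    transition_times = p$transition_times,
    rate_bpm = p$rate_bpm,
    n_cycles = p$n_cycles,
    motion_bursts = mb,
    seed = p$seed
  ), class = "breath_truth")
}

#' Export a breathing result to a directory
#'
#' Writes `waveform.csv` (time, S, flag, segment, and the motion mask column
#' of the ratio grid), `transitions.json` (times and angles) and `rate.json`
#' (rate summary with provenance).
#'
#' @param result A `breath_result` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_breath_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wav <- result$waveform
  if (!is.null(result$ratio)) {
    mask <- result$ratio |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(motion = any(.data$motion), .groups = "drop")
    wav <- dplyr::left_join(wav, mask, by = "time")
  }
  readr::write_csv(wav, file.path(dir, "waveform.csv"))
  jsonlite::write_json(
    list(times = result$transitions$time, angles = result$transitions$angle),
    file.path(dir, "transitions.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(rate_bpm = result$rate_bpm,
         segment_rates = result$segment_rates,
         provenance = attr(result, "provenance")),
    file.path(dir, "rate.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  invisible(dir)
}
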