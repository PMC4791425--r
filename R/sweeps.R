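#' Bundle one cell's current-clamp sweeps with the stimulus protocol
#'
#' A `sweep_set` holds everything recorded from one neuron that the feature
#' extractors need: the current-clamp voltage sweeps (one per injected current
#' level), the stimulus protocol, and optionally a voltage-clamp trace for
#' spontaneous postsynaptic currents and a ramp trace for the sodium current.
#'
#' @param cell_id Cell identifier (single string).
#' @param time Shared time base in seconds (uniformly sampled).
#' @param voltages Numeric matrix, `length(time)` rows by one column per
#'   sweep, in mV.
#' @param sampling_rate Sampling rate in Hz.
#' @param stim_amplitudes Injected current per sweep in pA (one per column of
#'   `voltages`). The default protocol steps current upward across sweeps.
#' @param stim_window Length-2 numeric, start and end of the current pulse in
#'   seconds. The default pulse duration is 0.5 s.
#' @param vc_trace Optional data frame `(time_s, current_pa)`: a voltage-clamp
#'   recording for PSC detection.
#' @param ramp_trace Optional data frame `(time_s, current_pa)`: response to a
#'   voltage ramp, for the sodium-current amplitude.
#' @param unexcitable Logical flag marking a cell that never fired during the
#'   recording session (its AP features are reported as not detected).
#'
#' @return An object of class `sweep_set`.
#' @seealso [extract_cell_features()], [read_sweep_csv()]
#' @export
sweep_set <- function(cell_id, time, voltages, sampling_rate, stim_amplitudes,
                      stim_window = c(0.1, 0.6), vc_trace = NULL,
                      ramp_trace = NULL, unexcitable = FALSE) {
  voltages <- as.matrix(voltages)
  assert_uniform_time(time)
  if (nrow(voltages) != length(time)) {
    abort("voltages must have one row per time sample", class = "patchseqr_malformed")
  }
  if (length(stim_amplitudes) != ncol(voltages)) {
    abort("need one stimulus amplitude per sweep", class = "patchseqr_malformed")
  }
  if (stim_window[1] < time[1] || stim_window[2] > time[length(time)]) {
    abort("stim_window must lie inside the trace extent", class = "patchseqr_malformed")
  }
  structure(
    list(
      cell_id = as.character(cell_id),
      time = as.numeric(time),
      voltages = voltages,
      sampling_rate = sampling_rate,
      stim_amplitudes = as.numeric(stim_amplitudes),
      stim_window = as.numeric(stim_window),
      vc_trace = vc_trace,
      ramp_trace = ramp_trace,
      unexcitable = isTRUE(unexcitable)
    ),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> cell %s: %d sweeps x %d samples @ %g Hz, pulse %g-%g s\n",
    x$cell_id, ncol(x$voltages), nrow(x$voltages), x$sampling_rate,
    x$stim_window[1], x$stim_window[2]
  ))
  cat(sprintf(
    "  stim %g..%g pA%s%s%s\n",
    min(x$stim_amplitudes), max(x$stim_amplitudes),
    if (!is.null(x$vc_trace)) ", vc trace" else "",
    if (!is.null(x$ramp_trace)) ", ramp trace" else "",
    if (x$unexcitable) ", unexcitable" else ""
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.sweep_set <- function(x, ...) {
  tibble(
    cell_id = x$cell_id,
    sweep = rep(seq_len(ncol(x$voltages)), each = nrow(x$voltages)),
    stim_pa = rep(x$stim_amplitudes, each = nrow(x$voltages)),
    time_s = rep(x$time, ncol(x$voltages)),
    voltage_mv = as.vector(x$voltages)
  )
}

#' Extract a single sweep as a (time, voltage) data frame
#'
#' @param x A [sweep_set()].
#' @param i Sweep index (column of the voltage matrix).
#' @return A tibble with columns `time_s` and `voltage_mv`.
#' @export
get_sweep <- function(x, i) {
  stopifnot(inherits(x, "sweep_set"), i >= 1, i <= ncol(x$voltages))
  tibble(time_s = x$time, voltage_mv = x$voltages[, i])
}

#' Read and write per-cell sweep CSV files
#'
#' One CSV per cell: `#`-prefixed header lines carry the protocol metadata
#' (`cell_id`, `sampling_rate_hz`, `stim_amplitudes_pa`, `stim_window_s`,
#' `unexcitable`), then a header row and one column of time (s) followed by
#' one voltage column (mV) per sweep. Companion files `<stem>_vc.csv` and
#' `<stem>_ramp.csv`, when present next to the sweep file, are read as the
#' voltage-clamp and ramp traces (`time_s, current_pa`).
#'
#' @param path CSV file path (for writing, companion traces are written next
#'   to it).
#' @return `read_sweep_csv()` returns a [sweep_set()]; `write_sweep_csv()`
#'   returns `path` invisibly.
#' @export
read_sweep_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  stem <- sub("\\.csv$", "", path)
  read_side <- function(suffix) {
    p <- paste0(stem, suffix)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  sweep_set(
    cell_id = meta$cell_id %||% basename(stem),
    time = body[[1L]],
    voltages = as.matrix(body[, -1L, drop = FALSE]),
    sampling_rate = as.numeric(meta$sampling_rate_hz),
    stim_amplitudes = as.numeric(strsplit(meta$stim_amplitudes_pa, "\\s+")[[1L]]),
    stim_window = as.numeric(strsplit(meta$stim_window_s, "\\s+")[[1L]]),
    vc_trace = read_side("_vc.csv"),
    ramp_trace = read_side("_ramp.csv"),
    unexcitable = identical(meta$unexcitable, "TRUE")
  )
}

#' @rdname read_sweep_csv
#' @param x A [sweep_set()] to write.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  header <- c(
    paste0("# cell_id: ", x$cell_id),
    paste0("# sampling_rate_hz: ", format(x$sampling_rate, digits = 15)),
    paste0("# stim_amplitudes_pa: ",
           paste(format(x$stim_amplitudes, digits = 15, trim = TRUE), collapse = " ")),
    paste0("# stim_window_s: ",
           paste(format(x$stim_window, digits = 15, trim = TRUE), collapse = " ")),
    paste0("# unexcitable: ", x$unexcitable)
  )
  body <- data.frame(time_s = x$time, x$voltages, check.names = FALSE)
  colnames(body) <- c("time_s", paste0("sweep_", seq_len(ncol(x$voltages))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(body, con, row.names = FALSE)
  stem <- sub("\\.csv$", "", path)
  if (!is.null(x$vc_trace)) readr::write_csv(x$vc_trace, paste0(stem, "_vc.csv"))
  if (!is.null(x$ramp_trace)) readr::write_csv(x$ramp_trace, paste0(stem, "_ramp.csv"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
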