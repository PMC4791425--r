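#' Detect action-potential peaks in a current-clamp sweep
#'
#' A spike is a local voltage maximum preceded (within `max_rise_ms`) by an
#' upward crossing of the dV/dt criterion and rising at least `min_amp_mv`
#' above the crossing voltage (so noise wiggles on a charging membrane are
#' not counted). Detections closer together than `refractory_ms` are merged,
#' keeping the larger peak.
#'
#' @param sweep Data frame with time (s) in column 1 and voltage (mV) in
#'   column 2, uniformly sampled.
#' @param dvdt_thresh Slope criterion in mV/ms marking spike initiation
#'   (default 10).
#' @param max_rise_ms Longest allowed onset-to-peak interval (ms).
#' @param refractory_ms Minimum separation between detected peaks (ms).
#' @param min_amp_mv Minimum rise from the dV/dt crossing to the peak (mV).
#' @return A tibble with one row per spike: `index` (sample of the peak),
#'   `time_s`, `peak_mv`. Zero rows when the sweep has no spikes.
#' @export
detect_spikes <- function(sweep, dvdt_thresh = 10, max_rise_ms = 10,
                          refractory_ms = 2, min_amp_mv = 10) {
  stopifnot(dvdt_thresh > 0)
  tr <- as_trace(sweep)
  dv <- dvdt_mv_per_ms(tr$value, tr$dt)
  n <- length(tr$value)
  up <- which(dv[-n] < dvdt_thresh & dv[-1L] >= dvdt_thresh) + 1L
  if (length(up) == 0L) {
    return(tibble(index = integer(0), time_s = numeric(0), peak_mv = numeric(0)))
  }
  win <- max(1L, round(max_rise_ms / 1000 / tr$dt))
  peaks <- integer(0)
  for (i in up) {
    j_end <- min(n, i + win)
    seg <- tr$value[i:j_end]
    pk_rel <- which.max(seg)
    pk <- i + pk_rel - 1L
    if (pk >= n) next
    # a genuine spike rises well above the crossing voltage ...
    if (tr$value[pk] - tr$value[i] < min_amp_mv) next
    # ... and repolarises afterwards (a charging ramp never does)
    fall_end <- min(n, pk + win)
    if (min(tr$value[(pk + 1L):fall_end]) > tr$value[pk] - min_amp_mv / 2) next
    peaks <- c(peaks, pk)
  }
  if (length(peaks) == 0L) {
    return(tibble(index = integer(0), time_s = numeric(0), peak_mv = numeric(0)))
  }
  # merge detections within the refractory window, keep the larger peak
  refr <- refractory_ms / 1000
  keep <- integer(0)
  for (pk in sort(unique(peaks))) {
    if (length(keep) > 0L && (tr$time[pk] - tr$time[keep[length(keep)]]) < refr) {
      if (tr$value[pk] > tr$value[keep[length(keep)]]) keep[length(keep)] <- pk
    } else {
      keep <- c(keep, pk)
    }
  }
  tibble(index = keep, time_s = tr$time[keep], peak_mv = tr$value[keep])
}

#' Action-potential threshold: membrane potential at spike onset
#'
#' The onset is the last dV/dt upcrossing of `dvdt_thresh` before the spike
#' peak; the threshold is the voltage at that sample.
#'
#' @inheritParams detect_spikes
#' @param spike_index Peak sample index, from [detect_spikes()].
#' @param search_ms How far before the peak to search for the onset (ms).
#' @return Threshold in mV, or `NA` (not detected) when no onset is found.
#' @export
ap_threshold <- function(sweep, spike_index, dvdt_thresh = 10, search_ms = 20) {
  tr <- as_trace(sweep)
  dv <- dvdt_mv_per_ms(tr$value, tr$dt)
  from <- max(1L, spike_index - round(search_ms / 1000 / tr$dt))
  if (spike_index <= from) return(NA_real_)
  seg <- from:(spike_index - 1L)
  below <- dv[seg] < dvdt_thresh
  if (all(below)) return(NA_real_)
  # onset = first sample of the last run of dV/dt >= criterion before the peak
  above <- which(!below)
  runs_start <- above[c(TRUE, diff(above) > 1L)]
  onset <- seg[runs_start[length(runs_start)]]
  tr$value[onset]
}

#' Action-potential shape features relative to threshold
#'
#' Amplitude is peak voltage minus threshold; rise time is the interval from
#' the (interpolated) threshold crossing to the peak; halfwidth is the
#' interval between the interpolated up- and down-crossings of
#' threshold + amplitude/2.
#'
#' @inheritParams ap_threshold
#' @param threshold Threshold voltage in mV (from [ap_threshold()]).
#' @return One-row tibble with `rise_time_ms`, `amplitude_mv`,
#'   `halfwidth_ms` (`NA` when the sweep ends before the half-amplitude
#'   down-crossing).
#' @export
ap_shape_features <- function(sweep, spike_index, threshold) {
  tr <- as_trace(sweep)
  n <- length(tr$value)
  v_peak <- tr$value[spike_index]
  if (!is.finite(threshold) || threshold >= v_peak) {
    abort("threshold must lie below the peak voltage", class = "patchseqr_malformed")
  }
  amplitude <- v_peak - threshold
  half <- threshold + amplitude / 2

  # onset: last crossing of `threshold` before the peak (interpolated)
  pre <- which(tr$value[1:(spike_index - 1L)] <= threshold &
                 tr$value[2:spike_index] > threshold)
  t_onset <- if (length(pre) > 0L) {
    interp_crossing(tr$time, tr$value, pre[length(pre)], threshold)
  } else {
    NA_real_
  }
  rise_time <- if (is.na(t_onset)) NA_real_ else (tr$time[spike_index] - t_onset) * 1000

  # half-amplitude crossings around the peak
  up <- which(tr$value[1:(spike_index - 1L)] < half &
                tr$value[2:spike_index] >= half)
  t_up <- if (length(up) > 0L) {
    interp_crossing(tr$time, tr$value, up[length(up)], half)
  } else {
    NA_real_
  }
  halfwidth <- NA_real_
  if (!is.na(t_up) && spike_index < n) {
    after <- spike_index:(n - 1L)
    down <- which(tr$value[after] >= half & tr$value[after + 1L] < half)
    if (length(down) > 0L) {
      t_down <- interp_crossing(tr$time, tr$value, after[down[1L]], half)
      halfwidth <- (t_down - t_up) * 1000
    }
  }
  tibble(rise_time_ms = rise_time, amplitude_mv = amplitude,
         halfwidth_ms = halfwidth)
}

#' Maximal firing rate across a sweep family
#'
#' The maximal firing frequency over sweeps: spike count inside the stimulus
#' window divided by the pulse duration, maximised over sweeps. Returns 0 Hz
#' for a cell that never spikes, and `NA` (not detected) when the sweep set
#' is flagged unexcitable.
#'
#' @param x A [sweep_set()].
#' @inheritParams detect_spikes
#' @return Firing rate in Hz (scalar).
#' @export
firing_rate <- function(x, dvdt_thresh = 10) {
  stopifnot(inherits(x, "sweep_set"))
  if (ncol(x$voltages) == 0L) {
    abort("empty sweep set", class = "patchseqr_malformed")
  }
  dur <- diff(x$stim_window)
  counts <- spike_counts(x, dvdt_thresh)
  if (all(counts == 0L) && x$unexcitable) return(NA_real_)
  max(counts) / dur
}

# spike count per sweep, restricted to the stimulus window
spike_counts <- function(x, dvdt_thresh = 10) {
  vapply(seq_len(ncol(x$voltages)), function(s) {
    sp <- detect_spikes(get_sweep(x, s), dvdt_thresh)
    sum(sp$time_s >= x$stim_window[1] & sp$time_s < x$stim_window[2])
  }, integer(1))
}

#' Input resistance from the first current step
#'
#' Rin = |mean voltage deflection from the pre-pulse baseline| / |first
#' stimulus amplitude|, measured in a configurable window after pulse onset
#' (late enough in the pulse for the membrane to have charged).
#'
#' @param x A [sweep_set()]; sweep 1 must be the first (hyperpolarising)
#'   current level.
#' @param window Length-2 numeric: measurement window in seconds relative to
#'   pulse onset.
#' @return Input resistance in MOhm (positive).
#' @export
input_resistance <- function(x, window = c(0.2, 0.45)) {
  stopifnot(inherits(x, "sweep_set"))
  i1 <- x$stim_amplitudes[1L]
  if (i1 == 0) abort("undefined Rin: first stimulus amplitude is zero")
  v <- x$voltages[, 1L]
  base <- x$time < x$stim_window[1]
  if (!any(base)) abort("no pre-pulse baseline available", class = "patchseqr_malformed")
  meas <- x$time >= x$stim_window[1] + window[1] &
    x$time <= x$stim_window[1] + window[2]
  defl <- mean(v[meas]) - mean(v[base])
  abs(defl) / abs(i1) * 1000   # mV / pA = GOhm -> MOhm
}

#' Extract the full nine-parameter phenotype for one cell
#'
#' Runs all feature extractors on a [sweep_set()]. The AP shape parameters
#' (threshold, rise time, halfwidth, amplitude) are taken from the first
#' spike of the rheobase sweep (the lowest current step that elicits a
#' spike), where the waveform is least distorted by adaptation. Cells
#' without any spike report those four parameters as `NA` (not detected) and
#' a firing rate of 0 Hz (or `NA` when flagged unexcitable).
#'
#' @param x A [sweep_set()].
#' @param dvdt_thresh Spike-initiation slope criterion (mV/ms).
#' @param lowpass Optional low-pass cutoff in Hz applied (zero-phase) before
#'   feature extraction; `NULL` disables filtering.
#' @param psc_amp_thresh Event amplitude threshold for PSC detection (pA).
#' @return One-row tibble: `cell_id` plus the nine parameter columns
#'   `threshold`, `rise_time`, `halfwidth`, `amplitude`, `firing_rate`,
#'   `rin`, `na_current`, `freq_epsc`, `freq_ipsc`.
#' @export
extract_cell_features <- function(x, dvdt_thresh = 10, lowpass = NULL,
                                  psc_amp_thresh = 15) {
  stopifnot(inherits(x, "sweep_set"))
  if (!is.null(lowpass)) {
    x$voltages <- apply(x$voltages, 2, lowpass_filter,
                        sampling_rate = x$sampling_rate, cutoff_hz = lowpass)
  }
  counts <- spike_counts(x, dvdt_thresh)
  dur <- diff(x$stim_window)
  fr <- if (all(counts == 0L) && x$unexcitable) NA_real_ else max(counts) / dur

  thr <- rt <- hw <- amp <- NA_real_
  rheo <- which(counts > 0L)
  if (length(rheo) > 0L) {
    sw <- get_sweep(x, rheo[1L])
    sp <- detect_spikes(sw, dvdt_thresh)
    sp <- sp[sp$time_s >= x$stim_window[1] & sp$time_s < x$stim_window[2], ]
    if (nrow(sp) > 0L) {
      idx <- sp$index[1L]
      thr <- ap_threshold(sw, idx, dvdt_thresh)
      if (!is.na(thr) && thr < sp$peak_mv[1L]) {
        shape <- ap_shape_features(sw, idx, thr)
        rt <- shape$rise_time_ms
        amp <- shape$amplitude_mv
        hw <- shape$halfwidth_ms
      }
    }
  }

  rin <- input_resistance(x)

  na_amp <- if (!is.null(x$ramp_trace)) na_current_amplitude(x$ramp_trace) else NA_real_

  f_e <- f_i <- NA_real_
  if (!is.null(x$vc_trace)) {
    psc <- detect_psc_events(x$vc_trace, amp_thresh = psc_amp_thresh)
    f_e <- psc$freq_epsc_hz
    f_i <- psc$freq_ipsc_hz
  }

  tibble(
    cell_id = x$cell_id, threshold = thr, rise_time = rt, halfwidth = hw,
    amplitude = amp, firing_rate = fr, rin = rin, na_current = na_amp,
    freq_epsc = f_e, freq_ipsc = f_i
  )
}

#' Assemble per-cell feature rows into the parameter table
#'
#' @param cells Either a list of [sweep_set()] objects (features are
#'   extracted) or a list/data frame of one-row feature tibbles from
#'   [extract_cell_features()].
#' @param ... Passed to [extract_cell_features()] when `cells` contains
#'   sweep sets.
#' @return A tibble with one row per cell and the nine parameter columns;
#'   `NA` entries are not-detected (ND) values. The ND mask is available via
#'   `is.na()` on the parameter columns.
#' @export
build_parameter_table <- function(cells, ...) {
  if (is.data.frame(cells)) {
    tbl <- as_tibble(cells)
  } else {
    rows <- purrr::map(cells, function(cl) {
      if (inherits(cl, "sweep_set")) extract_cell_features(cl, ...) else as_tibble(cl)
    })
    tbl <- dplyr::bind_rows(rows)
  }
  missing_cols <- setdiff(c("cell_id", EPHYS_PARAMS), names(tbl))
  if (length(missing_cols) > 0L) {
    abort(paste("missing parameter columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tbl$cell_id)) {
    abort(paste("duplicate cell_id:",
                paste(unique(tbl$cell_id[duplicated(tbl$cell_id)]), collapse = ", ")))
  }
  neg_freq <- c("firing_rate", "freq_epsc", "freq_ipsc")
  for (cn in neg_freq) {
    if (any(tbl[[cn]] < 0, na.rm = TRUE)) abort(paste("negative", cn))
  }
  dplyr::select(tbl, dplyr::all_of(c("cell_id", EPHYS_PARAMS)))
}

#' Read and write the parameter table with an explicit ND token
#'
#' Not-detected values are written as the literal token `"ND"` (never as an
#' empty field or zero) and read back as `NA`.
#'
#' @param path CSV path.
#' @return `read_param_table()` returns the parameter tibble;
#'   `write_param_table()` returns `path` invisibly.
#' @export
read_param_table <- function(path) {
  tbl <- readr::read_csv(path, na = "ND", show_col_types = FALSE,
                         col_types = readr::cols(cell_id = "c", .default = "d"))
  build_parameter_table(tbl)
}

#' @rdname read_param_table
#' @param tbl Parameter tibble from [build_parameter_table()].
#' @export
write_param_table <- function(tbl, path) {
  out <- tbl
  for (cn in EPHYS_PARAMS) out[[cn]] <- as.character(out[[cn]])
  out[is.na(out)] <- "ND"
  readr::write_csv(out, path)
  invisible(path)
}
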