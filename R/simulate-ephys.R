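#' Simulate a patch-clamp recording session for one neuron
#'
#' Generates the full per-cell recording bundle a Patch-seq rig would produce:
#' a family of 0.5-s current-step sweeps (passive charging plus stereotyped
#' action-potential waveforms stamped at known spike times), a 10-s
#' voltage-clamp trace with planted postsynaptic-current events, and a ramp
#' trace with a planted inward sodium current. Every quantity the feature
#' extractors estimate (threshold, rise time, halfwidth, amplitude, firing
#' rate, input resistance, Na amplitude, PSC times) is known analytically, so
#' the simulator doubles as the extractors' ground-truth oracle.
#'
#' Cell parameters interpolate linearly with the maturity coordinate
#' `m` in \[0, 1\]: input resistance 800 to 150 MOhm, AP amplitude 40 to 90 mV,
#' halfwidth 4 to 1 ms, threshold -30 to -45 mV, maximal steady firing 2 to
#' 40 Hz, sodium current 200 to 2000 pA, PSC rate 0.1 to 2 Hz. Cells with
#' `m < 0.1` may be unexcitable (no spikes in any sweep), which produces the
#' not-detected AP entries the downstream imputation step handles.
#'
#' @param m Maturity in \[0, 1\].
#' @param cell_id Identifier for the cell.
#' @param seed Integer seed; the same seed reproduces the bundle bit for bit.
#' @param noise_mv Recording noise s.d. on the voltage traces (mV); the
#'   default matches a 2-kHz-filtered whole-cell recording.
#' @param sampling_rate Hz; the default matches a 5-kHz acquisition.
#' @param stim_amplitudes Injected currents in pA, one sweep each. The default
#'   protocol starts with a -20 pA step (for input resistance) and increases
#'   in 10 pA increments.
#' @param with_vc,with_ramp Include the voltage-clamp PSC trace / ramp trace.
#'
#' @return A list with elements `sweeps` (a [sweep_set()]) and `truth`, a list
#'   of the planted parameter values (`threshold_mv`, `rise_time_ms`,
#'   `halfwidth_ms`, `amplitude_mv`, `firing_rate_hz`, `rin_mohm`,
#'   `na_current_pa`, `psc_times_s`, `psc_classes`, `freq_epsc_hz`,
#'   `freq_ipsc_hz`, `spike_counts`, `unexcitable`, `maturity`).
#' @export
simulate_cell <- function(m, cell_id = "cell", seed = 1L, noise_mv = 0.2,
                          sampling_rate = 5000,
                          stim_amplitudes = c(-20, seq(10, 200, by = 10)),
                          with_vc = TRUE, with_ramp = TRUE) {
  stopifnot(m >= 0, m <= 1)
  set.seed(seed)

  # maturity-interpolated cell parameters
  rin <- 800 + m * (150 - 800)        # MOhm
  amp <- 40 + m * (90 - 40)           # mV, threshold-to-peak
  hw <- 4 + m * (1 - 4)               # ms
  thr <- -30 + m * (-45 - -30)        # mV
  fmax <- 2 + m * (40 - 2)            # Hz
  ina <- 200 + m * (2000 - 200)       # pA
  psc_rate <- 0.1 + m * (2 - 0.1)     # Hz
  rise <- 3 + m * (0.8 - 3)           # ms
  v_rest <- -65
  cap_pf <- 30                        # pF -> tau = rin * cap
  tau_s <- rin * cap_pf * 1e-6        # MOhm * pF = us

  unexcitable <- m < 0.1 && stats::runif(1) < 0.5

  dt <- 1 / sampling_rate
  pre_s <- 0.1
  pulse_s <- 0.5
  post_s <- 0.1
  time <- seq(0, pre_s + pulse_s + post_s - dt, by = dt)
  n_t <- length(time)
  stim_window <- c(pre_s, pre_s + pulse_s)
  in_pulse <- time >= stim_window[1] & time < stim_window[2]
  t_in <- time - stim_window[1]

  # rheobase and firing-rate curve: spike count is monotone in current
  i_rheo <- (thr - v_rest) * 1000 / rin   # pA
  n_spikes_at <- function(i_pa) {
    if (unexcitable || i_pa <= i_rheo) return(0L)
    f <- fmax * min(1, (i_pa - i_rheo) / 60)
    as.integer(floor(f * pulse_s + 1e-9))
  }
  counts <- vapply(stim_amplitudes, n_spikes_at, integer(1))

  fall <- 2 * hw - rise                 # triangle: halfwidth = (rise + fall)/2
  plateau <- thr - 0.5                  # suprathreshold inter-spike voltage

  voltages <- matrix(v_rest, n_t, length(stim_amplitudes))
  for (s in seq_along(stim_amplitudes)) {
    i_pa <- stim_amplitudes[s]
    v <- rep(v_rest, n_t)
    defl <- i_pa * rin / 1000           # mV at steady state
    charge <- defl * (1 - exp(-pmax(t_in, 0) / tau_s))
    v[in_pulse] <- v_rest + charge[in_pulse]
    # decay after pulse
    post <- time >= stim_window[2]
    v[post] <- v_rest + defl * (1 - exp(-pulse_s / tau_s)) *
      exp(-(time[post] - stim_window[2]) / tau_s)
    # membrane cannot sit above spike threshold
    v <- pmin(v, plateau)
    n_sp <- counts[s]
    if (n_sp > 0L) {
      sp_t <- stim_window[1] + (seq_len(n_sp) - 0.5) / n_sp * pulse_s
      for (st in sp_t) {
        i0 <- which.min(abs(time - st))
        # linear rise from threshold to peak, linear fall back to threshold
        n_rise <- max(2L, round(rise / 1000 / dt))
        n_fall <- max(2L, round(fall / 1000 / dt))
        idx_r <- i0:min(n_t, i0 + n_rise)
        v[idx_r] <- thr + (seq_along(idx_r) - 1L) / n_rise * amp
        pk <- min(n_t, i0 + n_rise)
        idx_f <- pk:min(n_t, pk + n_fall)
        v[idx_f] <- (thr + amp) - (seq_along(idx_f) - 1L) / n_fall * amp
      }
    }
    voltages[, s] <- v
  }
  voltages <- voltages + matrix(stats::rnorm(n_t * length(stim_amplitudes),
                                             sd = noise_mv),
                                n_t, length(stim_amplitudes))

  truth <- list(
    maturity = m,
    threshold_mv = if (unexcitable) NA_real_ else thr,
    rise_time_ms = if (unexcitable) NA_real_ else rise,
    halfwidth_ms = if (unexcitable) NA_real_ else hw,
    amplitude_mv = if (unexcitable) NA_real_ else amp,
    firing_rate_hz = max(counts) / pulse_s,
    rin_mohm = rin,
    na_current_pa = ina,
    spike_counts = counts,
    unexcitable = unexcitable
  )

  vc <- NULL
  if (with_vc) {
    vc_dur <- 10
    vc_time <- seq(0, vc_dur - dt, by = dt)
    n_ev <- stats::rbinom(1, size = round(vc_dur * psc_rate * 2), prob = 0.5)
    ev_t <- sort(stats::runif(n_ev, 0.1, vc_dur - 0.2))
    # enforce separation so planted events are individually recoverable
    if (length(ev_t) > 1) {
      keep <- c(TRUE, diff(ev_t) > 0.1)
      ev_t <- ev_t[keep]
    }
    classes <- ifelse(stats::runif(length(ev_t)) < 0.6, "epsc", "ipsc")
    cur <- stats::rnorm(length(vc_time), sd = 4)
    for (k in seq_along(ev_t)) {
      tau_ms <- if (classes[k] == "epsc") 3 else 15
      ev_amp <- stats::runif(1, 25, 45)
      rel <- (vc_time - ev_t[k]) * 1000
      shape <- ifelse(rel >= 0, (1 - exp(-rel / 0.5)) * exp(-rel / tau_ms), 0)
      cur <- cur - ev_amp * shape
    }
    vc <- tibble(time_s = vc_time, current_pa = cur)
    truth$psc_times_s <- ev_t
    truth$psc_classes <- classes
    truth$freq_epsc_hz <- sum(classes == "epsc") / vc_dur
    truth$freq_ipsc_hz <- sum(classes == "ipsc") / vc_dur
  } else {
    truth$psc_times_s <- numeric(0)
    truth$psc_classes <- character(0)
    truth$freq_epsc_hz <- 0
    truth$freq_ipsc_hz <- 0
  }

  ramp <- NULL
  if (with_ramp) {
    ramp_time <- seq(0, 0.5 - dt, by = dt)
    drift <- 1200 * ramp_time^2            # outward K-like component
    dip <- -ina * exp(-((ramp_time - 0.15) / 0.004)^2)
    ramp <- tibble(
      time_s = ramp_time,
      current_pa = drift + dip + stats::rnorm(length(ramp_time), sd = 10)
    )
  }

  list(
    sweeps = sweep_set(
      cell_id = cell_id, time = time, voltages = voltages,
      sampling_rate = sampling_rate, stim_amplitudes = stim_amplitudes,
      stim_window = stim_window, vc_trace = vc, ramp_trace = ramp,
      unexcitable = unexcitable
    ),
    truth = truth
  )
}

#' Simulate a cohort of neurons spanning the maturity axis
#'
#' @param maturities Numeric vector of per-cell maturity values in \[0, 1\].
#'   The default spreads `n` cells evenly over the full range.
#' @param n Number of cells (ignored when `maturities` is given).
#' @param seed Base seed; cell `i` uses `seed * 1000 + i` so cells are
#'   independent but jointly reproducible.
#' @param ... Passed to [simulate_cell()].
#' @return A list with `cells` (list of per-cell bundles, named by cell id)
#'   and `truth` (tibble of planted parameters, one row per cell).
#' @export
simulate_cohort <- function(maturities = NULL, n = 20, seed = 1L, ...) {
  if (is.null(maturities)) maturities <- seq(0, 1, length.out = n)
  ids <- sprintf("Cell_%02d", seq_along(maturities))
  cells <- purrr::map2(maturities, seq_along(maturities), function(m, i) {
    simulate_cell(m, cell_id = ids[i], seed = seed * 1000L + i, ...)
  })
  names(cells) <- ids
  truth <- purrr::map2_dfr(cells, ids, function(cl, id) {
    tr <- cl$truth
    tibble(
      cell_id = id, maturity = tr$maturity, threshold = tr$threshold_mv,
      rise_time = tr$rise_time_ms, halfwidth = tr$halfwidth_ms,
      amplitude = tr$amplitude_mv, firing_rate = tr$firing_rate_hz,
      rin = tr$rin_mohm, na_current = tr$na_current_pa,
      freq_epsc = tr$freq_epsc_hz, freq_ipsc = tr$freq_ipsc_hz,
      unexcitable = tr$unexcitable
    )
  })
  list(cells = cells, truth = truth)
}
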