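#' Detect spontaneous postsynaptic currents in a voltage-clamp trace
#'
#' A simple documented detector: the trace is baseline-subtracted (global
#' median), lightly smoothed, and inward (negative) deflections exceeding
#' `amp_thresh` are taken as events, with a minimum inter-event interval.
#' Events are classified by their decay kinetics: the time for the deflection
#' to fall to 1/e of its peak. Decays faster than `class_tau_ms` are called
#' `"epsc"` (fast, excitatory-like), slower ones `"ipsc"`.
#'
#' @param vc_trace Data frame with time (s) in column 1 and current (pA) in
#'   column 2, uniformly sampled.
#' @param amp_thresh Event amplitude threshold in pA (> 0).
#' @param min_interval Minimum event separation in ms.
#' @param class_tau_ms Fast/slow decay boundary in ms (default 10).
#' @param smooth_ms Moving-average smoothing window in ms.
#' @return An object of class `psc_events`: a list with `events` (tibble:
#'   `time_s`, `amplitude_pa`, `decay_tau_ms`, `class`), `freq_hz`,
#'   `freq_epsc_hz`, `freq_ipsc_hz`, `duration_s`.
#' @export
detect_psc_events <- function(vc_trace, amp_thresh = 15, min_interval = 20,
                              class_tau_ms = 10, smooth_ms = 1) {
  stopifnot(amp_thresh > 0)
  tr <- as_trace(vc_trace)
  dur <- tr$time[length(tr$time)] - tr$time[1L] + tr$dt
  if (dur < 1) {
    warn("voltage-clamp trace shorter than 1 s; frequency estimate is noisy")
  }
  k <- max(1L, round(smooth_ms / 1000 / tr$dt))
  defl <- -(moving_average(tr$value, k) - stats::median(tr$value))  # inward positive
  n <- length(defl)

  above <- defl >= amp_thresh
  if (!any(above)) {
    ev <- tibble(time_s = numeric(0), amplitude_pa = numeric(0),
                 decay_tau_ms = numeric(0), class = character(0))
    return(structure(list(events = ev, freq_hz = 0, freq_epsc_hz = 0,
                          freq_ipsc_hz = 0, duration_s = dur),
                     class = "psc_events"))
  }
  # local maxima of the deflection above threshold
  cand <- which(above)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[defl[cand] >= defl[cand - 1L] & defl[cand] >= defl[cand + 1L]]
  cand <- cand[order(-defl[cand])]
  min_gap <- min_interval / 1000
  peaks <- integer(0)
  for (i in cand) {
    if (all(abs(tr$time[i] - tr$time[peaks]) >= min_gap)) peaks <- c(peaks, i)
  }
  peaks <- sort(peaks)

  tau <- vapply(peaks, function(i) {
    target <- defl[i] / exp(1)
    j_end <- min(n, i + round(0.1 / tr$dt))
    below <- which(defl[i:j_end] <= target)
    if (length(below) == 0L) return(NA_real_)
    (below[1L] - 1L) * tr$dt * 1000
  }, numeric(1))
  cls <- ifelse(is.na(tau) | tau > class_tau_ms, "ipsc", "epsc")

  ev <- tibble(time_s = tr$time[peaks], amplitude_pa = defl[peaks],
               decay_tau_ms = tau, class = cls)
  structure(
    list(events = ev, freq_hz = nrow(ev) / dur,
         freq_epsc_hz = sum(cls == "epsc") / dur,
         freq_ipsc_hz = sum(cls == "ipsc") / dur,
         duration_s = dur),
    class = "psc_events"
  )
}

#' @export
print.psc_events <- function(x, ...) {
  cat(sprintf("<psc_events> %d events in %.1f s (%.2f Hz; EPSC-like %.2f, IPSC-like %.2f)\n",
              nrow(x$events), x$duration_s, x$freq_hz, x$freq_epsc_hz, x$freq_ipsc_hz))
  invisible(x)
}

#' Peak inward sodium-current amplitude from a ramp trace
#'
#' The slow component of the ramp response (outward potassium current and
#' leak) is removed with a running median; the sodium current is the largest
#' inward (negative) residual deflection. Returns `NA` (not detected) when no
#' inward peak exceeds the noise floor (`noise_mult` robust s.d. of the
#' residual).
#'
#' @param ramp_trace Data frame with time (s) in column 1 and current (pA) in
#'   column 2; `NULL` returns `NA`.
#' @param baseline_ms Running-median window in ms (must be wide relative to
#'   the transient).
#' @param noise_mult Detection floor in multiples of the residual MAD.
#' @return Sodium-current magnitude in pA (positive), or `NA`.
#' @export
na_current_amplitude <- function(ramp_trace, baseline_ms = 50, noise_mult = 6) {
  if (is.null(ramp_trace)) return(NA_real_)
  tr <- as_trace(ramp_trace)
  k <- round(baseline_ms / 1000 / tr$dt)
  if (k %% 2L == 0L) k <- k + 1L
  base <- stats::runmed(tr$value, k, endrule = "median")
  resid <- moving_average(tr$value - base, max(1L, round(0.001 / tr$dt)))
  floor_pa <- noise_mult * stats::mad(resid)
  peak <- -min(resid)
  if (peak <= floor_pa) return(NA_real_)
  peak
}
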