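# Internal numeric helpers shared across feature extraction.

# Check a time base is uniformly sampled (relative tolerance on the step).
assert_uniform_time <- function(time, tol = 1e-6) {
  if (length(time) < 2L) {
    abort("trace must contain at least two samples", class = "patchseqr_malformed")
  }
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > tol * stats::median(dt)) {
    abort("non-uniform time base: samples must be evenly spaced",
          class = "patchseqr_malformed")
  }
  invisible(stats::median(dt))
}

# Coerce a two-column trace (time, value) data frame to a validated list.
as_trace <- function(x, value_col = 2L) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort("a trace must be a data frame with time and value columns",
          class = "patchseqr_malformed")
  }
  time <- as.numeric(x[[1L]])
  value <- as.numeric(x[[value_col]])
  dt <- assert_uniform_time(time)
  list(time = time, value = value, dt = dt)
}

# dV/dt in mV/ms for a voltage trace sampled every dt seconds.
# Forward difference; last element repeats so length is preserved.
dvdt_mv_per_ms <- function(voltage, dt) {
  d <- diff(voltage) / (dt * 1000)
  c(d, d[length(d)])
}

# Linearly interpolated time at which `values` crosses `level` between
# samples i and i+1 (assumes values[i] and values[i+1] bracket level).
interp_crossing <- function(time, values, i, level) {
  v0 <- values[i]
  v1 <- values[i + 1L]
  if (v1 == v0) return(time[i])
  time[i] + (level - v0) / (v1 - v0) * (time[i + 1L] - time[i])
}

# First index i in `idx` range where values crosses level upward; NA if none.
first_upcross <- function(values, level, from = 1L, to = length(values) - 1L) {
  if (to < from) return(NA_integer_)
  sub <- which(values[from:to] < level & values[(from + 1L):(to + 1L)] >= level)
  if (length(sub) == 0L) return(NA_integer_)
  from + sub[1L] - 1L
}

# Zero-phase low-pass Butterworth filter (2nd order), matching an acquisition
# anti-alias filter. cutoff_hz must be below Nyquist.
lowpass_filter <- function(voltage, sampling_rate, cutoff_hz = 2000) {
  if (cutoff_hz >= sampling_rate / 2) return(voltage)
  bf <- signal::butter(2, cutoff_hz / (sampling_rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, voltage))
}

# Moving-average smoother with an odd window (samples).
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) |>
    (\(y) {
      y[is.na(y)] <- x[is.na(y)]
      y
    })()
}
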