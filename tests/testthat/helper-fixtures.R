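# Fixture builders shared across tests. Everything is generated in code so
# the expected geometry (spike shape, crossings, planted structure) is known
# in closed form.

# A single triangular action potential riding on a flat baseline: a gentle
# sub-criterion approach ramp (5 mV/ms) from baseline up to `threshold`,
# then a linear rise to `threshold + amp` over `rise_ms` and a linear fall
# back over `fall_ms`. The dV/dt criterion (10 mV/ms) is first exceeded
# exactly at `threshold`, and for a triangle the half-amplitude width is
# (rise_ms + fall_ms) / 2 exactly.
make_triangle_spike <- function(baseline = -65, threshold = -40, amp = 70,
                                rise_ms = 1, fall_ms = 1, fs = 5000,
                                dur_s = 0.1, onset_s = 0.05) {
  dt <- 1 / fs
  tm <- seq(0, dur_s - dt, by = dt)
  v <- rep(baseline, length(tm))
  n_rise <- round(rise_ms / 1000 / dt)
  n_fall <- round(fall_ms / 1000 / dt)
  n_approach <- ceiling((threshold - baseline) / (5 * 1000 * dt))
  i0 <- which.min(abs(tm - onset_s))
  idx_a <- (i0 - n_approach):i0
  v[idx_a] <- seq(threshold - n_approach * 5 * 1000 * dt, threshold,
                  length.out = n_approach + 1)
  v[idx_a] <- pmax(v[idx_a], baseline)
  idx_r <- i0:(i0 + n_rise)
  v[idx_r] <- threshold + (seq_along(idx_r) - 1) / n_rise * amp
  pk <- i0 + n_rise
  idx_f <- pk:(pk + n_fall)
  v[idx_f] <- (threshold + amp) - (seq_along(idx_f) - 1) / n_fall * amp
  data.frame(time_s = tm, voltage_mv = v)
}

# Minimal sweep_set wrapping given voltage columns with a 0.5 s pulse.
make_sweep_set <- function(voltages, stim_amplitudes, fs = 5000,
                           stim_window = c(0.1, 0.6), cell_id = "c1",
                           unexcitable = FALSE) {
  tm <- seq(0, (nrow(as.matrix(voltages)) - 1) / fs, by = 1 / fs)
  sweep_set(cell_id, tm, as.matrix(voltages), fs, stim_amplitudes,
            stim_window, unexcitable = unexcitable)
}

# Small expression tibble with explicit classes.
make_expr <- function(values, classes = NULL, log2 = FALSE) {
  if (is.null(classes)) {
    classes <- stats::setNames(rep("neuron", ncol(values)), colnames(values))
  }
  expression_matrix(values, classes, log2 = log2)
}

# Adjusted Rand index between two label vectors (contingency form),
# independent of any clustering package.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
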