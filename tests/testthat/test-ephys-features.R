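test_that("spike detection finds planted peaks and nothing on flat traces", {
  dt <- 1 / 5000
  tm <- seq(0, 0.1 - dt, by = dt)
  flat <- data.frame(time_s = tm, voltage_mv = rep(-65, length(tm)))
  expect_identical(nrow(detect_spikes(flat)), 0L)

  sp <- make_triangle_spike()
  det <- detect_spikes(sp)
  expect_identical(nrow(det), 1L)
  expect_equal(det$peak_mv, max(sp$voltage_mv))
  expect_equal(det$index, which.max(sp$voltage_mv))

  # planted spikes in a simulated suprathreshold sweep are all recovered
  cl <- simulate_cell(0.7, seed = 1)
  counts_truth <- cl$truth$spike_counts
  s_best <- which.max(counts_truth)
  det_best <- detect_spikes(get_sweep(cl$sweeps, s_best))
  win <- cl$sweeps$stim_window
  in_win <- det_best$time_s >= win[1] & det_best$time_s < win[2]
  expect_identical(sum(in_win), max(counts_truth))
})

test_that("spike detection rejects a non-uniform time base", {
  bad <- data.frame(time_s = c(0, 0.001, 0.003, 0.004),
                    voltage_mv = rep(-65, 4))
  expect_error(detect_spikes(bad), class = "patchseqr_malformed")
})

test_that("spike count is monotone non-decreasing in injected current", {
  for (seed in c(2, 5, 11)) {
    cl <- simulate_cell(0.8, seed = seed, with_vc = FALSE, with_ramp = FALSE)
    counts <- vapply(seq_along(cl$sweeps$stim_amplitudes), function(s) {
      det <- detect_spikes(get_sweep(cl$sweeps, s))
      win <- cl$sweeps$stim_window
      sum(det$time_s >= win[1] & det$time_s < win[2])
    }, integer(1))
    pos <- cl$sweeps$stim_amplitudes > 0
    expect_true(all(diff(counts[pos]) >= 0))
    expect_identical(counts, cl$truth$spike_counts)
  }
})

test_that("AP threshold is the voltage at the dV/dt onset", {
  # linear rise at 70 mV/ms starting exactly at -40 mV
  sp <- make_triangle_spike(threshold = -40, amp = 70, rise_ms = 1)
  det <- detect_spikes(sp)
  thr <- ap_threshold(sp, det$index)
  expect_equal(thr, -40, tolerance = 1e-6)

  # criterion above the waveform's maximal slope: no onset
  expect_true(is.na(ap_threshold(sp, det$index, dvdt_thresh = 500)))

  # simulated AP: onset voltage within 1 mV of the planted threshold
  cl <- simulate_cell(0.5, seed = 1, with_vc = FALSE, with_ramp = FALSE)
  s <- which(cl$truth$spike_counts > 0)[1]
  sw <- get_sweep(cl$sweeps, s)
  det <- detect_spikes(sw)
  expect_lt(abs(ap_threshold(sw, det$index[1]) - cl$truth$threshold_mv), 1)
})

test_that("AP shape features match the triangle's closed-form geometry", {
  sp <- make_triangle_spike(threshold = -40, amp = 70, rise_ms = 1, fall_ms = 1)
  det <- detect_spikes(sp)
  shape <- ap_shape_features(sp, det$index, -40)
  expect_equal(shape$amplitude_mv, 70, tolerance = 0.01)
  expect_equal(shape$rise_time_ms, 1, tolerance = 0.01)
  # symmetric triangle: halfwidth equals the rise time
  expect_equal(shape$halfwidth_ms, 1, tolerance = 0.01)

  # asymmetric triangle: halfwidth = (rise + fall) / 2
  sp2 <- make_triangle_spike(rise_ms = 1, fall_ms = 3)
  det2 <- detect_spikes(sp2)
  shape2 <- ap_shape_features(sp2, det2$index, -40)
  expect_equal(shape2$halfwidth_ms, 2, tolerance = 0.01)

  # truncated sweep ending at the peak: halfwidth not detected
  cut <- sp[seq_len(det$index), ]
  shape3 <- ap_shape_features(cut, det$index, -40)
  expect_equal(shape3$amplitude_mv, 70, tolerance = 0.01)
  expect_true(is.na(shape3$halfwidth_ms))
})

test_that("shape features are invariant under a voltage offset", {
  sp <- make_triangle_spike()
  det <- detect_spikes(sp)
  base <- ap_shape_features(sp, det$index, ap_threshold(sp, det$index))
  shifted <- sp
  shifted$voltage_mv <- shifted$voltage_mv + 13
  det2 <- detect_spikes(shifted)
  thr2 <- ap_threshold(shifted, det2$index)
  expect_equal(thr2, ap_threshold(sp, det$index) + 13, tolerance = 1e-6)
  off <- ap_shape_features(shifted, det2$index, thr2)
  expect_equal(off$amplitude_mv, base$amplitude_mv, tolerance = 1e-6)
  expect_equal(off$halfwidth_ms, base$halfwidth_ms, tolerance = 1e-6)
  expect_equal(off$rise_time_ms, base$rise_time_ms, tolerance = 1e-6)
})

test_that("amplitude and firing rate survive 2x resampling", {
  cl <- simulate_cell(0.6, seed = 4, with_vc = FALSE, with_ramp = FALSE)
  fr1 <- firing_rate(cl$sweeps)
  s <- which(cl$truth$spike_counts > 0)[1]
  sw <- get_sweep(cl$sweeps, s)
  det <- detect_spikes(sw)
  amp1 <- ap_shape_features(sw, det$index[1],
                            ap_threshold(sw, det$index[1]))$amplitude_mv

  # linear 2x upsampling of every sweep
  tm2 <- seq(cl$sweeps$time[1], max(cl$sweeps$time), by = 1 / 10000)
  v2 <- apply(cl$sweeps$voltages, 2, function(v) {
    stats::approx(cl$sweeps$time, v, xout = tm2)$y
  })
  up <- sweep_set(cl$sweeps$cell_id, tm2, v2, 10000,
                  cl$sweeps$stim_amplitudes, cl$sweeps$stim_window)
  expect_equal(firing_rate(up), fr1)
  sw2 <- get_sweep(up, s)
  det2 <- detect_spikes(sw2)
  amp2 <- ap_shape_features(sw2, det2$index[1],
                            ap_threshold(sw2, det2$index[1]))$amplitude_mv
  # within one original sample interval worth of voltage slope
  expect_lt(abs(amp2 - amp1), 2)
})

test_that("firing rate is the maximal windowed spike count over the pulse", {
  # 10 stamped spikes in the 0.5 s pulse -> 20 Hz
  cl <- simulate_cell(0.45, seed = 6, with_vc = FALSE, with_ramp = FALSE)
  expect_equal(firing_rate(cl$sweeps), max(cl$truth$spike_counts) / 0.5)

  # spikeless cell: 0 Hz; flagged unexcitable: not detected
  flat <- make_sweep_set(matrix(-65, 3500, 2), c(-20, 10))
  expect_equal(firing_rate(flat), 0)
  flat_ux <- make_sweep_set(matrix(-65, 3500, 2), c(-20, 10),
                            unexcitable = TRUE)
  expect_true(is.na(firing_rate(flat_ux)))
})

test_that("input resistance recovers deflection over current", {
  # -4 mV deflection at -20 pA -> 200 MOhm
  tm <- seq(0, 3499 / 5000, by = 1 / 5000)
  in_pulse <- tm >= 0.1 & tm < 0.6
  v <- matrix(-65, 3500, 1)
  v[in_pulse, 1] <- -69
  ss <- make_sweep_set(v, -20)
  expect_equal(input_resistance(ss), 200, tolerance = 1e-6)

  # -10 mV at -50 pA -> same 200 MOhm
  v2 <- matrix(-65, 3500, 1)
  v2[in_pulse, 1] <- -75
  expect_equal(input_resistance(make_sweep_set(v2, -50)), 200, tolerance = 1e-6)

  expect_error(input_resistance(make_sweep_set(v, 0)), "undefined Rin")

  # simulated passive membrane: within 5 % of the planted resistance
  cl <- simulate_cell(0.9, seed = 3, with_vc = FALSE, with_ramp = FALSE)
  expect_lt(abs(input_resistance(cl$sweeps) - cl$truth$rin_mohm) /
              cl$truth$rin_mohm, 0.05)
})

test_that("parameter table enforces its shape, ND contract and round-trips", {
  co <- simulate_cohort(n = 4, seed = 2, with_vc = FALSE, with_ramp = FALSE)
  tbl <- build_parameter_table(lapply(co$cells, function(x) x$sweeps))
  expect_identical(dim(tbl), c(4L, 10L))
  expect_identical(names(tbl)[1], "cell_id")

  # a cell with no APs: AP shape parameters ND, firing rate 0
  flat <- make_sweep_set(matrix(-65 + rnorm(3500 * 2, sd = 0.2), 3500, 2),
                         c(-20, 10), cell_id = "quiet")
  row <- extract_cell_features(flat)
  expect_true(all(is.na(row[c("threshold", "rise_time", "halfwidth", "amplitude")])))
  expect_equal(row$firing_rate, 0)

  dup <- dplyr::bind_rows(tbl[1, ], tbl[1, ])
  expect_error(build_parameter_table(dup), "duplicate cell_id")

  # ND token round-trip
  tbl$halfwidth[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_param_table(tbl, path)
  expect_true(any(grepl("ND", readLines(path))))
  back <- read_param_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})
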