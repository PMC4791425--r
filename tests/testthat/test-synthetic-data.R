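test_that("the cell simulator is deterministic and spans the maturity axis", {
  a <- simulate_cell(0.5, seed = 7)
  b <- simulate_cell(0.5, seed = 7)
  expect_identical(a$sweeps$voltages, b$sweeps$voltages)
  expect_identical(a$truth, b$truth)

  hi <- simulate_cell(1, seed = 2, with_vc = FALSE, with_ramp = FALSE)
  lo <- simulate_cell(0, seed = 2, with_vc = FALSE, with_ramp = FALSE)
  expect_gte(firing_rate(hi$sweeps), max(firing_rate(lo$sweeps), 0, na.rm = TRUE))

  # an unexcitable immature draw has no spikes and ND AP features
  found_ux <- FALSE
  for (seed in 1:20) {
    cl <- simulate_cell(0.02, seed = seed, with_vc = FALSE, with_ramp = FALSE)
    if (cl$truth$unexcitable) {
      found_ux <- TRUE
      expect_true(all(cl$truth$spike_counts == 0L))
      expect_true(is.na(cl$truth$threshold_mv))
      row <- extract_cell_features(cl$sweeps)
      expect_true(is.na(row$threshold))
      expect_true(is.na(row$firing_rate))
      break
    }
  }
  expect_true(found_ux)
})

test_that("extracted parameters correlate with planted maturity in the expected directions", {
  co <- simulate_cohort(n = 20, seed = 77)
  params <- build_parameter_table(lapply(co$cells, function(x) x$sweeps))
  imp <- impute_nd(params)
  m <- co$truth$maturity
  pos <- c("firing_rate", "amplitude", "na_current")
  neg <- c("halfwidth", "rin", "rise_time", "threshold")
  for (p in pos) expect_gte(cor(imp[[p]], m), 0.6)
  for (p in neg) expect_lte(cor(imp[[p]], m), -0.6)
})

test_that("expression simulator plants programs consistent with its ground truth", {
  cfg <- synthetic_config(n_genes = 600,
                          module_sizes = c(100, 60, 30), n_candidates = 30,
                          n_external_overlap = 10, n_low_expr = 20,
                          n_factors = 10, seed = 44)
  ex <- simulate_expression(cfg)
  tr <- ex$truth
  expect_identical(length(tr$neuron_specific), 100L)
  expect_identical(length(intersect(tr$neuron_specific, tr$maturation_up)), 0L)
  expect_identical(length(intersect(tr$maturation_up, tr$maturation_down)), 0L)
  expect_true(all(tr$candidates %in% tr$maturation_up))
  expect_identical(length(tr$external_overlap), 10L)

  vals <- expr_values(ex$expr)
  neurons <- expr_samples(ex$expr, "neuron")
  contrast <- expr_samples(ex$expr, "contrast")
  # neuron-specific genes higher in neurons; low-expression genes under floor
  ns_gap <- rowMeans(log2(vals[tr$neuron_specific, neurons] + 1)) -
    rowMeans(log2(vals[tr$neuron_specific, contrast] + 1))
  expect_true(all(ns_gap > 1))
  expect_true(all(vals[tr$low_expr, ] < 0.1))

  # noiseless limit: maturation-down genes are perfectly anti-correlated
  # with maturity (Dim1 proxy = -maturity)
  cfg0 <- synthetic_config(n_genes = 600,
                           module_sizes = c(100, 60, 30), n_candidates = 30,
                           n_external_overlap = 10, n_low_expr = 20,
                           n_factors = 0, noise_sd = 1e-9, seed = 45)
  ex0 <- simulate_expression(cfg0)
  lv <- log2(expr_values(ex0$expr)[ex0$truth$maturation_down,
                                   expr_samples(ex0$expr, "neuron")] + 1)
  rr <- cor(t(lv), cfg0$maturities)
  expect_true(all(rr < -0.999))
})

test_that("zero effect size makes planted maturation genes null-like", {
  cfg <- synthetic_config(n_genes = 500, module_sizes = c(50, 80, 80),
                          n_candidates = 10, n_external_overlap = 5,
                          n_low_expr = 10, n_factors = 0,
                          effect_size = 0, seed = 46)
  ex <- simulate_expression(cfg)
  scores <- tibble::tibble(
    cell_id = expr_samples(ex$expr, "neuron"),
    dim1 = -unname(ex$truth$maturities)
  )
  filt <- filter_expressed(ex$expr)
  res <- gene_dim1_correlation(filt, scores)
  planted <- res[res$gene %in% c(ex$truth$maturation_up,
                                 ex$truth$maturation_down), ]
  sel <- mean(planted$r > 0.4 & planted$p < 0.05 |
                planted$r < -0.4 & planted$p < 0.05)
  expect_lte(sel, 0.1)  # about alpha, with sampling slack
})

test_that("the on-disk bundle is complete, reproducible, and guarded", {
  cfg <- synthetic_config(n_neurons = 4, n_contrast = 3, n_genes = 300,
                          module_sizes = c(60, 30, 20), n_candidates = 10,
                          n_external_overlap = 5, n_low_expr = 10,
                          n_factors = 5, seed = 9)
  dir1 <- withr::local_tempdir()
  out <- generate_dataset(file.path(dir1, "bundle"), cfg)
  paths <- out$paths
  expect_true(file.exists(paths$expression))
  expect_true(file.exists(paths$classes))
  expect_true(file.exists(paths$gmt))
  expect_true(file.exists(paths$external))
  expect_true(file.exists(paths$truth))
  expect_identical(length(list.files(paths$sweeps, pattern = "^Cell_\\d+\\.csv$")), 4L)

  # refusing to clobber
  expect_error(generate_dataset(file.path(dir1, "bundle"), cfg), "not empty")

  # byte-identical regeneration from the same seed
  dir2 <- withr::local_tempdir()
  generate_dataset(file.path(dir2, "bundle"), cfg)
  f1 <- list.files(file.path(dir1, "bundle"), recursive = TRUE, full.names = TRUE)
  f2 <- list.files(file.path(dir2, "bundle"), recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # sweep CSV round-trip preserves the sweep set
  ss <- out$cohort$cells[[1]]$sweeps
  back <- read_sweep_csv(list.files(paths$sweeps, pattern = "^Cell_01",
                                    full.names = TRUE)[1])
  expect_equal(back$voltages, ss$voltages, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$stim_amplitudes, ss$stim_amplitudes)
  expect_equal(back$stim_window, ss$stim_window)
  expect_equal(as.data.frame(back$vc_trace), as.data.frame(ss$vc_trace),
               tolerance = 1e-10)
})

test_that("expression matrix read back from the bundle matches the simulation", {
  cfg <- synthetic_config(n_neurons = 4, n_contrast = 3, n_genes = 300,
                          module_sizes = c(60, 30, 20), n_candidates = 10,
                          n_external_overlap = 5, n_low_expr = 10,
                          n_factors = 5, seed = 9)
  dir <- withr::local_tempdir()
  out <- generate_dataset(file.path(dir, "bundle"), cfg)
  m <- read_expression(out$paths$expression, out$paths$classes)
  expect_equal(expr_values(m), expr_values(out$expression$expr),
               tolerance = 1e-9)
  expect_identical(expr_classes(m), expr_classes(out$expression$expr))
  ext <- read_gene_list(out$paths$external)
  expect_identical(ext, out$expression$truth$external_list)
})
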