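#' Configuration of the synthetic Patch-seq study
#'
#' Defaults reproduce the study design the pipeline targets: 20 recorded
#' neurons spanning the immature-to-mature range, 21 non-neuronal (blood-
#' like) contrast samples, and an expression matrix with planted structure —
#' a neuron-specific gene block (the "blue module" analogue), a
#' maturation-up program (rising with maturity; magenta-cluster analogue),
#' and a maturation-down program (falling with maturity; green-cluster
#' analogue). The maturation programs live only in neuron samples. A subset
#' of the maturation-up genes (`n_candidates`) additionally carries the
#' neuron-vs-contrast offset: they are both neuron-specific and
#' mature-enriched, i.e. the planted biomarker candidates — the analogue of
#' the genes shared between the magenta cluster and the blue module — and
#' the synthetic external list shares exactly `n_external_overlap` of them.
#'
#' @param n_neurons Number of recorded neurons (default 20).
#' @param n_contrast Number of contrast samples (default 21).
#' @param n_genes Total genes in the matrix (default 2000).
#' @param module_sizes Named or positional integer vector:
#'   (neuron_specific, maturation_up, maturation_down) planted program sizes
#'   (default 300, 120, 60).
#' @param n_candidates How many maturation-up genes also carry the neuron
#'   offset (planted biomarker candidates; default 60).
#' @param n_external_overlap Planted overlap between the biomarker
#'   candidates and the synthetic external maturity list (default 39).
#' @param effect_size Log2 fold-change amplitude of the maturation programs
#'   across the full maturity range (default 2).
#' @param neuron_offset Log2 offset of neuron-program genes over contrast
#'   samples (default 4).
#' @param noise_sd Log2-scale residual s.d. (default 0.5).
#' @param n_factors Latent background factors (shared housekeeping-style
#'   variation) with follower counts falling off as 1/rank; these give the
#'   background the heterogeneous, heavy-tailed co-expression structure of
#'   real transcriptomes (default 40).
#' @param factor_scale Log2 s.d. of the latent factor signal (default 1,
#'   giving within-factor correlations in the 0.5-0.7 range typical of real
#'   co-expression modules).
#' @param n_low_expr Genes forced below the 0.1-FPKM floor everywhere, to
#'   exercise the expression filter (default 80).
#' @param maturities Optional per-neuron maturity vector in \[0, 1\];
#'   defaults to an even grid spanning the full range.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_neurons = 20, n_contrast = 21, n_genes = 2000,
                             module_sizes = c(neuron_specific = 300,
                                              maturation_up = 120,
                                              maturation_down = 60),
                             n_candidates = 60, n_external_overlap = 39,
                             effect_size = 2, neuron_offset = 4,
                             noise_sd = 0.5, n_factors = 40,
                             factor_scale = 1, n_low_expr = 80,
                             maturities = NULL, seed = 15L) {
  stopifnot(all(module_sizes > 0), n_candidates <= module_sizes[2],
            n_external_overlap <= n_candidates,
            sum(module_sizes) + n_low_expr < n_genes)
  if (is.null(maturities)) maturities <- seq(0, 1, length.out = n_neurons)
  stopifnot(length(maturities) == n_neurons,
            min(maturities) >= 0, max(maturities) <= 1)
  structure(
    list(n_neurons = n_neurons, n_contrast = n_contrast, n_genes = n_genes,
         module_sizes = module_sizes, n_candidates = n_candidates,
         n_external_overlap = n_external_overlap, effect_size = effect_size,
         neuron_offset = neuron_offset, noise_sd = noise_sd,
         n_factors = n_factors, factor_scale = factor_scale,
         n_low_expr = n_low_expr, maturities = maturities,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate the structured FPKM expression matrix
#'
#' Log2-FPKM values are built additively: per-gene baseline, plus the neuron
#' offset for neuron-program genes in neuron samples, plus the maturity
#' gradient (`effect_size * m` for maturation-up genes, `effect_size *
#' (1 - m)` for maturation-down genes) in neuron samples only, plus Gaussian
#' noise; the matrix is then back-transformed to FPKM. Contrast samples
#' carry no neuron program. A block of genes is forced below 0.1 FPKM
#' everywhere.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A list with `expr` (expression tibble, FPKM scale),
#'   `truth` (list: `neuron_specific`, `maturation_up`, `maturation_down`,
#'   `candidates` — the maturation-up genes carrying the neuron offset,
#'   `neuron_block` — all offset-carrying genes, `external_list`,
#'   `external_overlap`, `low_expr`, `maturities` named by neuron id).
#' @export
simulate_expression <- function(cfg = synthetic_config(), seed = NULL) {
  set.seed(seed %||% cfg$seed)
  n_s <- cfg$n_neurons + cfg$n_contrast
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  neurons <- sprintf("Cell_%02d", seq_len(cfg$n_neurons))
  contrast <- sprintf("a%d", seq_len(cfg$n_contrast))
  samples <- c(neurons, contrast)
  is_neuron <- c(rep(TRUE, cfg$n_neurons), rep(FALSE, cfg$n_contrast))
  m <- cfg$maturities

  ms <- cfg$module_sizes
  idx_ns <- seq_len(ms[1])
  idx_up <- ms[1] + seq_len(ms[2])
  idx_down <- ms[1] + ms[2] + seq_len(ms[3])
  idx_low <- ms[1] + ms[2] + ms[3] + seq_len(cfg$n_low_expr)
  idx_cand <- idx_up[seq_len(cfg$n_candidates)]

  baseline <- stats::runif(cfg$n_genes, 1, 5)   # log2(FPKM+1) scale
  log_expr <- matrix(rep(baseline, n_s), cfg$n_genes, n_s)

  # neuron-vs-contrast offset: the neuron-specific block plus the
  # biomarker-candidate subset of the maturation-up program
  off_rows <- c(idx_ns, idx_cand)
  log_expr[off_rows, is_neuron] <- log_expr[off_rows, is_neuron] + cfg$neuron_offset

  # maturity gradients (neuron samples only)
  log_expr[idx_up, is_neuron] <- log_expr[idx_up, is_neuron] +
    matrix(rep(cfg$effect_size * m, each = length(idx_up)),
           length(idx_up), cfg$n_neurons)
  log_expr[idx_down, is_neuron] <- log_expr[idx_down, is_neuron] +
    matrix(rep(cfg$effect_size * (1 - m), each = length(idx_down)),
           length(idx_down), cfg$n_neurons)

  # latent background factors: follower counts fall off as 1/rank, giving
  # the heavy-tailed connectivity spectrum of real co-expression data
  idx_bg <- setdiff(seq_len(cfg$n_genes), c(idx_ns, idx_up, idx_down, idx_low))
  if (cfg$n_factors > 0 && length(idx_bg) > 0) {
    w <- 1 / seq_len(cfg$n_factors)
    sizes_f <- pmax(1L, round(length(idx_bg) * 0.7 * w / sum(w)))
    assign_f <- rep(seq_len(cfg$n_factors), times = sizes_f)
    assign_f <- assign_f[seq_len(min(length(assign_f), length(idx_bg)))]
    fac <- matrix(stats::rnorm(cfg$n_factors * n_s), cfg$n_factors, n_s)
    load <- stats::runif(length(assign_f), 0.4, 1) * cfg$factor_scale
    rows <- idx_bg[seq_along(assign_f)]
    log_expr[rows, ] <- log_expr[rows, ] + load * fac[assign_f, , drop = FALSE]
  }

  log_expr <- log_expr + matrix(stats::rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
                                cfg$n_genes, n_s)
  fpkm <- pmax(2^log_expr - 1, 0)
  fpkm[idx_low, ] <- matrix(stats::runif(length(idx_low) * n_s, 0, 0.09),
                            length(idx_low), n_s)
  dimnames(fpkm) <- list(genes, samples)

  classes <- stats::setNames(ifelse(is_neuron, "neuron", "contrast"), samples)
  expr <- expression_matrix(fpkm, classes, log2 = FALSE)

  cand_genes <- genes[idx_cand]
  ext_shared <- cand_genes[seq_len(cfg$n_external_overlap)]
  ext_filler <- sprintf("extgene%04d", seq_len(200))  # symbols absent from the matrix
  external <- tolower(c(ext_shared, ext_filler))      # exercises case normalisation

  truth <- list(
    neuron_specific = genes[idx_ns],
    maturation_up = genes[idx_up],
    maturation_down = genes[idx_down],
    candidates = cand_genes,
    neuron_block = genes[off_rows],
    low_expr = genes[idx_low],
    external_list = external,
    external_overlap = ext_shared,
    maturities = stats::setNames(m, neurons)
  )
  list(expr = expr, truth = truth)
}

#' Generate the full synthetic Patch-seq bundle on disk
#'
#' Writes everything the pipeline consumes, in the formats the readers
#' expect: one sweep CSV per neuron (plus `_vc`/`_ramp` companions), the
#' FPKM matrix TSV, the sample-class CSV, a GMT whose planted terms include
#' the neuron-specific and maturation programs (plus random decoy terms),
#' the external maturity gene list, and a `ground_truth.json` with the
#' planted values. Fully reproducible from the seed.
#'
#' @param dir Output directory.
#' @param cfg A [synthetic_config()].
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, a list with `cohort` (see [simulate_cohort()]),
#'   `expression` (see [simulate_expression()]) and the file `paths`.
#' @export
generate_dataset <- function(dir, cfg = synthetic_config(), force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force) {
    abort(paste("output directory is not empty:", dir, "(use force = TRUE)"))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sweep_dir <- file.path(dir, "sweeps")
  if (!dir.exists(sweep_dir)) dir.create(sweep_dir)

  cohort <- simulate_cohort(maturities = cfg$maturities, seed = cfg$seed)
  for (id in names(cohort$cells)) {
    write_sweep_csv(cohort$cells[[id]]$sweeps,
                    file.path(sweep_dir, paste0(id, ".csv")))
  }

  ex <- simulate_expression(cfg)
  write_expression(ex$expr, file.path(dir, "expression.tsv"))
  readr::write_csv(
    tibble(sample = names(expr_classes(ex$expr)),
           class = unname(expr_classes(ex$expr))),
    file.path(dir, "classes.csv")
  )

  # GMT: planted program terms plus random decoys drawn from the background
  set.seed(cfg$seed + 1L)
  all_genes <- ex$expr$gene
  background <- setdiff(all_genes, unlist(ex$truth[c("neuron_specific",
                                                     "maturation_up",
                                                     "maturation_down")]))
  decoys <- purrr::map(1:10, function(i) sample(background, 50))
  names(decoys) <- sprintf("DECOY_TERM_%02d", 1:10)
  coll <- c(
    list(NEURON_PROGRAM = ex$truth$neuron_specific,
         MATURATION_UP_PROGRAM = ex$truth$maturation_up,
         MATURATION_DOWN_PROGRAM = ex$truth$maturation_down),
    decoys
  )
  attr(coll, "descriptions") <- stats::setNames(
    c("planted neuron-specific program", "planted maturation-up program",
      "planted maturation-down program", rep("random decoy set", 10)),
    names(coll)
  )
  class(coll) <- "gene_set_collection"
  write_gmt(coll, file.path(dir, "gene_sets.gmt"))

  writeLines(ex$truth$external_list, file.path(dir, "external_list.txt"))

  truth_json <- c(
    ex$truth[c("neuron_specific", "maturation_up", "maturation_down",
               "candidates", "neuron_block", "low_expr", "external_overlap")],
    list(maturities = as.list(ex$truth$maturities),
         cell_truth = cohort$truth)
  )
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "columns")

  invisible(list(
    cohort = cohort, expression = ex,
    paths = list(
      sweeps = sweep_dir, expression = file.path(dir, "expression.tsv"),
      classes = file.path(dir, "classes.csv"),
      gmt = file.path(dir, "gene_sets.gmt"),
      external = file.path(dir, "external_list.txt"),
      truth = file.path(dir, "ground_truth.json")
    )
  ))
}
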