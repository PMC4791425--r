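#' Run the full Patch-seq maturation pipeline
#'
#' End-to-end driver: extract the nine-parameter electrophysiological
#' phenotype from per-cell sweep sets, build the oriented Dim1 maturity
#' index with three maturity groups, filter and log-transform the
#' expression matrix, construct the signed co-expression network and detect
#' modules, identify the neuron-specific module by gene-set enrichment,
#' correlate genes with Dim1 to form the green/magenta maturation clusters,
#' intersect the magenta cluster with the neuron module into candidate
#' biomarkers, and cross-reference an external maturity gene list.
#'
#' @param sweep_sets List of [sweep_set()] objects (or a directory of sweep
#'   CSVs).
#' @param expr Expression tibble in FPKM scale (or a TSV path; then
#'   `classes` must be given).
#' @param gmt A `gene_set_collection` or GMT path used both for enrichment
#'   reporting and to pick the neuron-specific module (the module whose
#'   best term has the smallest p).
#' @param external Character vector or file of external maturity gene
#'   symbols; `NULL` skips cross-referencing.
#' @param classes Sample-class map when `expr` is a path.
#' @param fpkm_min Expression floor (default 0.1).
#' @param r_min,alpha Maturation-cluster thresholds (default 0.4 / 0.05).
#' @param cfg A [network_config()].
#' @param neuron_term GMT term whose enrichment identifies the
#'   neuron-specific module; `NULL` uses each module's best term.
#' @return A list with `params`, `maturity`, `expr_filtered`, `network`,
#'   `enrichment` (per-module best-term table), `neuron_module` (label),
#'   `correlations`, `clusters`, `candidates`, `biomarkers`.
#' @export
run_pipeline <- function(sweep_sets, expr, gmt, external = NULL,
                         classes = NULL, fpkm_min = 0.1, r_min = 0.4,
                         alpha = 0.05, cfg = network_config(),
                         neuron_term = NULL) {
  if (is.character(sweep_sets) && length(sweep_sets) == 1L) {
    files <- list.files(sweep_sets, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!grepl("_(vc|ramp)\\.csv$", files)]
    sweep_sets <- purrr::map(files, read_sweep_csv)
  }
  if (is.character(expr) && length(expr) == 1L) {
    expr <- read_expression(expr, classes)
  }
  if (is.character(gmt) && length(gmt) == 1L) gmt <- read_gmt(gmt)

  params <- build_parameter_table(sweep_sets)
  maturity <- maturity_index(params)

  filtered <- filter_expressed(expr, fpkm_min = fpkm_min)
  net <- build_network(filtered, cfg = cfg)

  universe <- filtered$gene
  mod_labels <- setdiff(unique(net$modules$module), "grey")
  enr <- purrr::map_dfr(mod_labels, function(lab) {
    res <- fisher_enrichment(module_genes(net, lab), universe, gmt)
    res$module <- lab
    utils::head(res, 1)
  })
  neuron_module <- if (!is.null(neuron_term)) {
    scored <- purrr::map_dbl(mod_labels, function(lab) {
      res <- fisher_enrichment(module_genes(net, lab), universe, gmt)
      res$p[res$term == neuron_term]
    })
    mod_labels[which.min(scored)]
  } else {
    enr$module[which.min(enr$p)]
  }

  correlations <- gene_dim1_correlation(filtered, tidy(maturity))
  clusters <- threshold_clusters(correlations, r_min = r_min, alpha = alpha)
  candidates <- intersect_sets(clusters$magenta$gene,
                               module_genes(net, neuron_module))
  biomarkers <- if (!is.null(external)) {
    cross_reference_external(candidates, external)
  } else {
    NULL
  }

  list(
    params = params, maturity = maturity, expr_filtered = filtered,
    network = net, enrichment = enr, neuron_module = neuron_module,
    correlations = correlations, clusters = clusters,
    candidates = candidates, biomarkers = biomarkers
  )
}
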