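#' Correlate every gene with the Dim1 maturity axis
#'
#' Pearson correlation of each gene's log2(FPKM + 1) expression across the
#' neuron samples with the per-cell Dim1 score, with the classical
#' two-sided Student p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' n - 2 degrees of freedom. Constant genes get r = 0, p = 1. No
#' multiple-testing correction is applied (raw p-values are thresholded
#' downstream, a deliberate reproduction choice).
#'
#' @param m Expression tibble; contrast samples are dropped and values are
#'   log-transformed internally when needed.
#' @param scores Tibble with `cell_id` and `dim1` (e.g. from
#'   [tidy.maturity_result()]); ids must match the neuron sample names.
#' @return Tibble with `gene`, `r`, `p`, sorted by the input gene order.
#' @export
gene_dim1_correlation <- function(m, scores) {
  neurons <- expr_samples(m, class = "neuron")
  if (is.null(neurons) || length(neurons) == 0L) neurons <- expr_samples(m)
  unmatched <- setdiff(scores$cell_id, neurons)
  if (length(unmatched) > 0L) {
    abort(paste("cell ids without expression columns:",
                paste(unmatched, collapse = ", ")))
  }
  unmatched2 <- setdiff(neurons, scores$cell_id)
  if (length(unmatched2) > 0L) {
    abort(paste("neuron samples without Dim1 scores:",
                paste(unmatched2, collapse = ", ")))
  }
  n <- length(neurons)
  if (n < 4L) abort("need at least 4 matched neuron samples")
  vals <- expr_log_values(m)[, scores$cell_id, drop = FALSE]
  dim1 <- scores$dim1
  r <- suppressWarnings(as.numeric(stats::cor(t(vals), dim1)))
  r[is.na(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[r == 0] <- 1
  p[abs(r) == 1] <- 0
  tibble(gene = rownames(vals), r = r, p = p)
}

#' Threshold the correlation list into maturation gene clusters
#'
#' Green cluster: genes positively correlated with Dim1 (`r > r_min`,
#' `p < alpha`), i.e. enriched in immature neurons since Dim1 is oriented
#' against maturity. Magenta cluster: genes negatively correlated
#' (`r < -r_min`, `p < alpha`), enriched in matured neurons. Both
#' inequalities are strict.
#'
#' @param correlations Tibble from [gene_dim1_correlation()].
#' @param r_min Correlation magnitude threshold (default 0.4).
#' @param alpha Raw p-value threshold (default 0.05).
#' @return A list with `green` and `magenta`, each a tibble (`gene`, `r`,
#'   `p`) sorted by gene.
#' @export
threshold_clusters <- function(correlations, r_min = 0.4, alpha = 0.05) {
  green <- correlations |>
    dplyr::filter(.data$r > r_min, .data$p < alpha) |>
    dplyr::arrange(.data$gene)
  magenta <- correlations |>
    dplyr::filter(.data$r < -r_min, .data$p < alpha) |>
    dplyr::arrange(.data$gene)
  list(green = green, magenta = magenta)
}

#' Exact intersection of two gene sets
#'
#' @param a,b Character vectors of gene ids in the same namespace.
#' @return Sorted character vector of the shared genes.
#' @export
intersect_sets <- function(a, b) {
  sort(intersect(unique(a), unique(b)))
}

#' Cross-reference candidates against an external gene list
#'
#' Intersects a candidate set with an externally published gene list after
#' upper-casing both sides; an optional two-column synonym map (`from`,
#' `to`) is applied to the external list first to absorb symbol drift
#' between studies. Candidates with no match are reported in the
#' `"unmatched"` attribute.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param external Character vector of external symbols, or a path to a
#'   plain-text file with one symbol per line.
#' @param id_map Optional data frame mapping external symbols (`from`) to
#'   the candidate namespace (`to`).
#' @return Sorted character vector of shared genes, with attribute
#'   `unmatched` (candidates not in the external list).
#' @export
cross_reference_external <- function(candidates, external, id_map = NULL) {
  if (is.character(external) && length(external) == 1L && file.exists(external)) {
    external <- read_gene_list(external)
  }
  ext <- toupper(trimws(external))
  ext <- ext[nzchar(ext)]
  if (!is.null(id_map)) {
    hit <- match(ext, toupper(id_map[[1L]]))
    ext[!is.na(hit)] <- toupper(id_map[[2L]][hit[!is.na(hit)]])
  }
  cand <- toupper(trimws(candidates))
  shared <- sort(unique(cand[cand %in% ext]))
  structure(shared, unmatched = sort(setdiff(cand, ext)))
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path File path.
#' @return Character vector of symbols (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write the maturation-gene outputs
#'
#' Writes `green.csv` and `magenta.csv` (gene, r, p), plus optional
#' `intersect.csv` and `biomarkers.csv`, all deterministically ordered.
#'
#' @param clusters List from [threshold_clusters()].
#' @param dir Output directory.
#' @param intersect,biomarkers Optional gene vectors to write alongside.
#' @return `dir`, invisibly.
#' @export
write_maturation_genes <- function(clusters, dir, intersect = NULL,
                                   biomarkers = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(clusters$green, file.path(dir, "green.csv"))
  readr::write_csv(clusters$magenta, file.path(dir, "magenta.csv"))
  if (!is.null(intersect)) {
    readr::write_csv(tibble(gene = sort(intersect)), file.path(dir, "intersect.csv"))
  }
  if (!is.null(biomarkers)) {
    readr::write_csv(tibble(gene = sort(biomarkers)), file.path(dir, "biomarkers.csv"))
  }
  invisible(dir)
}
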