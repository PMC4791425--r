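#' Read and write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-delimited — term id, description,
#' then member genes. Duplicate genes within a set are counted once.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    term <- fields[1L]
    sets[[term]] <- unique(fields[-(1:2)])
    desc[term] <- fields[2L]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param coll A `gene_set_collection` (or plain named list of gene
#'   vectors).
#' @export
write_gmt <- function(coll, path) {
  desc <- attr(coll, "descriptions")
  lines <- vapply(names(coll), function(term) {
    d <- if (!is.null(desc) && term %in% names(desc)) desc[[term]] else term
    paste(c(term, d, coll[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d..%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Fisher's-exact over-representation test across a gene-set collection
#'
#' For each annotation term, the one-sided Fisher's exact p-value of the
#' 2x2 table (overlap; query not in set; set not in query; neither) — the
#' upper hypergeometric tail P(X >= overlap). Sets are intersected with the
#' universe before testing; the universe is conventionally the genes that
#' survived the expression filter.
#'
#' @param query Character vector of query genes (must be a subset of the
#'   universe).
#' @param universe Character vector: the tested background.
#' @param coll A `gene_set_collection` (or named list of gene vectors).
#' @param p_adjust Apply Benjamini-Hochberg correction and add a `p_adj`
#'   column (off by default: raw p-values are reported, matching the
#'   -log10 p bar convention).
#' @param min_set_size Drop terms with fewer in-universe genes than this.
#' @return Tibble with `term`, `description`, `overlap`, `query_size`,
#'   `set_size`, `universe_size`, `p`, `neg_log10_p`, sorted by p then
#'   term.
#' @export
fisher_enrichment <- function(query, universe, coll, p_adjust = FALSE,
                              min_set_size = 1) {
  query <- unique(query)
  universe <- unique(universe)
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0L) {
    abort(paste("query genes outside the universe:",
                paste(utils::head(offenders, 10), collapse = ", ")))
  }
  desc <- attr(coll, "descriptions")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::map_dfr(names(coll), function(term) {
    set <- intersect(unique(coll[[term]]), universe)
    if (length(set) < min_set_size) return(NULL)
    ov <- length(intersect(query, set))
    # upper tail P(X >= ov), X ~ Hypergeom(set, universe \ set, draws = query)
    p <- stats::phyper(ov - 1L, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    tibble(
      term = term,
      description = if (!is.null(desc) && term %in% names(desc)) desc[[term]] else term,
      overlap = ov, query_size = n_q, set_size = length(set),
      universe_size = n_u, p = p, neg_log10_p = -log10(p)
    )
  })
  rows <- dplyr::arrange(rows, .data$p, .data$term)
  if (p_adjust) rows$p_adj <- stats::p.adjust(rows$p, method = "BH")
  rows
}
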