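#' Build an expression matrix tibble with sample classes
#'
#' The package's expression container is a plain tibble — `gene` in column 1,
#' one numeric column per sample — carrying two attributes: `sample_class`
#' (named character, values `"neuron"` or `"contrast"`) and `log2` (whether
#' values are log2(FPKM + 1)). Helper accessors keep the attributes straight.
#'
#' @param values Numeric matrix (genes x samples) with dimnames, or a data
#'   frame with a `gene` column.
#' @param classes Named character vector, or a two-column data frame
#'   (`sample`, `class`) covering every sample column.
#' @param log2 Whether values are already log2-transformed.
#' @return An expression tibble.
#' @export
expression_matrix <- function(values, classes, log2 = FALSE) {
  if (is.matrix(values)) {
    tbl <- as_tibble(values, rownames = "gene")
  } else {
    tbl <- as_tibble(values)
    if (names(tbl)[1L] != "gene") names(tbl)[1L] <- "gene"
  }
  if (anyDuplicated(tbl$gene)) abort("duplicate gene identifiers")
  samples <- names(tbl)[-1L]
  if (is.data.frame(classes)) classes <- stats::setNames(classes[[2L]], classes[[1L]])
  unknown <- setdiff(samples, names(classes))
  if (length(unknown) > 0L) {
    abort(paste("samples missing from class map:", paste(unknown, collapse = ", ")))
  }
  vals <- as.matrix(tbl[-1L])
  if (!log2 && any(vals < 0)) abort("FPKM values must be non-negative")
  attr(tbl, "sample_class") <- classes[samples]
  attr(tbl, "log2") <- isTRUE(log2)
  tbl
}

#' @rdname expression_matrix
#' @param m Expression tibble.
#' @export
expr_classes <- function(m) attr(m, "sample_class")

#' @rdname expression_matrix
#' @export
expr_is_log <- function(m) isTRUE(attr(m, "log2"))

#' @rdname expression_matrix
#' @export
expr_values <- function(m) {
  v <- as.matrix(m[-1L])
  rownames(v) <- m$gene
  v
}

#' @rdname expression_matrix
#' @param class Optional class to restrict to (`"neuron"` or `"contrast"`).
#' @export
expr_samples <- function(m, class = NULL) {
  s <- names(m)[-1L]
  if (is.null(class)) return(s)
  cls <- expr_classes(m)
  s[cls[s] == class]
}

# rebuild attributes after a dplyr verb stripped them
reattach_expr <- function(tbl, template, log2 = NULL) {
  attr(tbl, "sample_class") <- expr_classes(template)[names(tbl)[-1L]]
  attr(tbl, "log2") <- if (is.null(log2)) expr_is_log(template) else log2
  tbl
}

#' Read an FPKM expression matrix from TSV or MatrixMarket files
#'
#' TSV: genes in column 1, header row of sample names. MTX: a MatrixMarket
#' file with sidecar row- and column-label files (one identifier per line).
#' Duplicate gene rows are collapsed by the elementwise maximum, with a
#' warning (needed for downstream symbol-level cross-referencing).
#'
#' @param path TSV or `.mtx` file path.
#' @param class_map Two-column data frame/CSV path (`sample`, `class`) or a
#'   named character vector assigning each sample to `neuron` or `contrast`.
#' @param row_labels,col_labels Label files for the MTX route; default
#'   `<path>.rows` / `<path>.cols`.
#' @return An expression tibble (see [expression_matrix()]).
#' @export
read_expression <- function(path, class_map, row_labels = paste0(path, ".rows"),
                            col_labels = paste0(path, ".cols")) {
  if (is.character(class_map) && length(class_map) == 1L && file.exists(class_map)) {
    class_map <- readr::read_csv(class_map, show_col_types = FALSE)
  }
  if (grepl("\\.mtx$", path)) {
    mm <- as.matrix(Matrix::readMM(path))
    rownames(mm) <- readLines(row_labels)
    colnames(mm) <- readLines(col_labels)
    tbl <- as_tibble(mm, rownames = "gene")
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    names(raw)[1L] <- "gene"
    num <- raw
    for (j in seq(2L, ncol(raw))) {
      v <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(v) & !is.na(raw[[j]]))
      if (length(bad) > 0L) {
        abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                      raw[[j]][bad[1L]], bad[1L], names(raw)[j]))
      }
      num[[j]] <- v
    }
    tbl <- num
  }
  if (anyDuplicated(tbl$gene)) {
    warn("duplicate gene rows collapsed by elementwise max")
    tbl <- tbl |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), max), .groups = "drop")
  }
  expression_matrix(tbl, class_map, log2 = FALSE)
}

#' Write an expression tibble as TSV
#'
#' @param m Expression tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' Log-transform an FPKM matrix
#'
#' Applies `log2(x + 1)` and sets the log flag. Applying it twice is an
#' error.
#'
#' @param m Expression tibble in FPKM scale.
#' @return The log2-scale expression tibble.
#' @export
log_transform <- function(m) {
  if (expr_is_log(m)) abort("matrix is already log-transformed")
  out <- m
  for (j in seq(2L, ncol(m))) out[[j]] <- log2(m[[j]] + 1)
  reattach_expr(out, m, log2 = TRUE)
}

#' Technical-replicate QC: whole-transcriptome Pearson correlation
#'
#' Pearson correlation over all genes between two (log-transformed) sample
#' columns; values near 0.99 indicate a negligible batch effect between
#' technical replicates.
#'
#' @param m Log-transformed expression tibble.
#' @param sample_a,sample_b Sample column names.
#' @return Pearson r (scalar).
#' @export
replicate_correlation <- function(m, sample_a, sample_b) {
  if (!expr_is_log(m)) abort("replicate correlation is defined on the log-transformed matrix")
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(m)) abort(paste("sample not found:", s))
    if (stats::sd(m[[s]]) == 0) abort(paste("zero variance in sample:", s))
  }
  stats::cor(m[[sample_a]], m[[sample_b]])
}

#' Keep genes expressed above an FPKM floor in at least one sample
#'
#' A gene is retained iff its maximum FPKM across samples is at least
#' `fpkm_min` (inclusive boundary). Applied on the raw FPKM scale, before
#' any log transform.
#'
#' @param m Expression tibble in FPKM scale.
#' @param fpkm_min Expression floor (default 0.1 FPKM).
#' @return The filtered expression tibble.
#' @export
filter_expressed <- function(m, fpkm_min = 0.1) {
  if (expr_is_log(m)) abort("apply the expression filter on the raw FPKM scale")
  vals <- expr_values(m)
  keep <- apply(vals, 1, max) >= fpkm_min
  if (!any(keep)) abort("no gene passes the expression filter")
  reattach_expr(m[keep, ], m)
}
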