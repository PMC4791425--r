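#' Default maturation direction of each electrophysiological parameter
#'
#' Parameters that increase with neuronal maturation (firing rate, AP
#' amplitude, sodium current, PSC frequencies) versus parameters that
#' decrease (halfwidth, input resistance, rise time, threshold — threshold
#' hyperpolarises, i.e. its signed value falls, as neurons mature). This map
#' drives the not-detected imputation rule: an ND entry is replaced by the
#' column minimum for a maturation-positive parameter and by the column
#' maximum for a maturation-negative one, so unexcitable cells land at the
#' immature end of every axis.
#'
#' @return A tibble with columns `parameter` and `direction`
#'   (`"maturation_positive"` / `"maturation_negative"`).
#' @export
default_direction_map <- function() {
  tibble(
    parameter = EPHYS_PARAMS,
    direction = dplyr::if_else(
      EPHYS_PARAMS %in% c("firing_rate", "amplitude", "na_current",
                          "freq_epsc", "freq_ipsc"),
      "maturation_positive", "maturation_negative"
    )
  )
}

#' Impute not-detected entries by the max/min rule
#'
#' ND (`NA`) entries of a parameter column are replaced by the column's
#' observed maximum when the parameter is negatively correlated with
#' maturation, and by the observed minimum when positively correlated. The
#' original ND mask is preserved in the `"nd_mask"` attribute for audit.
#'
#' @param tbl Parameter tibble from [build_parameter_table()].
#' @param dirs Direction map tibble (`parameter`, `direction`); defaults to
#'   [default_direction_map()].
#' @return The imputed tibble with attribute `nd_mask` (logical matrix).
#' @export
impute_nd <- function(tbl, dirs = default_direction_map()) {
  params <- intersect(EPHYS_PARAMS, names(tbl))
  nd_cols <- params[vapply(params, function(p) anyNA(tbl[[p]]), logical(1))]
  missing_dir <- setdiff(nd_cols, dirs$parameter)
  if (length(missing_dir) > 0L) {
    abort(paste("columns with ND but no direction:",
                paste(missing_dir, collapse = ", ")))
  }
  mask <- as.matrix(is.na(tbl[params]))
  out <- tbl
  for (p in nd_cols) {
    dir <- dirs$direction[dirs$parameter == p]
    fill <- if (dir == "maturation_negative") {
      max(tbl[[p]], na.rm = TRUE)
    } else {
      min(tbl[[p]], na.rm = TRUE)
    }
    out[[p]][is.na(out[[p]])] <- fill
  }
  attr(out, "nd_mask") <- mask
  out
}

#' Principal-component maturity decomposition of the parameter table
#'
#' Columns are standardised (zero mean, unit variance; equivalently the PCA
#' is on the correlation matrix, required because parameter units are
#' heterogeneous — Hz, mV, MOhm, pA). Scores and loadings are returned for
#' all components, along with the Pearson correlation of each raw parameter
#' with each score vector (the variable factor map).
#'
#' @param tbl Imputed parameter tibble (no `NA` remaining, at least 3 cells).
#' @return A `maturity_result` object: list with `scores` (tibble `cell_id`,
#'   `dim1`, `dim2`), `loadings` (parameter x component matrix), `var_corr`
#'   (tibble `parameter`, `dim1`, `dim2`), `explained_variance` (fraction per
#'   component), and the input `data`.
#' @export
run_pca <- function(tbl) {
  params <- intersect(EPHYS_PARAMS, names(tbl))
  x <- as.matrix(tbl[params])
  if (anyNA(x)) abort("ND values remain; run impute_nd() first")
  if (nrow(x) < 3L) abort("PCA needs at least 3 cells")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste("zero-variance column(s):",
                paste(params[sds == 0], collapse = ", ")))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble(
    cell_id = tbl$cell_id,
    dim1 = pc$x[, 1L],
    dim2 = pc$x[, 2L]
  )
  var_corr <- tibble(
    parameter = params,
    dim1 = as.numeric(stats::cor(x, pc$x[, 1L])),
    dim2 = as.numeric(stats::cor(x, pc$x[, 2L]))
  )
  structure(
    list(scores = scores, loadings = pc$rotation, var_corr = var_corr,
         explained_variance = ev, all_scores = pc$x, data = tbl),
    class = "maturity_result"
  )
}

#' Fix the sign of Dim1 against the firing-rate anchor
#'
#' Eigenvector signs are arbitrary; by convention the maturity axis Dim1 is
#' oriented so that it anti-correlates with firing rate (larger Dim1 = less
#' mature). Idempotent.
#'
#' @param res A `maturity_result` from [run_pca()].
#' @param anchor Parameter used as the maturity anchor (default
#'   `"firing_rate"`).
#' @return The result with `dim1`, its loadings and correlations flipped if
#'   needed.
#' @export
orient_dim1 <- function(res, anchor = "firing_rate") {
  stopifnot(inherits(res, "maturity_result"))
  if (!anchor %in% names(res$data)) abort(paste("anchor column missing:", anchor))
  r <- stats::cor(res$scores$dim1, res$data[[anchor]])
  if (is.finite(r) && r > 0) {
    res$scores$dim1 <- -res$scores$dim1
    res$all_scores[, 1L] <- -res$all_scores[, 1L]
    res$loadings[, 1L] <- -res$loadings[, 1L]
    res$var_corr$dim1 <- -res$var_corr$dim1
  }
  res
}

# Deterministic 1-D k-means: centers initialised at the k quantile midpoints,
# Lloyd iterations to convergence. Returns integer assignments.
kmeans_1d <- function(x, k, max_iter = 100L) {
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  centers <- as.numeric(stats::quantile(x, probs = probs, names = FALSE))
  assign <- integer(length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    new_assign <- max.col(-d, ties.method = "first")
    if (any(tabulate(new_assign, k) == 0L)) return(NULL)  # empty cluster
    new_centers <- vapply(seq_len(k), function(j) mean(x[new_assign == j]),
                          numeric(1))
    if (identical(new_assign, assign) && all(new_centers == centers)) break
    assign <- new_assign
    centers <- new_centers
  }
  assign
}

#' Bin cells into maturity groups along Dim1
#'
#' Deterministic 1-D k-means on the oriented Dim1 scores (centers initialised
#' at quantile midpoints, so repeated runs agree). Clusters are ordered by
#' mean Dim1: since larger Dim1 means less mature, the lowest-Dim1 cluster is
#' `matured`, then `maturing`, then `immature`. When a cluster empties
#' (massive ties), a tertile split is used instead, with a warning.
#'
#' @param res A `maturity_result` (or a numeric vector of Dim1 scores).
#' @param k Number of groups (default 3).
#' @return For a `maturity_result`, the result with a `group` factor added to
#'   `$scores`; for a numeric vector, the factor itself.
#' @export
assign_groups <- function(res, k = 3) {
  x <- if (inherits(res, "maturity_result")) res$scores$dim1 else as.numeric(res)
  if (length(x) < k) abort("need at least k cells to form k groups")
  assign <- kmeans_1d(x, k)
  if (is.null(assign)) {
    warn("degenerate Dim1 scores: falling back to a tertile split")
    br <- stats::quantile(x, probs = seq(0, 1, length.out = k + 1))
    br[1] <- -Inf
    br[k + 1] <- Inf
    assign <- as.integer(cut(x, breaks = unique(br), labels = FALSE))
    assign[is.na(assign)] <- 1L
    if (length(unique(br)) - 1L < k) {
      # total degeneracy: everything in one group
      assign <- rep(1L, length(x))
    }
  }
  level_names <- c("matured", "maturing", "immature")
  if (k != 3) level_names <- paste0("group", seq_len(k))
  ord <- order(vapply(seq_len(max(assign)), function(j) mean(x[assign == j]),
                      numeric(1)))
  lab <- integer(length(assign))
  for (j in seq_along(ord)) lab[assign == ord[j]] <- j
  grp <- factor(level_names[pmin(lab, length(level_names))],
                levels = level_names[seq_len(min(k, length(level_names)))])
  if (inherits(res, "maturity_result")) {
    res$scores$group <- grp
    res
  } else {
    grp
  }
}

#' Full maturity pipeline: impute, decompose, orient, group
#'
#' Convenience wrapper chaining [impute_nd()], [run_pca()], [orient_dim1()]
#' and [assign_groups()].
#'
#' @inheritParams impute_nd
#' @inheritParams assign_groups
#' @return An oriented, grouped `maturity_result`.
#' @export
maturity_index <- function(tbl, dirs = default_direction_map(), k = 3) {
  tbl |>
    impute_nd(dirs) |>
    run_pca() |>
    orient_dim1() |>
    assign_groups(k = k)
}

#' @export
print.maturity_result <- function(x, ...) {
  cat(sprintf(
    "<maturity_result> %d cells; Dim1 %.1f%%, Dim2 %.1f%% of variance\n",
    nrow(x$scores), 100 * x$explained_variance[1], 100 * x$explained_variance[2]
  ))
  if (!is.null(x$scores$group)) print(table(x$scores$group))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cell maturity scores as a tibble
#'
#' @param x A `maturity_result`.
#' @param ... Unused.
#' @return Tibble of `cell_id`, `dim1`, `dim2` and (if assigned) `group`.
#' @exportS3Method generics::tidy
tidy.maturity_result <- function(x, ...) x$scores

#' One-row summary of the maturity decomposition
#'
#' @param x A `maturity_result`.
#' @param ... Unused.
#' @return Tibble with cell count, variance explained by the first two
#'   components, and the Dim1-firing-rate correlation.
#' @exportS3Method generics::glance
glance.maturity_result <- function(x, ...) {
  tibble(
    n_cells = nrow(x$scores),
    var_dim1 = x$explained_variance[1],
    var_dim2 = x$explained_variance[2],
    dim1_firing_rate_r = stats::cor(x$scores$dim1, x$data$firing_rate)
  )
}

#' Write maturity scores and loadings
#'
#' @param res A `maturity_result`.
#' @param dir Output directory (created if absent); writes `scores.csv`
#'   (cell_id, dim1, dim2, group) and `loadings.csv`.
#' @return `dir`, invisibly.
#' @export
write_maturity <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(res$scores, file.path(dir, "scores.csv"))
  ld <- as_tibble(res$loadings, rownames = "parameter")
  readr::write_csv(ld, file.path(dir, "loadings.csv"))
  invisible(dir)
}
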