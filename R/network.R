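#' Configuration for co-expression network construction
#'
#' @param powers Candidate soft-threshold exponents (default 1..20).
#' @param rsq_cut Scale-free topology fit threshold for picking the soft
#'   power (default 0.8).
#' @param min_module_size Smallest allowed module (genes, default 30).
#' @param cut_height Dendrogram height below which module cores must have
#'   fully assembled; `NULL` uses half the tallest merge.
#' @param deep_split Split sensitivity 0-4; larger values split branches more
#'   aggressively.
#' @param pam_stage Optionally re-assign unclustered genes to the nearest
#'   module core by mean topological overlap (off by default; the
#'   eigengene-based refinement in [build_network()] is the recommended
#'   assignment stage).
#' @param refine Refine module membership by eigengene correlation (kME) in
#'   [build_network()] (default `TRUE`).
#' @param kme_min Minimum module-eigengene correlation for membership during
#'   refinement (default 0.7).
#' @return A list of class `network_config`.
#' @export
network_config <- function(powers = 1:20, rsq_cut = 0.8, min_module_size = 30,
                           cut_height = NULL, deep_split = 2,
                           pam_stage = FALSE, refine = TRUE, kme_min = 0.7) {
  stopifnot(all(powers >= 1), rsq_cut > 0, rsq_cut < 1, min_module_size >= 2,
            deep_split %in% 0:4, kme_min > 0, kme_min < 1)
  structure(
    list(powers = powers, rsq_cut = rsq_cut,
         min_module_size = min_module_size, cut_height = cut_height,
         deep_split = deep_split, pam_stage = pam_stage, refine = refine,
         kme_min = kme_min),
    class = "network_config"
  )
}

# WGCNA module colour order: modules are labelled largest-first.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + r_ij)/2)^beta`: perfectly anti-correlated genes get weight
#' 0, perfectly correlated genes weight 1, so correlation sign is preserved
#' (a signed network). The diagonal is zeroed for connectivity purposes.
#'
#' @param corr Symmetric gene-gene Pearson correlation matrix, entries in
#'   \[-1, 1\].
#' @param beta Soft-threshold exponent (>= 1).
#' @return Adjacency matrix with zero diagonal.
#' @export
signed_adjacency <- function(corr, beta) {
  if (beta < 1) abort("beta must be at least 1")
  if (any(abs(corr) > 1 + 1e-8)) abort("correlations must lie in [-1, 1]")
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  a
}

# Scale-free topology fit index for one connectivity vector:
# R^2 of log10 p(k) on log10 k over equal-width bins, sign-corrected so a
# positive slope (anti-scale-free) scores negatively.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 10) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Estimate the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, the signed adjacency is formed and the
#' scale-free fit index (R^2 of the log-log connectivity-distribution
#' regression, sign-corrected for the slope) computed. The smallest power
#' reaching `rsq_cut` is returned; if none does, the power with the maximal
#' fit is returned with a warning.
#'
#' @param m Expression tibble (log-transformed internally if needed).
#' @param cfg A [network_config()].
#' @return A list with `beta` (chosen power) and `fit` (tibble `power`,
#'   `rsq`, `mean_k`).
#' @export
estimate_soft_power <- function(m, cfg = network_config()) {
  vals <- expr_log_values(m)
  if (nrow(vals) < 3L) abort("need at least 3 genes")
  if (ncol(vals) < 3L) abort("need at least 3 samples")
  corr <- stats::cor(t(vals))
  fit <- purrr::map_dfr(cfg$powers, function(b) {
    a <- signed_adjacency(corr, b)
    k <- colSums(a)
    tibble(power = b, rsq = scale_free_fit(k), mean_k = mean(k))
  })
  hit <- which(!is.na(fit$rsq) & fit$rsq >= cfg$rsq_cut)
  if (length(hit) > 0L) {
    beta <- fit$power[hit[1L]]
  } else {
    beta <- fit$power[which.max(fit$rsq)]
    warn(sprintf("no power reached scale-free fit %.2f; using argmax power %d",
                 cfg$rsq_cut, beta))
  }
  list(beta = beta, fit = fit)
}

# log2(FPKM + 1) matrix regardless of the input's scale
expr_log_values <- function(m) {
  vals <- expr_values(m)
  if (!expr_is_log(m)) vals <- log2(vals + 1)
  vals
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the connectivity (row sum); the diagonal is 1 and `1 - TOM` is the
#' clustering distance. Two genes overlap strongly when they share
#' neighbours even if their direct edge is modest.
#'
#' @param adjacency Symmetric matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return The TOM matrix (unit diagonal).
#' @export
topological_overlap <- function(adjacency) {
  if (any(adjacency < 0 | adjacency > 1)) {
    abort("adjacency entries must lie in [0, 1]")
  }
  k <- colSums(adjacency)
  shared <- adjacency %*% adjacency
  kmin <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  tom
}

#' Detect gene modules by dynamic cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, followed by a
#' dynamic dendrogram cut: a static cut at `cut_height` yields initial
#' branches; each branch large enough to be a module is recursively split
#' whenever both sub-branches reach `min_module_size` and the merge is
#' separated from its sub-branches by a height gap (the gap criterion
#' loosens with `deep_split`). Genes in branches below the size floor stay
#' unassigned (`"grey"`). Modules are labelled by decreasing size with the
#' conventional colour sequence (largest = `"turquoise"`, then `"blue"`,
#' `"brown"`, ...).
#'
#' @param tom TOM matrix from [topological_overlap()] (dimnames = genes).
#' @param cfg A [network_config()].
#' @param adjacency Optional adjacency matrix for centrality annotation; when
#'   supplied, per-gene within-module connectivity and hub rank are attached.
#' @return A list with `modules` (tibble `gene`, `module`, and when
#'   `adjacency` is given `centrality`, `hub_rank`), `dendrogram` (hclust),
#'   and `sizes` (named module sizes, largest first).
#' @export
cluster_modules <- function(tom, cfg = network_config(), adjacency = NULL) {
  n <- nrow(tom)
  if (cfg$min_module_size > n) abort("min_module_size exceeds the gene count")
  genes <- rownames(tom) %||% paste0("g", seq_len(n))
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  labels <- dynamic_tree_cut(hc, min_size = cfg$min_module_size,
                             deep_split = cfg$deep_split,
                             cut_height = cfg$cut_height)
  if (cfg$pam_stage && any(labels == 0L) && any(labels > 0L)) {
    labels <- pam_assign(labels, tom)
  }
  sizes <- sort(table(labels[labels > 0L]), decreasing = TRUE)
  color_of <- stats::setNames(rep("grey", n), genes)
  module_names <- character(0)
  if (length(sizes) > 0L) {
    pal <- rep(MODULE_COLORS, length.out = length(sizes))
    for (i in seq_along(sizes)) {
      color_of[labels == as.integer(names(sizes)[i])] <- pal[i]
    }
    module_names <- stats::setNames(as.integer(sizes), pal[seq_along(sizes)])
  }
  modules <- tibble(gene = genes, module = unname(color_of))
  if (!is.null(adjacency)) {
    modules <- modules |>
      dplyr::group_by(.data$module) |>
      dplyr::group_modify(function(df, key) {
        if (key$module == "grey") {
          df$centrality <- NA_real_
          df$hub_rank <- NA_integer_
          return(df)
        }
        cent <- node_centrality(adjacency, df$gene)
        dplyr::left_join(df, cent, by = "gene")
      }) |>
      dplyr::ungroup() |>
      dplyr::arrange(match(.data$gene, genes))
  }
  list(modules = modules, dendrogram = hc, sizes = module_names)
}

# assign unclustered genes to the module with the highest mean TOM
# similarity, when that similarity is comparable to the module's interior
pam_assign <- function(labels, tom) {
  mods <- sort(unique(labels[labels > 0L]))
  grey <- which(labels == 0L)
  for (g in grey) {
    sims <- vapply(mods, function(m) mean(tom[g, labels == m]), numeric(1))
    best <- mods[which.max(sims)]
    interior <- tom[labels == best, labels == best]
    thresh <- stats::quantile(interior[upper.tri(interior)], 0.05, names = FALSE)
    if (max(sims) >= thresh) labels[g] <- best
  }
  labels
}

#' Within-module node centrality and hub ranking
#'
#' Centrality of gene i is the sum of its adjacency to the other module
#' members (within-cluster connectivity); `hub_rank` orders genes by
#' decreasing centrality, ties broken lexicographically by gene id.
#'
#' @param adjacency Adjacency matrix with gene dimnames.
#' @param module Character vector of module gene ids (subset of the
#'   adjacency index).
#' @return Tibble with `gene`, `centrality`, `hub_rank`.
#' @export
node_centrality <- function(adjacency, module) {
  if (length(module) == 0L) abort("empty module")
  missing <- setdiff(module, rownames(adjacency))
  if (length(missing) > 0L) {
    abort(paste("module genes absent from adjacency:",
                paste(missing, collapse = ", ")))
  }
  sub <- adjacency[module, module, drop = FALSE]
  cent <- rowSums(sub)
  ord <- order(-cent, module)
  rank <- integer(length(module))
  rank[ord] <- seq_along(module)
  tibble(gene = module, centrality = unname(cent), hub_rank = rank)
}

#' Export the strongest within-module edges (VisANT dialect)
#'
#' The k heaviest within-module edges, sorted by weight (ties broken by the
#' lexicographic node pair). When fewer than k edges exist, all are returned
#' with a warning.
#'
#' @inheritParams node_centrality
#' @param k Number of edges to keep (default 100, the conventional
#'   visualisation budget).
#' @return Tibble with `node1`, `node2`, `weight`.
#' @export
export_top_edges <- function(adjacency, module, k = 100) {
  if (length(module) < 2L) abort("module must contain at least 2 genes")
  module <- sort(module)
  sub <- adjacency[module, module, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  edges <- tibble(
    node1 = module[idx[, 1L]],
    node2 = module[idx[, 2L]],
    weight = sub[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$node1, .data$node2)
  if (k > nrow(edges)) {
    warn(sprintf("only %d edges available (k = %d); returning all", nrow(edges), k))
    k <- nrow(edges)
  }
  edges[seq_len(k), ]
}

#' @rdname export_top_edges
#' @param edges Edge tibble from `export_top_edges()`.
#' @param path Output path; written tab-delimited, three columns, no header.
#' @export
write_visant_edges <- function(edges, path) {
  readr::write_tsv(edges, path, col_names = FALSE)
  invisible(path)
}

#' Build the full signed co-expression network from an expression matrix
#'
#' Chains the network stage end to end: gene-gene Pearson correlation on
#' log2(FPKM + 1), soft-power estimation, signed adjacency, topological
#' overlap, dynamic module detection, and per-module centrality.
#'
#' @param m Filtered expression tibble (see [filter_expressed()]).
#' @param cfg A [network_config()].
#' @param beta Optional fixed soft power; `NULL` estimates it.
#' @return A `gene_network` object: list with `modules` (tibble `gene`,
#'   `module`, `centrality`, `hub_rank`), `beta`, `power_fit`, `adjacency`,
#'   `tom`, `dendrogram`, `sizes`.
#' @export
build_network <- function(m, cfg = network_config(), beta = NULL) {
  vals <- expr_log_values(m)
  corr <- stats::cor(t(vals))
  fit <- NULL
  if (is.null(beta)) {
    sp <- estimate_soft_power(m, cfg)
    beta <- sp$beta
    fit <- sp$fit
  }
  adj <- signed_adjacency(corr, beta)
  tom <- topological_overlap(adj)
  cl <- cluster_modules(tom, cfg, adjacency = NULL)
  labels <- cl$modules$module
  if (cfg$refine && length(cl$sizes) > 0L) {
    labels <- refine_membership(vals, labels, kme_min = cfg$kme_min,
                                min_size = cfg$min_module_size)
  }
  # relabel by refined size and attach centrality
  out <- relabel_modules(cl$modules$gene, labels, adj)
  structure(
    list(modules = out$modules, beta = beta, power_fit = fit, adjacency = adj,
         tom = tom, dendrogram = cl$dendrogram, sizes = out$sizes),
    class = "gene_network"
  )
}

# Eigengene-based membership refinement (kME): each raw module's eigengene
# is the first principal component of its standardised log expression
# (oriented to correlate positively with the module's mean profile); every
# gene is then assigned to the module whose eigengene it correlates with
# most, provided that correlation reaches kme_min, otherwise it is grey.
# This trims genes that accreted onto a branch without sharing its profile
# and rescues tightly co-expressed genes the tree cut missed.
refine_membership <- function(vals, labels, kme_min = 0.7, min_size = 30) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) return(labels)
  eig <- vapply(mods, function(lab) {
    sub <- vals[labels == lab, , drop = FALSE]
    sub <- t(scale(t(sub)))
    e <- stats::prcomp(t(sub), center = FALSE, scale. = FALSE)$x[, 1L]
    if (stats::cor(e, colMeans(sub)) < 0) e <- -e
    e
  }, numeric(ncol(vals)))
  kme <- suppressWarnings(stats::cor(t(vals), eig))
  kme[is.na(kme)] <- 0
  best <- max.col(kme, ties.method = "first")
  best_kme <- kme[cbind(seq_len(nrow(kme)), best)]
  new_labels <- ifelse(best_kme >= kme_min, mods[best], "grey")
  # drop refined modules that fell below the size floor
  sz <- table(new_labels[new_labels != "grey"])
  too_small <- names(sz)[sz < min_size]
  new_labels[new_labels %in% too_small] <- "grey"
  new_labels
}

# order module labels by size (colour convention: largest = turquoise) and
# annotate within-module centrality and hub rank
relabel_modules <- function(genes, labels, adjacency) {
  sizes <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  color_of <- stats::setNames(rep("grey", length(genes)), genes)
  out_sizes <- integer(0)
  if (length(sizes) > 0L) {
    pal <- rep(MODULE_COLORS, length.out = length(sizes))
    for (i in seq_along(sizes)) {
      color_of[labels == names(sizes)[i]] <- pal[i]
    }
    out_sizes <- stats::setNames(as.integer(sizes), pal[seq_along(sizes)])
  }
  modules <- tibble(gene = genes, module = unname(color_of))
  modules <- modules |>
    dplyr::group_by(.data$module) |>
    dplyr::group_modify(function(df, key) {
      if (key$module == "grey") {
        df$centrality <- NA_real_
        df$hub_rank <- NA_integer_
        return(df)
      }
      dplyr::left_join(df, node_centrality(adjacency, df$gene), by = "gene")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$gene, genes))
  list(modules = modules, sizes = out_sizes)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, beta = %d, %d modules (+grey)\n",
              nrow(x$modules), x$beta, length(x$sizes)))
  if (length(x$sizes) > 0L) {
    print(utils::head(x$sizes, 10))
  }
  invisible(x)
}

#' Genes belonging to one module of a network
#'
#' @param net A `gene_network`.
#' @param label Module colour label.
#' @return Sorted character vector of gene ids.
#' @export
module_genes <- function(net, label) {
  sort(net$modules$gene[net$modules$module == label])
}
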