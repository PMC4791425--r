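#' Plot the maturity PCA: cells along Dim1/Dim2
#'
#' @param object A `maturity_result`.
#' @param ... Unused.
#' @return A ggplot: per-cell scores, coloured by maturity group when
#'   assigned.
#' @exportS3Method ggplot2::autoplot
autoplot.maturity_result <- function(object, ...) {
  df <- object$scores
  p <- ggplot(df, aes(x = .data$dim1, y = .data$dim2)) +
    labs(
      x = sprintf("Dim1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("Dim2 (%.1f%%)", 100 * object$explained_variance[2]),
      title = "Electrophysiological maturity PCA"
    ) +
    theme_minimal()
  if (!is.null(df$group)) {
    p + geom_point(aes(colour = .data$group), size = 3)
  } else {
    p + geom_point(size = 3)
  }
}

#' Variable factor map of the maturity PCA
#'
#' Each electrophysiological parameter drawn as an arrow whose tip is its
#' correlation with (Dim1, Dim2) — the conventional reading of which
#' parameters drive the maturity axis.
#'
#' @param res A `maturity_result`.
#' @return A ggplot.
#' @export
plot_variable_map <- function(res) {
  vc <- res$var_corr
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 200))
  ggplot(vc) +
    geom_path(data = circ, aes(x = cos(.data$theta), y = sin(.data$theta)),
              colour = "grey70") +
    geom_segment(aes(x = 0, y = 0, xend = .data$dim1, yend = .data$dim2),
                 arrow = arrow(length = unit(2, "mm"))) +
    geom_text(aes(x = .data$dim1 * 1.08, y = .data$dim2 * 1.08,
                  label = .data$parameter), size = 3) +
    coord_fixed() +
    labs(x = "correlation with Dim1", y = "correlation with Dim2",
         title = "Variable factor map") +
    theme_minimal()
}

#' Bar chart of enrichment significance
#'
#' @param enrich Tibble from [fisher_enrichment()].
#' @param top How many terms to show (by p-value).
#' @return A ggplot of -log10 p per term.
#' @export
plot_enrichment <- function(enrich, top = 10) {
  df <- utils::head(dplyr::arrange(enrich, .data$p), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot(df, aes(x = .data$neg_log10_p, y = .data$term)) +
    geom_col(fill = "steelblue") +
    labs(x = expression(-log[10] ~ italic(P)), y = NULL,
         title = "Gene-set enrichment (Fisher's exact test)") +
    theme_minimal()
}

#' Module sizes of a co-expression network
#'
#' @param object A `gene_network`.
#' @param ... Unused.
#' @return A ggplot bar chart of module sizes (grey excluded).
#' @exportS3Method ggplot2::autoplot
autoplot.gene_network <- function(object, ...) {
  df <- tibble(module = names(object$sizes), size = as.integer(object$sizes))
  df$module <- factor(df$module, levels = df$module)
  ggplot(df, aes(x = .data$module, y = .data$size)) +
    geom_col(aes(fill = .data$module), show.legend = FALSE) +
    scale_fill_identity() +
    labs(x = NULL, y = "genes",
         title = sprintf("Co-expression modules (beta = %d)", object$beta)) +
    theme_minimal()
}

#' Sweep gallery for one cell
#'
#' @param x A [sweep_set()].
#' @param sweeps Which sweeps to draw (default: all).
#' @return A ggplot of voltage traces offset by stimulus level.
#' @export
plot_sweeps <- function(x, sweeps = NULL) {
  df <- as_tibble(x)
  if (!is.null(sweeps)) df <- df[df$sweep %in% sweeps, ]
  ggplot(df, aes(x = .data$time_s, y = .data$voltage_mv,
                 group = .data$sweep, colour = .data$stim_pa)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "membrane potential (mV)", colour = "I (pA)",
         title = x$cell_id) +
    theme_minimal()
}
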