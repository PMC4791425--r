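# Dynamic dendrogram cut.
#
# Core-finding cut of an average-linkage (1 - TOM) dendrogram. Genuine
# co-expression modules have tight cores that assemble low in the tree,
# whereas unclustered genes accrete onto branches in near-continuous chains
# reaching almost to the root — so membership boundaries along those chains
# are not identifiable from the tree alone. This cut therefore extracts the
# tight cores: maximal subtrees assembled entirely below `cut_height`
# (default half the tallest merge) with at least `min_size` leaves. Within a
# core, the branch is split recursively wherever BOTH children are
# themselves sizeable and separated from the merge by a relative height gap
# (the gap threshold loosens with `deep_split` 0..4: 0.5, 0.4, 0.3, 0.2,
# 0.1). Leaves outside any core are unassigned (label 0); downstream
# membership refinement (see build_network) re-assigns them by module
# eigengene correlation.
#
# Returns an integer label per leaf, 0 = unassigned, 1..K = modules.
dynamic_tree_cut <- function(hc, min_size = 30, deep_split = 2,
                             cut_height = NULL) {
  n <- length(hc$order)
  gap_frac <- c(0.5, 0.4, 0.3, 0.2, 0.1)[deep_split + 1]
  merge <- hc$merge
  height <- hc$height
  n_merge <- nrow(merge)
  if (n_merge < 1L) return(integer(n))
  if (is.null(cut_height)) cut_height <- 0.5 * max(height)

  leaves_of <- vector("list", n_merge)
  for (i in seq_len(n_merge)) {
    lf <- integer(0)
    for (child in merge[i, ]) {
      lf <- c(lf, if (child < 0) -child else leaves_of[[child]])
    }
    leaves_of[[i]] <- lf
  }
  node_size <- function(ch) if (ch < 0) 1L else length(leaves_of[[ch]])
  node_height <- function(ch) if (ch < 0) 0 else height[ch]

  labels <- integer(n)
  next_label <- 0L

  splittable <- function(node) {
    ch <- merge[node, ]
    all(vapply(ch, function(c) {
      node_size(c) >= min_size &&
        height[node] > 0 &&
        (height[node] - node_height(c)) / height[node] >= gap_frac
    }, logical(1)))
  }

  assign_module <- function(node) {
    if (node > 0 && splittable(node)) {
      for (child in merge[node, ]) assign_module(child)
    } else {
      next_label <<- next_label + 1L
      lf <- if (node < 0) -node else leaves_of[[node]]
      labels[lf] <<- next_label
    }
  }

  # maximal subtrees below the cut, walked top-down from the root
  stack <- n_merge
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (height[node] <= cut_height) {
      if (length(leaves_of[[node]]) >= min_size) assign_module(node)
      next
    }
    for (child in merge[node, ]) {
      if (child > 0) stack <- c(stack, child)
    }
  }
  labels
}
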