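random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

test_that("signed adjacency maps correlation through ((1 + r)/2)^beta", {
  corr <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(signed_adjacency(corr, 6)[1, 2], 1)
  corr2 <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(signed_adjacency(corr2, 6)[1, 2], 0)
  corr3 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(signed_adjacency(corr3, 6)[1, 2], 0.015625)
  expect_equal(diag(signed_adjacency(corr, 6)), c(0, 0))
  expect_error(signed_adjacency(corr, 0.5), "beta")

  # monotone in correlation; increasing beta shrinks sub-unit weights
  r <- seq(-0.9, 0.9, by = 0.3)
  a6 <- ((1 + r) / 2)^6
  expect_true(all(diff(a6) > 0))
  a12 <- ((1 + r) / 2)^12
  expect_true(all(a12 < a6))
})

test_that("TOM matches a brute-force double-loop oracle", {
  for (seed in c(9, 19, 29)) {
    a <- random_adjacency(20, seed)
    tom <- topological_overlap(a)
    k <- rowSums(a)
    oracle <- matrix(0, 20, 20)
    for (i in 1:20) {
      for (j in 1:20) {
        if (i == j) { oracle[i, j] <- 1; next }
        l <- sum(a[i, ] * a[, j])
        oracle[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      }
    }
    expect_lt(max(abs(tom - oracle)), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
  }

  # degenerate cases
  full <- matrix(1, 3, 3); diag(full) <- 0
  expect_equal(topological_overlap(full)[1, 2], 1)
  zero <- matrix(0, 4, 4)
  expect_true(all(topological_overlap(zero)[upper.tri(zero)] == 0))
  expect_error(topological_overlap(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("soft power selection follows the scale-free criterion", {
  # heavy-tailed latent-factor background reaches the fit threshold at a
  # moderate power (frozen from an independent run of the fit regression)
  ex <- simulate_expression(synthetic_config(seed = 8))
  filt <- filter_expressed(ex$expr)
  tr <- ex$truth
  keep <- !(filt$gene %in% c(tr$neuron_specific, tr$maturation_up,
                             tr$maturation_down))
  bg <- filt[keep, ]
  attr(bg, "sample_class") <- expr_classes(filt)[names(bg)[-1]]
  attr(bg, "log2") <- FALSE
  sp <- estimate_soft_power(bg)
  expect_identical(sp$beta, 6L)
  expect_gte(sp$fit$rsq[sp$fit$power == sp$beta], 0.8)
  # the selection equals an independent scan of the fit table
  first_hit <- sp$fit$power[which(sp$fit$rsq >= 0.8)[1]]
  expect_identical(sp$beta, first_hit)

  # grid of length one returns that power
  sp1 <- suppressWarnings(estimate_soft_power(bg, network_config(powers = 4)))
  expect_identical(sp1$beta, 4)

  # when nothing reaches the threshold, fall back to the argmax with warning
  expect_warning(
    sp2 <- estimate_soft_power(bg, network_config(rsq_cut = 0.999)),
    "argmax"
  )
  expect_identical(sp2$beta, sp2$fit$power[which.max(sp2$fit$rsq)])
})

planted_blocks <- function(seed, n_block = 100, n_noise = 0, r_signal = 3) {
  set.seed(seed)
  lat <- matrix(rnorm(2 * 20), 2, 20)
  x <- rbind(
    r_signal * lat[rep(1, n_block), ] + matrix(rnorm(n_block * 20), n_block),
    r_signal * lat[rep(2, n_block), ] + matrix(rnorm(n_block * 20), n_block)
  )
  if (n_noise > 0) x <- rbind(x, matrix(rnorm(n_noise * 20), n_noise))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  truth <- c(rep(1, n_block), rep(2, n_block), rep(0, length.out = n_noise))
  list(x = x, truth = truth)
}

test_that("planted partitions are recovered across seeds", {
  for (seed in 101:110) {
    pb <- planted_blocks(seed)
    tom <- topological_overlap(signed_adjacency(cor(t(pb$x)), 6))
    dimnames(tom) <- list(rownames(pb$x), rownames(pb$x))
    cl <- cluster_modules(tom, network_config())
    labels <- cl$modules$module
    expect_identical(length(setdiff(unique(labels), "grey")), 2L)
    expect_gte(ari(labels, pb$truth), 0.95)
    if (seed == 101 && requireNamespace("mclust", quietly = TRUE)) {
      # helper ARI agrees with an independent implementation
      expect_equal(ari(labels, pb$truth),
                   mclust::adjustedRandIndex(labels, pb$truth),
                   tolerance = 1e-12)
    }
  }
})

test_that("noise genes stay grey and degenerate adjacency yields no modules", {
  pb <- planted_blocks(1, n_block = 100, n_noise = 10)
  tom <- topological_overlap(signed_adjacency(cor(t(pb$x)), 6))
  dimnames(tom) <- list(rownames(pb$x), rownames(pb$x))
  cl <- cluster_modules(tom, network_config())
  noise_labels <- cl$modules$module[pb$truth == 0]
  expect_true(mean(noise_labels == "grey") >= 0.9)

  zero <- matrix(0, 50, 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("g%02d", 1:50)))
  clz <- cluster_modules(topological_overlap(zero),
                         network_config(min_module_size = 5))
  expect_true(all(clz$modules$module == "grey"))

  expect_error(cluster_modules(topological_overlap(zero),
                               network_config(min_module_size = 100)),
               "min_module_size")
})

test_that("module detection is invariant under gene relabeling", {
  pb <- planted_blocks(42)
  tom <- topological_overlap(signed_adjacency(cor(t(pb$x)), 6))
  dimnames(tom) <- list(rownames(pb$x), rownames(pb$x))
  cl1 <- cluster_modules(tom, network_config())
  perm <- sample(nrow(tom))
  tom_p <- tom[perm, perm]
  cl2 <- cluster_modules(tom_p, network_config())
  m1 <- cl1$modules$module[match(rownames(tom_p), cl1$modules$gene)]
  expect_gte(ari(m1, cl2$modules$module), 0.999)
})

test_that("node centrality equals within-module row sums, ranked with ties broken by id", {
  full <- matrix(1, 3, 3); diag(full) <- 0
  dimnames(full) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cent <- node_centrality(full, c("a", "b", "c"))
  expect_equal(cent$centrality, c(2, 2, 2))
  expect_identical(cent$hub_rank, 1:3)  # ties resolved alphabetically

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  dimnames(star) <- list(paste0("g", 1:5), paste0("g", 1:5))
  cent2 <- node_centrality(star, paste0("g", 1:5))
  expect_equal(cent2$centrality, c(4, 1, 1, 1, 1))
  expect_identical(cent2$hub_rank[1], 1L)

  a <- random_adjacency(15, 11)
  mod <- sample(rownames(a), 8)
  cent3 <- node_centrality(a, mod)
  oracle <- vapply(mod, function(g) sum(a[g, setdiff(mod, g)]), numeric(1))
  expect_lt(max(abs(cent3$centrality - unname(oracle))), 1e-12)

  expect_error(node_centrality(a, character(0)), "empty")
})

test_that("top-edge export matches a brute-force sort of all edges", {
  a <- random_adjacency(12, 12)
  mod <- rownames(a)
  edges <- export_top_edges(a, mod, k = 10)
  # oracle: enumerate all pairs and sort
  pairs <- t(combn(sort(mod), 2))
  w <- a[cbind(pairs[, 1], pairs[, 2])]
  ord <- order(-w, pairs[, 1], pairs[, 2])
  expect_equal(edges$weight, w[ord][1:10])
  expect_identical(edges$node1, pairs[ord, 1][1:10])

  small <- a[1:3, 1:3]
  expect_warning(all_edges <- export_top_edges(small, rownames(small), k = 100),
                 "only 3 edges")
  expect_identical(nrow(all_edges), 3L)

  k1 <- export_top_edges(a, mod, k = 1)
  expect_equal(k1$weight, max(w))

  # VisANT dialect: three tab-separated columns, no header
  path <- withr::local_tempfile(fileext = ".txt")
  write_visant_edges(edges, path)
  lines <- readLines(path)
  expect_identical(length(lines), 10L)
  expect_identical(length(strsplit(lines[1], "\t")[[1]]), 3L)
})
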