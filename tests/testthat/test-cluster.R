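# Dimensionality reduction, scree selection, Jaccard-kNN graph geometry,
# Louvain determinism, and the 2-D embedding.

test_that("a rank-1 matrix concentrates variance in the first component", {
  set.seed(1)
  X <- outer(rnorm(30), rnorm(12))
  e <- reduce_dims(X, k = 5)
  expect_gte(e$explained_variance[1] / sum(e$explained_variance), 0.999)
})

test_that("truncated components match a dense SVD oracle on a small matrix", {
  set.seed(2)
  X <- matrix(rnorm(200), 20, 10)
  e <- reduce_dims(X, k = 4)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  dense <- sv$u[, 1:4] %*% diag(sv$d[1:4])
  for (j in 1:4) {
    s <- sign(sum(dense[, j] * e$components[, j]))
    expect_lt(max(abs(dense[, j] * s - e$components[, j])), 1e-8)
  }
  expect_true(all(diff(e$explained_variance) <= 1e-12))
})

test_that("permuting nuclei permutes component rows identically", {
  set.seed(3)
  X <- matrix(rnorm(40 * 8), 40, 8)
  e1 <- reduce_dims(X, k = 3)
  perm <- sample(40)
  e2 <- reduce_dims(X[perm, ], k = 3)
  for (j in 1:3) {
    s <- sign(sum(e1$components[perm, j] * e2$components[, j]))
    expect_lt(max(abs(e1$components[perm, j] * s - e2$components[, j])), 1e-8)
  }
})

test_that("scree plateau selection follows its rule on hand-evaluated cases", {
  ev <- c(10, 5, 1, 1, 1, 1, 1, 1) / 21
  expect_equal(select_pcs(ev, tol = 0.02), 3)
  expect_equal(select_pcs(rep(0.1, 6)), 1)
  geo <- 0.5^(0:9)
  expect_equal(select_pcs(geo / sum(geo), tol = 0), 10)
  expect_error(select_pcs(numeric(0)), "empty")
  expect_error(select_pcs(c(0.1, 0.5)), "non-increasing")
})

test_that("Jaccard weights match set enumeration on a crafted geometry", {
  # line positions: two tight triads far apart; with k = 2 each point's
  # neighbors are the other two members of its triad
  X <- cbind(c(0, 1, 2, 100, 101, 102), 0)
  g <- build_knn_graph(X, k_neighbors = 2)
  nn <- g$neighbor_index
  expect_equal(sort(nn[1, ]), c(2, 3))
  expect_equal(sort(nn[4, ]), c(5, 6))
  ig <- g$graph
  get_w <- function(i, j) {
    eid <- igraph::get_edge_ids(ig, c(i, j))
    if (eid == 0) NA_real_ else igraph::E(ig)$weight[eid]
  }
  # sets {2,3} vs {1,3}: intersection 1, union 3
  expect_equal(get_w(1, 2), 1 / 3)
  # disjoint triads: no edge
  expect_true(is.na(get_w(1, 4)))
  # sets {a,b,c} and {b,c,d} -> 2/4 with k = 3
  g3 <- build_knn_graph(X, k_neighbors = 3)
  # point 1 neighbors {2,3,4}; point 5 neighbors {4,6,3}? verify directly
  w <- g3$neighbor_index
  i <- 2; j <- 3
  inter <- length(intersect(w[i, ], w[j, ]))
  expect_equal(igraph::E(g3$graph)$weight[
    igraph::get_edge_ids(g3$graph, c(i, j))],
    inter / (6 - inter))
})

test_that("identical neighbor sets give weight 1 and weights are symmetric in (0,1]", {
  set.seed(4)
  X <- matrix(rnorm(60 * 3), 60, 3)
  g <- build_knn_graph(X)
  w <- igraph::E(g$graph)$weight
  expect_true(all(w > 0 & w <= 1))
  # square grid corners: 4 points where each pair shares the same others
  Y <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)) * 1e-6
  Y <- rbind(Y, cbind(c(10, 10, 11), c(0, 1, 0)))
  g2 <- build_knn_graph(Y, k_neighbors = 3)
  # in the tight quad, every point's 3 neighbors are the other 3; pairs
  # share 2 of 4 -> 0.5
  e <- igraph::get_edge_ids(g2$graph, c(1, 2))
  expect_equal(igraph::E(g2$graph)$weight[e], 0.5)
  expect_error(build_knn_graph(X[1:3, , drop = FALSE]), "at least 4")
})

test_that("two cliques joined by one edge give two communities; modularity matches the formula", {
  el <- rbind(t(utils::combn(1:10, 2)), t(utils::combn(11:20, 2)), c(10, 11))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(ig)$weight <- 1
  cl <- louvain_cluster(ig, seed = 5)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(length(unique(cl$labels[1:10])), 1)
  expect_equal(length(unique(cl$labels[11:20])), 1)
  # independent recomputation of weighted modularity
  w <- igraph::E(ig)$weight
  W <- sum(w)
  lab <- cl$labels
  elist <- igraph::as_edgelist(ig)
  str <- numeric(20)
  for (e in seq_len(nrow(elist))) {
    str[elist[e, 1]] <- str[elist[e, 1]] + w[e]
    str[elist[e, 2]] <- str[elist[e, 2]] + w[e]
  }
  Q <- sum(w[lab[elist[, 1]] == lab[elist[, 2]]]) / W -
    sum(tapply(str, lab, sum)^2) / (4 * W^2)
  expect_lt(abs(cl$modularity - Q), 1e-9)
  # better than the all-singletons partition
  Q_singleton <- -sum(str^2) / (4 * W^2)
  expect_gte(cl$modularity, Q_singleton)
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(6)
  X <- matrix(rnorm(120 * 4), 120, 4)
  g <- build_knn_graph(X)
  a <- louvain_cluster(g, seed = 9)
  b <- louvain_cluster(g, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$modularity, b$modularity)
  expect_equal(min(a$labels), 0)
  expect_equal(sort(unique(a$labels)), seq_along(unique(a$labels)) - 1L)
})

test_that("recovery improves (never degrades) with marker effect size over seeds", {
  ari_at <- function(fc, seed) {
    sim <- simulate_umi_matrix(sn_sim_config(
      seed = seed, n_nuclei = 400, n_genes = 600, n_clusters = 3,
      n_marker_genes_per_cluster = 45, marker_log2fc = fc,
      platform_log2fc = 0, frac_qc_fail_low_genes = 0,
      frac_qc_fail_high_mito = 0, n_de_genes = 0))
    norm <- normalize_umi(filter_genes(sim$matrix))
    e <- reduce_dims(norm, k = 40)
    cl <- louvain_cluster(build_knn_graph(e), seed = seed)
    mclust::adjustedRandIndex(cl$labels, sim$truth$cluster_labels)
  }
  seeds <- 1:5
  weak <- vapply(seeds, function(s) ari_at(0.5, s), numeric(1))
  strong <- vapply(seeds, function(s) ari_at(1.5, s), numeric(1))
  expect_gte(mean(strong), mean(weak))
})

test_that("the 2-D embedding has the right shape, is seeded, and separates planted clusters", {
  fx <- small_norm()
  e <- reduce_dims(fx$norm, k = 30)
  y1 <- embed_2d(e, seed = 3)
  y2 <- embed_2d(e, seed = 3)
  expect_equal(dim(y1), c(nrow(fx$norm$values), 2))
  expect_identical(y1, y2)
  sil <- cluster::silhouette(fx$labels, stats::dist(y1))
  expect_gt(mean(sil[, "sil_width"]), 0.2)
})
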