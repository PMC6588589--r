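# Dimensionality reduction (centered truncated SVD), scree-plateau PC
# selection, Jaccard-weighted kNN graph construction (k = round(sqrt(N))),
# Louvain community detection, and a t-SNE embedding for visualization.

#' Truncated SVD (PCA) of a normalized expression matrix
#'
#' Column-centers the matrix and computes the top-k principal directions
#' with a truncated SVD. \code{explained_variance} holds each component's
#' fraction of total variance (non-increasing). \code{k_selected} is
#' initialized with the scree-plateau rule of \code{\link{select_pcs}}.
#'
#' @param m a \code{\link{normalized_matrix}} or numeric matrix
#'   (nuclei x genes).
#' @param k number of components (default 50).
#' @param tol plateau tolerance passed to \code{\link{select_pcs}}.
#' @return List of class \code{embedding}: \code{components} (nuclei x k),
#'   \code{explained_variance}, \code{k_selected}.
#' @export
reduce_dims <- function(m, k = 50, tol = 0.02) {
  vals <- if (inherits(m, "normalized_matrix")) m$values else m
  n <- nrow(vals); g <- ncol(vals)
  if (k >= min(n, g)) stop("k must be smaller than both matrix dimensions")
  ctr <- colMeans(vals)
  total_var <- sum(apply(vals, 2, stats::var))
  if (k <= 0.5 * min(n, g) && min(n, g) > 3 * k) {
    sv <- with_seed(1L, irlba::irlba(vals, nv = k, center = ctr))
  } else {
    X <- sweep(vals, 2, ctr)
    svf <- svd(X, nu = k, nv = k)
    sv <- list(u = svf$u, d = svf$d[seq_len(k)], v = svf$v)
  }
  comps <- sv$u %*% diag(sv$d, k, k)
  ev <- sv$d^2 / (n - 1) / total_var
  rownames(comps) <- rownames(vals)
  structure(list(components = comps, explained_variance = ev,
                 k_selected = select_pcs(ev, tol = tol)),
            class = "embedding")
}

#' Select significant components by the scree-plateau rule
#'
#' Returns the smallest index j such that every subsequent drop
#' \code{ev[i] - ev[i+1]} (for i >= j) is below \code{tol * ev[1]} -- the
#' last component before the explained variance reaches its plateau. If
#' even the final drop exceeds the tolerance, returns \code{length(ev)}.
#'
#' @param ev non-increasing, non-negative explained-variance vector.
#' @param tol plateau tolerance relative to the first component's variance
#'   (default 0.02).
#' @return Integer number of selected components.
#' @export
select_pcs <- function(ev, tol = 0.02) {
  if (length(ev) == 0) stop("empty explained-variance vector")
  if (any(diff(ev) > 1e-12) || any(ev < 0))
    stop("ev must be non-increasing and non-negative")
  if (length(ev) == 1) return(1L)
  drops <- -diff(ev)
  small <- drops < tol * ev[1]
  # smallest j with all drops at indices >= j small
  bad <- which(!small)
  if (length(bad) == 0) return(1L)
  j <- max(bad) + 1L
  if (j > length(ev) - 1L) return(length(ev))
  j
}

#' Build the Jaccard-weighted nearest-neighbor graph
#'
#' Computes Euclidean k-nearest neighbors (k = \code{round(sqrt(N))},
#' excluding self, distance ties broken by nucleus index) on the first
#' \code{k_selected} components, then connects every pair that is a kNN of
#' the other in at least one direction with edge weight equal to the
#' Jaccard similarity of their neighbor sets,
#' \code{|kNN(i) n kNN(j)| / |kNN(i) u kNN(j)|}. Zero-weight pairs are
#' omitted.
#'
#' @param e an \code{embedding} from \code{\link{reduce_dims}} (or a plain
#'   numeric matrix of coordinates).
#' @param k_neighbors override the default \code{round(sqrt(N))}.
#' @return List of class \code{pl_graph}: \code{graph} (weighted undirected
#'   igraph), \code{k_neighbors}, \code{neighbor_index} (N x k matrix).
#' @export
build_knn_graph <- function(e, k_neighbors = NULL) {
  X <- if (inherits(e, "embedding"))
    e$components[, seq_len(e$k_selected), drop = FALSE] else e
  n <- nrow(X)
  if (n < 4) stop("need at least 4 nuclei to build a neighbor graph")
  k <- if (is.null(k_neighbors)) round(sqrt(n)) else k_neighbors
  k <- max(1L, min(k, n - 1L))
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn <- matrix(0L, n, k)
  for (i in seq_len(n))
    nn[i, ] <- order(d[i, ])[seq_len(k)]  # stable order: ties by index
  # sparse membership matrix: A[i, j] = 1 iff j is a kNN of i
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)           # |kNN(i) ∩ kNN(j)|
  mask <- (A + Matrix::t(A)) > 0           # kNN in at least one direction
  inter <- inter * mask
  inter <- Matrix::drop0(inter)
  Matrix::diag(inter) <- 0
  inter <- Matrix::drop0(inter)
  tri <- Matrix::which(Matrix::tril(inter, -1) > 0, arr.ind = TRUE)
  w_int <- inter[tri]
  w <- w_int / (2 * k - w_int)             # |union| = 2k - |intersection|
  g <- igraph::graph_from_edgelist(cbind(tri[, 1], tri[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  structure(list(graph = g, k_neighbors = k, neighbor_index = nn),
            class = "pl_graph")
}

#' Louvain community detection on the Jaccard-weighted graph
#'
#' Greedy weighted-modularity optimization (delegated to igraph's Louvain
#' implementation) with the RNG seeded for reproducibility.
#'
#' @param g a \code{pl_graph} from \code{\link{build_knn_graph}} or a
#'   weighted igraph object.
#' @param seed integer RNG seed; identical seeds give identical labels.
#' @param resolution modularity resolution (default 1, classic modularity).
#' @return List of class \code{cluster_assignment}: \code{labels}
#'   (contiguous integers from 0), \code{modularity}, \code{seed},
#'   \code{graph}.
#' @export
louvain_cluster <- function(g, seed = 1L, resolution = 1.0) {
  gr <- if (inherits(g, "pl_graph")) g$graph else g
  if (igraph::vcount(gr) == 0) stop("empty graph")
  comm <- with_seed(as.integer(seed),
                    igraph::cluster_louvain(gr, resolution = resolution))
  labels <- as.integer(igraph::membership(comm)) - 1L
  mod <- igraph::modularity(gr, labels + 1L,
                            weights = igraph::E(gr)$weight)
  structure(list(labels = labels, modularity = mod,
                 seed = as.integer(seed), graph = gr),
            class = "cluster_assignment")
}

#' @exportS3Method base::print
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d nuclei, %d communities, modularity %.4f\n",
              length(x$labels), length(unique(x$labels)), x$modularity))
  print(table(x$labels))
  invisible(x)
}

#' Two-dimensional t-SNE embedding of the selected components
#'
#' Visualization only; feeds no downstream statistic.
#'
#' @param e an \code{embedding} from \code{\link{reduce_dims}}.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   for small N).
#' @return N x 2 numeric matrix of coordinates.
#' @export
embed_2d <- function(e, seed = 1L, perplexity = 30) {
  X <- if (inherits(e, "embedding"))
    e$components[, seq_len(e$k_selected), drop = FALSE] else e
  perplexity <- min(perplexity, floor((nrow(X) - 1) / 3))
  out <- with_seed(as.integer(seed),
                   Rtsne::Rtsne(X, dims = 2, pca = FALSE,
                                perplexity = perplexity,
                                check_duplicates = FALSE))
  out$Y
}

#' Run the full clustering chain on a UMI matrix
#'
#' Convenience wrapper: nucleus filter, gene filter, normalization,
#' truncated SVD, scree PC selection, sqrt(N)-kNN Jaccard graph, Louvain.
#'
#' @param m a \code{\link{umi_matrix}}.
#' @param k SVD components (default 50).
#' @param seed RNG seed for the Louvain step.
#' @param drop_genes optional gene ids (e.g. platform-associated genes) to
#'   remove before reduction.
#' @return List with \code{matrix} (filtered), \code{normalized},
#'   \code{embedding}, \code{graph}, \code{clusters}.
#' @export
cluster_pipeline <- function(m, k = 50, seed = 1L, drop_genes = NULL) {
  m <- filter_nuclei(m)
  m <- filter_genes(m)
  if (!is.null(drop_genes))
    m <- subset_umi(m, j = which(!m$gene_meta$gene_id %in% drop_genes))
  norm <- normalize_umi(m)
  emb <- reduce_dims(norm, k = min(k, min(dim(norm$values)) - 1))
  gr <- build_knn_graph(emb)
  cl <- louvain_cluster(gr, seed = seed)
  list(matrix = m, normalized = norm, embedding = emb, graph = gr,
       clusters = cl)
}
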