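# Shared fixtures, built once per test run.

# small 3-population simulation reused by several files
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small_sim))
    .fixture_env$small_sim <- simulate_umi_matrix(sn_sim_config(
      seed = 101, n_nuclei = 600, n_genes = 800, n_clusters = 3,
      n_marker_genes_per_cluster = 60, marker_log2fc = 1.5,
      n_de_genes = 20, n_individuals = 8))
  .fixture_env$small_sim
}

small_norm <- function() {
  if (is.null(.fixture_env$small_norm)) {
    sim <- small_sim()
    m <- filter_genes(filter_nuclei(sim$matrix))
    .fixture_env$small_norm <- list(
      norm = normalize_umi(m),
      labels = sim$truth$cluster_labels[
        sim$matrix$nucleus_meta$barcode %in% m$nucleus_meta$barcode],
      truth = sim$truth)
  }
  .fixture_env$small_norm
}

# default-scale simulation (1500 nuclei, 2000 genes, 30 planted DE genes,
# 8 donors): the case-control DE conditions, with the target population
# holding ~450-500 nuclei
full_sim <- function() {
  if (is.null(.fixture_env$full_sim)) {
    sim <- simulate_umi_matrix(sn_sim_config(seed = 5))
    m <- filter_genes(filter_nuclei(sim$matrix))
    .fixture_env$full_sim <- list(
      norm = normalize_umi(m),
      labels = sim$truth$cluster_labels[
        sim$matrix$nucleus_meta$barcode %in% m$nucleus_meta$barcode],
      truth = sim$truth)
  }
  .fixture_env$full_sim
}

# tiny deterministic UMI matrix with hand-countable supports
toy_umi <- function() {
  counts <- rbind(
    c(5, 0, 1, 0, 2),
    c(3, 1, 0, 0, 2),
    c(0, 2, 0, 0, 1),
    c(1, 0, 0, 0, 3),
    c(2, 0, 0, 0, 0),
    c(4, 3, 0, 0, 1))
  gm <- data.frame(gene_id = paste0("G", 1:5),
                   symbol = c("A", "B", "MT-1", "C", "RPL1"),
                   stringsAsFactors = FALSE)
  nm <- data.frame(barcode = paste0("N", 1:6), stringsAsFactors = FALSE)
  umi_matrix(counts, nm, gm)
}

# adjusted Rand index against planted labels for a pipeline result
pipeline_ari <- function(sim, res) {
  keep <- sim$matrix$nucleus_meta$barcode %in% res$matrix$nucleus_meta$barcode
  mclust::adjustedRandIndex(res$clusters$labels,
                            sim$truth$cluster_labels[keep])
}
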