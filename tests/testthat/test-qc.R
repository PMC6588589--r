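# Nucleus/gene filters: exact threshold semantics, idempotence, and
# normalization identities.

# build a matrix where nucleus i expresses exactly n_expr[i] genes, with an
# optional block of mito counts
qc_toy <- function(n_expr, n_genes = 500, mito_counts = NULL) {
  n <- length(n_expr)
  counts <- matrix(0L, n, n_genes)
  for (i in seq_len(n)) counts[i, seq_len(n_expr[i])] <- 1L
  gm <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                   symbol = c("MT-1", sprintf("S%03d", seq_len(n_genes - 1))),
                   stringsAsFactors = FALSE)
  if (!is.null(mito_counts)) counts[, 1] <- as.integer(mito_counts)
  umi_matrix(counts, data.frame(barcode = paste0("N", seq_len(n))), gm)
}

test_that("the 400-expressed-genes boundary is inclusive", {
  m <- qc_toy(c(399, 400, 450))
  f <- filter_nuclei(m)
  expect_setequal(f$nucleus_meta$barcode, c("N2", "N3"))
  expect_equal(f$provenance$filter_nuclei$removed$barcode, "N1")
})

test_that("the 10 percent mito+ribo fraction boundary is exclusive", {
  # nucleus 1: 50 mito / 500 total = exactly 0.10 -> removed
  # nucleus 2: 49 mito / 499 total < 0.10 -> kept
  counts <- matrix(1L, 2, 500)
  counts[1, 1] <- 50L; counts[1, 2:50] <- 0L   # 450 ones + 50 = 500 total
  counts[2, 1] <- 49L; counts[2, 2:50] <- 0L   # 49/499 < 0.10
  gm <- data.frame(gene_id = sprintf("G%03d", 1:500),
                   symbol = c("MT-1", sprintf("S%03d", 1:499)))
  m <- umi_matrix(counts, data.frame(barcode = c("A", "B")), gm)
  frac <- Matrix::rowSums(m$counts[, gm$symbol == "MT-1", drop = FALSE]) /
    Matrix::rowSums(m$counts)
  expect_equal(frac[[1]], 0.10)
  f <- filter_nuclei(m)
  expect_equal(f$nucleus_meta$barcode, "B")
})

test_that("on simulated data the surviving nuclei equal the truth complement exactly", {
  sim <- small_sim()
  f <- filter_nuclei(sim$matrix)
  expect_setequal(f$nucleus_meta$barcode,
                  setdiff(sim$matrix$nucleus_meta$barcode,
                          sim$truth$qc_fail$barcode))
})

test_that("gene filtering matches hand-counted supports and drops mito genes", {
  m <- toy_umi()
  # supports: G1 in 5, G2 in 3, G3 (MT) in 1, G4 in 0, G5 in 5
  f <- filter_genes(m, min_nuclei = 3, drop_mito = TRUE)
  expect_setequal(f$gene_meta$gene_id, c("G1", "G2", "G5"))
  f2 <- filter_genes(m, min_nuclei = 3, drop_mito = FALSE)
  expect_setequal(f2$gene_meta$gene_id, c("G1", "G2", "G5"))
  # boundary: expressed in exactly min_nuclei kept, one fewer removed
  f3 <- filter_genes(m, min_nuclei = 5, drop_mito = FALSE)
  expect_setequal(f3$gene_meta$gene_id, c("G1", "G5"))
  # ribosomal genes are retained (G5 = RPL1 kept above)
  expect_true("G5" %in% f$gene_meta$gene_id)
})

test_that("filters are idempotent in the pipeline order", {
  sim <- small_sim()
  once <- filter_genes(filter_nuclei(sim$matrix))
  twice <- filter_genes(filter_nuclei(once))
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
})

test_that("normalization follows its closed form and preserves structure", {
  counts <- matrix(0L, 2, 3)
  counts[1, ] <- c(100L, 9900L, 0L)   # total 10000
  counts[2, ] <- c(10L, 20L, 40L)
  m <- umi_matrix(counts, data.frame(barcode = c("A", "B")),
                  data.frame(gene_id = c("g1", "g2", "g3"),
                             symbol = c("g1", "g2", "g3")))
  nm <- normalize_umi(m, scale = 10000)
  expect_equal(nm$values[1, 1], log2(101))
  expect_equal(nm$values[1, 3], 0)
  # doubling a nucleus's counts leaves its normalized vector unchanged
  m2 <- umi_matrix(counts * 2L, m$nucleus_meta, m$gene_meta)
  expect_equal(normalize_umi(m2)$values, nm$values)
  # within-nucleus rank order preserved
  expect_equal(order(nm$values[2, ]), order(counts[2, ]))
})

test_that("normalization rejects zero-total nuclei", {
  counts <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  m <- umi_matrix(counts, data.frame(barcode = c("A", "B")),
                  data.frame(gene_id = c("g1", "g2"),
                             symbol = c("g1", "g2")))
  expect_error(normalize_umi(m), "zero-total")
})

test_that("platform-gene flagging requires two platforms and controls nulls", {
  sim <- small_sim()
  one <- sim$matrix
  one$nucleus_meta$platform <- "A"
  expect_error(flag_platform_genes(one), "two platforms")
  # with no planted platform effect the flagged fraction is near zero
  null_sim <- simulate_umi_matrix(sn_sim_config(
    seed = 33, n_nuclei = 500, n_genes = 600, n_clusters = 1,
    cluster_proportions = 1, n_marker_genes_per_cluster = 0,
    marker_log2fc = 0, n_de_genes = 0, platform_log2fc = 0,
    frac_qc_fail_low_genes = 0, frac_qc_fail_high_mito = 0))
  flagged <- flag_platform_genes(null_sim$matrix)
  n_tested <- sum(!is.na(attr(flagged, "table")$p_value))
  expect_lte(length(flagged),
             0.05 * n_tested + 3 * sqrt(0.05 * 0.95 * n_tested))
})

test_that("planted platform genes are recovered with high recall and precision", {
  sim <- simulate_umi_matrix(sn_sim_config(
    seed = 34, n_nuclei = 800, n_genes = 1200, n_clusters = 1,
    cluster_proportions = 1, n_marker_genes_per_cluster = 0,
    marker_log2fc = 0, n_de_genes = 0,
    platform_gene_fraction = 50 / 1200, platform_log2fc = 1,
    frac_qc_fail_low_genes = 0, frac_qc_fail_high_mito = 0))
  flagged <- flag_platform_genes(sim$matrix)
  truth <- sim$truth$platform_gene_set
  expect_gte(mean(truth %in% flagged), 0.9)
  expect_gte(mean(flagged %in% truth), 0.8)
})
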