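# Synthetic snRNA-seq generator: gamma-Poisson UMI counts with planted
# cluster markers, diagnosis DE restricted to one target cluster, platform
# batch genes, per-donor expression shifts, and designated QC-failing nuclei.
# Ground truth is recorded so downstream stages can be scored exactly.

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the snRNA-seq simulator
#'
#' Defaults describe a desk-scale version of a multi-donor amygdala
#' experiment: eight post-mortem donors (half autism-spectrum, half
#' control) sequenced on two platforms with four dual-platform libraries,
#' a few transcriptionally distinct cell populations with planted marker
#' genes, and diagnosis-associated genes planted in a single target
#' population only.
#'
#' @param n_nuclei,n_genes matrix dimensions.
#' @param n_clusters number of planted cell populations.
#' @param cluster_proportions probability vector (sums to 1) of population
#'   sizes; default equal.
#' @param n_individuals number of donors; the first half are labelled
#'   \code{control}, the rest \code{ASD}.
#' @param n_marker_genes_per_cluster,marker_log2fc planted marker genes per
#'   population and their log2 fold change over the rest.
#' @param n_de_genes,de_log2fc,de_target_cluster diagnosis-associated genes:
#'   shift (log2) applied to ASD nuclei of the target population only.
#' @param platform_gene_fraction,platform_log2fc fraction of genes shifted
#'   on the second sequencing platform, and the shift size.
#' @param mito_gene_fraction,ribo_gene_fraction fractions of genes labelled
#'   mitochondrial (\code{MT-}) and ribosomal (\code{RPL}/\code{RPS}).
#' @param frac_qc_fail_low_genes,frac_qc_fail_high_mito fractions of nuclei
#'   planted to fail the 400-expressed-genes rule and the 10 percent
#'   mito+ribo UMI rule, respectively.
#' @param library_size_log_mean,library_size_log_sd lognormal library-size
#'   parameters (natural-log scale).
#' @param gene_dispersion shared negative-binomial dispersion (0 = Poisson).
#' @param donor_effect_sd sd of the per-donor, per-gene Gaussian intercept
#'   on the log2 mean; this is what makes nuclei from one donor correlated
#'   and a donor random intercept necessary in differential expression.
#' @param n_expression_factors,expression_factor_sd,expression_factor_decay
#'   latent per-nucleus expression programs: factor f (f = 1..n) adds
#'   \code{score ~ N(0, 1)} times gene loadings
#'   \code{N(0, (expression_factor_sd * expression_factor_decay^(f-1))^2)}
#'   to the log2 mean. These emulate the smoothly decaying variance
#'   spectrum of real data (continuous within-population variation such as
#'   maturation state), without which the scree plateau sits unrealistically
#'   early.
#' @param n_dual_individuals donors whose nuclei are split across both
#'   platforms (dual-platform libraries used to flag platform genes).
#' @param seed RNG seed; identical seeds give identical output.
#' @return A list of class \code{sn_sim_config}.
#' @export
sn_sim_config <- function(n_nuclei = 1500, n_genes = 2000, n_clusters = 3,
                          cluster_proportions = NULL, n_individuals = 8,
                          n_marker_genes_per_cluster = 150, marker_log2fc = 1.5,
                          n_de_genes = 30, de_log2fc = 1,
                          de_target_cluster = min(2, n_clusters),
                          platform_gene_fraction = 0.025, platform_log2fc = 1,
                          mito_gene_fraction = 0.01, ribo_gene_fraction = 0.04,
                          frac_qc_fail_low_genes = 0.05,
                          frac_qc_fail_high_mito = 0.05,
                          library_size_log_mean = log(3000),
                          library_size_log_sd = 0.3,
                          gene_dispersion = 0.3, donor_effect_sd = 0.1,
                          n_expression_factors = 12,
                          expression_factor_sd = 0.25,
                          expression_factor_decay = 0.9,
                          n_dual_individuals = min(4, n_individuals),
                          seed = 1L) {
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  cfg <- list(n_nuclei = n_nuclei, n_genes = n_genes, n_clusters = n_clusters,
              cluster_proportions = cluster_proportions,
              n_individuals = n_individuals,
              n_marker_genes_per_cluster = n_marker_genes_per_cluster,
              marker_log2fc = marker_log2fc, n_de_genes = n_de_genes,
              de_log2fc = de_log2fc, de_target_cluster = de_target_cluster,
              platform_gene_fraction = platform_gene_fraction,
              platform_log2fc = platform_log2fc,
              mito_gene_fraction = mito_gene_fraction,
              ribo_gene_fraction = ribo_gene_fraction,
              frac_qc_fail_low_genes = frac_qc_fail_low_genes,
              frac_qc_fail_high_mito = frac_qc_fail_high_mito,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              gene_dispersion = gene_dispersion,
              donor_effect_sd = donor_effect_sd,
              n_expression_factors = n_expression_factors,
              expression_factor_sd = expression_factor_sd,
              expression_factor_decay = expression_factor_decay,
              n_dual_individuals = n_dual_individuals, seed = as.integer(seed))
  validate_sn_sim_config(cfg)
  structure(cfg, class = "sn_sim_config")
}

validate_sn_sim_config <- function(cfg) {
  stopifnot(cfg$n_nuclei >= 1, cfg$n_genes >= 1, cfg$n_clusters >= 1,
            cfg$n_individuals >= 1, cfg$n_marker_genes_per_cluster >= 0,
            cfg$marker_log2fc >= 0, cfg$n_de_genes >= 0,
            cfg$gene_dispersion >= 0, cfg$donor_effect_sd >= 0)
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9)
    stop("cluster_proportions must sum to 1")
  fracs <- c(cfg$cluster_proportions, cfg$platform_gene_fraction,
             cfg$mito_gene_fraction, cfg$ribo_gene_fraction,
             cfg$frac_qc_fail_low_genes, cfg$frac_qc_fail_high_mito)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_de_genes > cfg$n_genes) stop("n_de_genes exceeds n_genes")
  if (cfg$de_target_cluster < 1 || cfg$de_target_cluster > cfg$n_clusters)
    stop("de_target_cluster out of range")
  n_special <- cfg$n_clusters * cfg$n_marker_genes_per_cluster +
    cfg$n_de_genes + round(cfg$platform_gene_fraction * cfg$n_genes)
  n_plain <- cfg$n_genes -
    round(cfg$mito_gene_fraction * cfg$n_genes) -
    round(cfg$ribo_gene_fraction * cfg$n_genes)
  if (n_special > floor(n_plain / 2))
    stop("not enough well-expressed genes to draw disjoint marker/DE/platform sets")
  invisible(cfg)
}

#' Simulate a multi-donor, two-platform UMI matrix with ground truth
#'
#' Counts follow a gamma-Poisson (negative binomial) law per gene. The log2
#' mean receives cluster-specific shifts for marker genes, a diagnosis shift
#' for planted DE genes within ASD nuclei of the target population, a
#' platform shift for platform genes, and a per-donor per-gene Gaussian
#' intercept. Library sizes are lognormal. Marker, DE and platform gene sets
#' are drawn disjoint (and never mitochondrial/ribosomal) so recovery can be
#' scored without ambiguity. A designated subset of nuclei is planted to
#' fail each quality rule (under 400 expressed genes; at least 10 percent of
#' UMIs mitochondrial+ribosomal) and all remaining nuclei are guaranteed to
#' pass both, so the recorded truth matches a brute-force re-check exactly.
#'
#' @param config an \code{\link{sn_sim_config}}.
#' @return A list with elements \code{matrix} (a \code{\link{umi_matrix}})
#'   and \code{truth}, a list with \code{cluster_labels} (integer 1..K per
#'   nucleus), \code{marker_gene_sets} (per-cluster character vectors),
#'   \code{de_gene_table} (gene id and planted log2 fold change),
#'   \code{platform_gene_set}, and \code{qc_fail} (data.frame of barcode and
#'   failure reason).
#' @export
simulate_umi_matrix <- function(config) {
  validate_sn_sim_config(config)
  with_seed(config$seed, simulate_umi_matrix_impl(config))
}

simulate_umi_matrix_impl <- function(cfg) {
  n <- cfg$n_nuclei; g <- cfg$n_genes; K <- cfg$n_clusters
  n_mito <- round(cfg$mito_gene_fraction * g)
  n_ribo <- round(cfg$ribo_gene_fraction * g)

  gene_id <- sprintf("G%05d", seq_len(g))
  symbol <- gene_id
  mito_idx <- seq_len(n_mito)
  ribo_idx <- if (n_ribo > 0) n_mito + seq_len(n_ribo) else integer(0)
  if (n_mito > 0) symbol[mito_idx] <- sprintf("MT-%d", seq_len(n_mito))
  if (n_ribo > 0) symbol[ribo_idx] <- sprintf("RPL%d", seq_len(n_ribo))
  plain_idx <- setdiff(seq_len(g), c(mito_idx, ribo_idx))

  # baseline relative abundance; mito+ribo tuned to ~4% of UMIs
  w <- stats::rlnorm(g, meanlog = 0, sdlog = 1)

  # disjoint special gene sets among non-mito/ribo genes, drawn from the
  # upper half of the abundance distribution: planted signal must sit on
  # genes detectable at the simulated sequencing depth, as real marker and
  # disease-effect genes are
  n_plat <- round(cfg$platform_gene_fraction * g)
  expressed_pool <- plain_idx[w[plain_idx] >= stats::median(w[plain_idx])]
  pool <- sample(expressed_pool)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  marker_idx <- lapply(seq_len(K),
                       function(kk) sort(take(cfg$n_marker_genes_per_cluster)))
  de_idx <- sort(take(cfg$n_de_genes))
  plat_idx <- sort(take(n_plat))
  mr_idx <- c(mito_idx, ribo_idx)
  if (length(mr_idx) > 0) {
    target <- 0.04
    w[mr_idx] <- w[mr_idx] *
      (target / (1 - target)) * sum(w[-mr_idx]) / sum(w[mr_idx])
  }

  # nuclei: cluster labels, donors, diagnosis, platform
  labels <- sample.int(K, n, replace = TRUE, prob = cfg$cluster_proportions)
  ind <- sample.int(cfg$n_individuals, n, replace = TRUE)
  diagnosis_by_ind <- ifelse(seq_len(cfg$n_individuals) <=
                               cfg$n_individuals / 2, "control", "ASD")
  age_by_ind <- stats::runif(cfg$n_individuals, 4, 15)
  sex_by_ind <- sample(c("M", "F"), cfg$n_individuals, replace = TRUE)
  rin_by_ind <- stats::runif(cfg$n_individuals, 6.5, 9)
  pmi_by_ind <- stats::runif(cfg$n_individuals, 4, 30)
  dual <- seq_len(cfg$n_dual_individuals)
  base_platform_by_ind <- rep(c("A", "B"),
                              length.out = cfg$n_individuals)
  platform <- base_platform_by_ind[ind]
  is_dual <- ind %in% dual
  platform[is_dual] <- sample(c("A", "B"), sum(is_dual), replace = TRUE)
  sample_id <- paste0("S", ind, "_", platform)

  # log2 mean shifts
  S <- matrix(0, n, g)
  for (kk in seq_len(K))
    if (length(marker_idx[[kk]]) > 0)
      S[labels == kk, marker_idx[[kk]]] <-
        S[labels == kk, marker_idx[[kk]]] + cfg$marker_log2fc
  de_cells <- labels == cfg$de_target_cluster & diagnosis_by_ind[ind] == "ASD"
  if (length(de_idx) > 0)
    S[de_cells, de_idx] <- S[de_cells, de_idx] + cfg$de_log2fc
  if (length(plat_idx) > 0)
    S[platform == "B", plat_idx] <-
      S[platform == "B", plat_idx] + cfg$platform_log2fc
  if (cfg$donor_effect_sd > 0) {
    E <- matrix(stats::rnorm(cfg$n_individuals * g, 0, cfg$donor_effect_sd),
                cfg$n_individuals, g)
    S <- S + E[ind, , drop = FALSE]
  }
  if (cfg$n_expression_factors > 0 && cfg$expression_factor_sd > 0) {
    # latent expression programs with geometrically decaying strength:
    # give the simulated data a smoothly decaying variance spectrum
    nf <- cfg$n_expression_factors
    Z <- matrix(stats::rnorm(n * nf), n, nf)
    Lo <- matrix(stats::rnorm(nf * g), nf, g) *
      (cfg$expression_factor_sd * cfg$expression_factor_decay^(seq_len(nf) - 1))
    S <- S + Z %*% Lo
  }

  lib <- stats::rlnorm(n, cfg$library_size_log_mean, cfg$library_size_log_sd)
  W <- sweep(2^S, 2, w, `*`)
  P <- W / rowSums(W)
  mu <- P * lib
  counts <- if (cfg$gene_dispersion > 0)
    matrix(stats::rnbinom(n * g, mu = mu, size = 1 / cfg$gene_dispersion), n, g)
  else matrix(stats::rpois(n * g, mu), n, g)

  # plant QC failures and guarantee everything else passes both rules
  n_low <- round(cfg$frac_qc_fail_low_genes * n)
  n_high <- round(cfg$frac_qc_fail_high_mito * n)
  fail_pool <- sample.int(n, n_low + n_high)
  low_set <- fail_pool[seq_len(n_low)]
  high_set <- if (n_high > 0) fail_pool[n_low + seq_len(n_high)] else integer(0)
  if (n_high > 0 && length(mr_idx) == 0)
    stop("cannot plant high-mito failures without mito/ribo genes")

  for (i in low_set) {
    expressed <- which(counts[i, ] > 0)
    if (length(expressed) >= 400) {  # truncate below the rule; else it fails already
      tgt <- sample(150:399, 1)
      drop <- sample(expressed, length(expressed) - tgt)
      counts[i, drop] <- 0
    }
  }
  for (i in high_set) {
    tot <- sum(counts[i, ]); mr <- sum(counts[i, mr_idx])
    need <- ceiling(0.15 / 0.85 * (tot - mr))  # lift fraction to ~15%
    if (mr < need) counts[i, mr_idx[1]] <- counts[i, mr_idx[1]] + (need - mr)
  }
  ok <- setdiff(seq_len(n), c(low_set, high_set))
  for (i in ok) {
    if (length(mr_idx) > 0) {
      tot <- sum(counts[i, ]); mr <- sum(counts[i, mr_idx])
      if (tot > 0 && mr / tot >= 0.10) {
        # scale mito+ribo counts down to an 8% fraction
        f <- 0.08 / 0.92 * (tot - mr) / mr
        counts[i, mr_idx] <- floor(counts[i, mr_idx] * f)
      }
    }
    n_expr <- sum(counts[i, ] > 0)
    if (n_expr < 400) {
      zeros <- setdiff(which(counts[i, ] == 0), mr_idx)
      n_add <- min(400 - n_expr, length(zeros))
      add <- zeros[order(w[zeros], decreasing = TRUE)][seq_len(n_add)]
      counts[i, add] <- 1L
    }
  }

  barcode <- sprintf("BC%05d", seq_len(n))
  nucleus_meta <- data.frame(
    barcode = barcode, sample_id = sample_id,
    individual = paste0("D", ind), diagnosis = diagnosis_by_ind[ind],
    age = age_by_ind[ind], sex = sex_by_ind[ind], RIN = rin_by_ind[ind],
    PMI = pmi_by_ind[ind], platform = platform,
    stringsAsFactors = FALSE)
  gene_meta <- data.frame(
    gene_id = gene_id, symbol = symbol,
    is_mito = seq_len(g) %in% mito_idx,
    is_ribo = seq_len(g) %in% ribo_idx, stringsAsFactors = FALSE)

  qc_fail <- data.frame(
    barcode = barcode[c(low_set, high_set)],
    reason = rep(c("low_genes", "high_mito"), c(n_low, length(high_set))),
    stringsAsFactors = FALSE)

  truth <- list(
    cluster_labels = labels,
    marker_gene_sets = lapply(marker_idx, function(ix) gene_id[ix]),
    de_gene_table = data.frame(gene_id = gene_id[de_idx],
                               log2fc = rep(cfg$de_log2fc, length(de_idx)),
                               stringsAsFactors = FALSE),
    platform_gene_set = gene_id[plat_idx],
    qc_fail = qc_fail)

  list(matrix = umi_matrix(counts, nucleus_meta, gene_meta), truth = truth)
}
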