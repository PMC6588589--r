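# Cluster marker detection (cluster vs rest, fixed effects) and
# case-control differential expression within one cluster (donor random
# intercept, demographic/technical covariates, dual fold-change filters).

#' Detect cluster marker genes (one cluster vs the rest)
#'
#' For each cluster, every gene is tested with the fixed-effects hurdle
#' model of in-cluster vs rest, with centered detection rate
#' (\code{cngeneson}) as covariate. BH-FDR is computed within each
#' cluster's tested gene set. Markers are genes with \code{fdr <
#' fdr_thresh} and composite log2 fold change \code{>= log2fc_thresh}
#' (up in the cluster).
#'
#' @param m a \code{\link{normalized_matrix}}.
#' @param clusters a \code{\link{cluster_assignment}} or integer vector of
#'   per-nucleus labels.
#' @param fdr_thresh,log2fc_thresh selection thresholds (defaults 0.05, 1).
#' @param all_genes return the full per-gene tables instead of only the
#'   selected markers.
#' @return Named list (one element per cluster) of data.frames sorted by
#'   fdr, columns \code{gene, lrt_stat, df, p_value, fdr, log2fc,
#'   converged}.
#' @export
find_markers <- function(m, clusters, fdr_thresh = 0.05, log2fc_thresh = 1,
                         all_genes = FALSE) {
  stopifnot(inherits(m, "normalized_matrix"))
  labels <- if (inherits(clusters, "cluster_assignment"))
    clusters$labels else clusters
  stopifnot(length(labels) == nrow(m$values))
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("need at least 2 clusters")
  cdr <- detection_rate(m, center = TRUE)
  out <- list()
  for (cl in ulab) {
    inside <- labels == cl
    if (sum(inside) < 2) {
      warning("singleton cluster ", cl, " skipped")
      next
    }
    grp <- factor(ifelse(inside, "cluster", "rest"),
                  levels = c("rest", "cluster"))
    res <- hurdle_test_all(m$values, grp,
                           covariates = data.frame(cngeneson = cdr))
    res$fdr <- bh_fdr(res$p_value)
    res <- res[order(res$fdr, res$p_value), ]
    if (!all_genes)
      res <- res[!is.na(res$fdr) & res$fdr < fdr_thresh &
                   res$log2fc >= log2fc_thresh & res$converged, ]
    rownames(res) <- NULL
    out[[as.character(cl)]] <- res
  }
  out
}

#' Case-control differential expression within one cell population
#'
#' For each gene expressed in at least \code{min_support} nuclei of the
#' subset, fits the full hurdle model (diagnosis + donor random intercept +
#' detection rate + age + sex + RIN + PMI) and the nested model without
#' diagnosis; significance from the summed two-component LRT (df = 2),
#' BH-FDR across tested genes. A diagnosis-only fixed-effects fit provides
#' the raw log2 fold change. The selected set requires
#' \code{|log2fc| >= log2fc_thresh}, \code{fdr < fdr_thresh} and
#' \code{|raw_log2fc| >= log2fc_thresh}; non-converged genes are excluded
#' from the selection but kept (flagged) in the table.
#'
#' @param m a \code{\link{normalized_matrix}} whose metadata carry
#'   \code{diagnosis}, \code{individual}, \code{age}, \code{sex},
#'   \code{RIN}, \code{PMI}.
#' @param subset nucleus indices or barcodes restricting the analysis to
#'   one cell population (default: all nuclei).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @param log2fc_thresh composite and raw log2 fold-change threshold
#'   (default 0.14, i.e. roughly a 10 percent expression difference).
#' @param covariates covariate columns for the full model.
#' @param min_support minimum expressing nuclei for a gene to be tested.
#' @param genes optional subset of gene ids to test.
#' @param random_intercept include the donor random intercept (default
#'   TRUE); FALSE gives the purely fixed-effects fit, which does not
#'   account for nuclei of one donor being correlated.
#' @return data.frame with one row per tested gene: \code{gene, lrt_stat,
#'   df, p_value, fdr, log2fc, raw_log2fc, converged, significant}, sorted
#'   by fdr.
#' @export
de_by_diagnosis <- function(m, subset = NULL, fdr_thresh = 0.05,
                            log2fc_thresh = 0.14,
                            covariates = c("cngeneson", "age", "sex",
                                           "RIN", "PMI"),
                            min_support = 3, genes = NULL,
                            random_intercept = TRUE) {
  stopifnot(inherits(m, "normalized_matrix"))
  idx <- if (is.null(subset)) seq_len(nrow(m$values))
  else if (is.character(subset)) match(subset, m$nucleus_meta$barcode)
  else subset
  vals <- m$values[idx, , drop = FALSE]
  meta <- m$nucleus_meta[idx, , drop = FALSE]
  dia <- factor(meta$diagnosis, levels = c("control", "ASD"))
  if (nlevels(droplevels(dia)) < 2)
    stop("subset must contain both diagnoses")
  for (dlev in levels(dia))
    if (length(unique(meta$individual[dia == dlev])) < 2)
      stop("need at least 2 individuals per diagnosis")

  dat <- data.frame(diagnosis = dia, individual = factor(meta$individual))
  dat$cngeneson <- detection_rate(vals, center = TRUE)
  for (cv in setdiff(covariates, "cngeneson")) dat[[cv]] <- meta[[cv]]
  # drop covariates that are constant in this subset (non-estimable)
  keep_cov <- vapply(covariates, function(cv)
    length(unique(dat[[cv]])) > 1, logical(1))
  if (any(!keep_cov))
    warning("dropping constant covariates: ",
            paste(covariates[!keep_cov], collapse = ", "))
  covariates <- covariates[keep_cov]

  support <- colSums(vals > 0)
  test_genes <- colnames(vals)[support >= min_support]
  if (!is.null(genes)) test_genes <- intersect(test_genes, genes)

  rows <- vector("list", length(test_genes))
  for (k in seq_along(test_genes)) {
    gid <- test_genes[k]
    y <- vals[, gid]
    full <- fit_hurdle(y, dat, "diagnosis", covariates,
                       random_intercept = if (random_intercept)
                         "individual" else NULL)
    raw <- fit_hurdle(y, dat, "diagnosis", covariates = character())
    full$raw_log2fc <- raw$log2fc
    full$gene <- gid
    rows[[k]] <- full
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_thresh &
    abs(res$log2fc) >= log2fc_thresh & abs(res$raw_log2fc) >= log2fc_thresh &
    res$converged
  res <- res[order(res$fdr, res$p_value),
             c("gene", "lrt_stat", "df", "p_value", "fdr", "log2fc",
               "raw_log2fc", "converged", "fallback", "significant")]
  rownames(res) <- NULL
  res
}
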