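# Nucleus and gene quality filters, platform-effect gene removal, and
# library-size log-normalization for UMI matrices.

#' Filter low-quality nuclei
#'
#' Retains nuclei that express at least \code{min_genes} genes (count > 0)
#' AND have a mitochondrial+ribosomal UMI fraction strictly below
#' \code{max_mito_ribo_frac}. Both boundaries follow the original filtering
#' convention: 400 genes is inclusive, the 10 percent fraction is exclusive.
#'
#' @param m a \code{\link{umi_matrix}} with \code{is_mito}/\code{is_ribo}
#'   flags populated.
#' @param min_genes minimum number of expressed genes (default 400).
#' @param max_mito_ribo_frac maximum tolerated mito+ribo UMI fraction
#'   (default 0.10, strict).
#' @return The filtered \code{umi_matrix}; removals are recorded in
#'   \code{provenance$filter_nuclei}.
#' @export
filter_nuclei <- function(m, min_genes = 400, max_mito_ribo_frac = 0.10) {
  stopifnot(inherits(m, "umi_matrix"))
  n_expr <- Matrix::rowSums(m$counts > 0)
  tot <- Matrix::rowSums(m$counts)
  mr <- m$gene_meta$is_mito | m$gene_meta$is_ribo
  mr_frac <- if (any(mr))
    Matrix::rowSums(m$counts[, mr, drop = FALSE]) / pmax(tot, 1)
  else rep(0, nrow(m$counts))
  keep <- n_expr >= min_genes & mr_frac < max_mito_ribo_frac
  if (!any(keep)) stop("all nuclei filtered out")
  removed <- data.frame(
    barcode = m$nucleus_meta$barcode[!keep],
    low_genes = n_expr[!keep] < min_genes,
    high_mito_ribo = mr_frac[!keep] >= max_mito_ribo_frac)
  m <- subset_umi(m, i = which(keep))
  m$provenance$filter_nuclei <- list(
    summary = sprintf("removed %d nuclei (min_genes=%d, max_frac=%g)",
                      nrow(removed), min_genes, max_mito_ribo_frac),
    removed = removed, min_genes = min_genes,
    max_mito_ribo_frac = max_mito_ribo_frac)
  m
}

#' Filter rarely expressed and mitochondrial genes
#'
#' Removes genes expressed (count > 0) in fewer than \code{min_nuclei}
#' nuclei and, when \code{drop_mito}, all mitochondrial genes. Ribosomal
#' genes participate in the nucleus-level fraction rule but are retained
#' here.
#'
#' @param m a \code{\link{umi_matrix}}.
#' @param min_nuclei minimum supporting nuclei (default 3).
#' @param drop_mito drop all \code{is_mito} genes (default TRUE).
#' @return Filtered \code{umi_matrix} with provenance.
#' @export
filter_genes <- function(m, min_nuclei = 3, drop_mito = TRUE) {
  stopifnot(inherits(m, "umi_matrix"))
  support <- Matrix::colSums(m$counts > 0)
  keep <- support >= min_nuclei
  if (drop_mito) keep <- keep & !m$gene_meta$is_mito
  if (!any(keep)) stop("all genes filtered out")
  removed <- m$gene_meta$gene_id[!keep]
  m <- subset_umi(m, j = which(keep))
  m$provenance$filter_genes <- list(
    summary = sprintf("removed %d genes (min_nuclei=%d, drop_mito=%s)",
                      length(removed), min_nuclei, drop_mito),
    removed = removed, min_nuclei = min_nuclei, drop_mito = drop_mito)
  m
}

#' Flag genes associated with sequencing platform
#'
#' Using only nuclei from samples sequenced on both platforms, tests each
#' gene for a platform effect with the fixed-effects hurdle model (detection
#' rate as covariate) and returns genes with BH-FDR below
#' \code{fdr_thresh} and absolute composite log2 fold change above
#' \code{log2fc_thresh}. The returned set is meant to be removed before
#' dimensionality reduction.
#'
#' @param m a \code{\link{umi_matrix}} (filtered).
#' @param dual_samples values of \code{sample_id} present on both platforms;
#'   default: all samples whose individual appears on both platforms.
#' @param fdr_thresh,log2fc_thresh selection thresholds (defaults 0.05, 0.1).
#' @return Character vector of flagged gene ids; the full per-gene table is
#'   attached as attribute \code{"table"}.
#' @export
flag_platform_genes <- function(m, dual_samples = NULL, fdr_thresh = 0.05,
                                log2fc_thresh = 0.1) {
  stopifnot(inherits(m, "umi_matrix"))
  meta <- m$nucleus_meta
  if (is.null(dual_samples)) {
    tab <- unique(meta[, c("individual", "platform")])
    both <- names(which(table(tab$individual) >= 2))
    dual_samples <- unique(meta$sample_id[meta$individual %in% both])
  }
  sel <- meta$sample_id %in% dual_samples
  if (length(unique(meta$platform[sel])) < 2)
    stop("dual samples must cover at least two platforms")
  sub <- subset_umi(m, i = which(sel))
  norm <- normalize_umi(sub)
  cdr <- detection_rate(norm, center = TRUE)
  res <- hurdle_test_all(norm$values,
                         group = factor(sub$nucleus_meta$platform),
                         covariates = data.frame(cngeneson = cdr))
  res$fdr <- bh_fdr(res$p_value)
  flagged <- res$gene[!is.na(res$fdr) & res$fdr < fdr_thresh &
                        abs(res$log2fc) > log2fc_thresh]
  structure(flagged, table = res)
}

#' Library-size normalize and log-transform a UMI matrix
#'
#' \code{value[i, g] = log2(1 + scale * count[i, g] / total[i])}: counts are
#' scaled to a common per-nucleus total and log2-transformed with a
#' pseudocount of 1, so zeros stay zero and within-nucleus rank order is
#' preserved.
#'
#' @param m a \code{\link{umi_matrix}} with no zero-total nuclei.
#' @param scale common per-nucleus total (default 10000).
#' @return A \code{\link{normalized_matrix}}.
#' @export
normalize_umi <- function(m, scale = 10000) {
  stopifnot(inherits(m, "umi_matrix"), scale > 0)
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0)) stop("zero-total nuclei present; run filter_nuclei first")
  vals <- as.matrix(m$counts / tot) * scale
  vals <- log2(1 + vals)
  dimnames(vals) <- dimnames(m$counts)
  prov <- m$provenance
  prov$normalize <- list(summary = sprintf("log2(1 + %g * count/total)", scale),
                         scale = scale)
  normalized_matrix(vals, m$nucleus_meta, m$gene_meta,
                    normalization_scale = scale, provenance = prov)
}
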