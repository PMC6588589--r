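#' UMI count matrix with nucleus and gene metadata
#'
#' The central container of the snRNA-seq pipeline: a sparse nuclei x genes
#' matrix of deduplicated transcript (UMI) counts together with per-nucleus
#' and per-gene annotation tables.
#'
#' @param counts sparse or dense non-negative integer matrix, nuclei in rows,
#'   genes in columns. Coerced to \code{dgCMatrix}.
#' @param nucleus_meta data.frame with one row per nucleus. Expected columns
#'   for the full pipeline: \code{barcode}, \code{sample_id},
#'   \code{individual}, \code{diagnosis}, \code{age}, \code{sex}, \code{RIN},
#'   \code{PMI}, \code{platform}. Only \code{barcode} is mandatory.
#' @param gene_meta data.frame with one row per gene: \code{gene_id},
#'   \code{symbol}, and logical flags \code{is_mito}, \code{is_ribo}. When
#'   the flags are absent they are derived from symbol prefixes
#'   (\code{MT-} for mitochondrial, \code{RPL}/\code{RPS} for ribosomal).
#'
#' @return An object of class \code{umi_matrix}: a list with elements
#'   \code{counts}, \code{nucleus_meta}, \code{gene_meta} and a
#'   \code{provenance} list recording filtering history.
#' @export
umi_matrix <- function(counts, nucleus_meta, gene_meta) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  stopifnot(is.data.frame(nucleus_meta), is.data.frame(gene_meta))
  if (nrow(nucleus_meta) != nrow(counts))
    stop("nucleus_meta rows must match matrix rows")
  if (nrow(gene_meta) != ncol(counts))
    stop("gene_meta rows must match matrix columns")
  if (is.null(nucleus_meta$barcode))
    nucleus_meta$barcode <- paste0("N", seq_len(nrow(counts)))
  if (is.null(gene_meta$gene_id))
    gene_meta$gene_id <- paste0("G", seq_len(ncol(counts)))
  if (is.null(gene_meta$symbol)) gene_meta$symbol <- gene_meta$gene_id
  if (is.null(gene_meta$is_mito))
    gene_meta$is_mito <- startsWith(gene_meta$symbol, "MT-")
  if (is.null(gene_meta$is_ribo))
    gene_meta$is_ribo <- startsWith(gene_meta$symbol, "RPL") |
      startsWith(gene_meta$symbol, "RPS")
  rownames(counts) <- nucleus_meta$barcode
  colnames(counts) <- gene_meta$gene_id
  structure(
    list(counts = counts, nucleus_meta = nucleus_meta, gene_meta = gene_meta,
         provenance = list()),
    class = "umi_matrix")
}

#' @exportS3Method base::print
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d nuclei x %d genes (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) /
                (as.numeric(nrow(x$counts)) * ncol(x$counts))))
  for (step in names(x$provenance))
    cat(" -", step, ":", x$provenance[[step]]$summary, "\n")
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

# subset nuclei (i) and/or genes (j), keeping metadata in register
subset_umi <- function(m, i = NULL, j = NULL) {
  if (!is.null(i)) {
    m$counts <- m$counts[i, , drop = FALSE]
    m$nucleus_meta <- m$nucleus_meta[i, , drop = FALSE]
    rownames(m$nucleus_meta) <- NULL
  }
  if (!is.null(j)) {
    m$counts <- m$counts[, j, drop = FALSE]
    m$gene_meta <- m$gene_meta[j, , drop = FALSE]
    rownames(m$gene_meta) <- NULL
  }
  m
}

#' Log-normalized expression matrix
#'
#' @param values dense numeric nuclei x genes matrix of log2-normalized
#'   expression.
#' @param nucleus_meta,gene_meta metadata tables carried over from the
#'   source \code{umi_matrix}.
#' @param normalization_scale scale factor used during normalization.
#' @param provenance filtering/normalization history list.
#' @return An object of class \code{normalized_matrix}.
#' @export
normalized_matrix <- function(values, nucleus_meta, gene_meta,
                              normalization_scale, provenance = list()) {
  stopifnot(nrow(values) == nrow(nucleus_meta),
            ncol(values) == nrow(gene_meta), normalization_scale > 0)
  structure(
    list(values = values, nucleus_meta = nucleus_meta, gene_meta = gene_meta,
         normalization_scale = normalization_scale, provenance = provenance),
    class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d nuclei x %d genes (log2, scale %g)\n",
              nrow(x$values), ncol(x$values), x$normalization_scale))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)
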