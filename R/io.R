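# Disk interchange: 10x-style MTX triplet directories for UMI matrices,
# CSV for metadata and histology tables, JSON for simulation truth.

#' Write a UMI matrix as a 10x-style directory
#'
#' Writes \code{matrix.mtx} (genes x barcodes, 1-based triplets),
#' \code{genes.tsv} (id, symbol), \code{barcodes.tsv}, and
#' \code{metadata.csv} (the nucleus table).
#'
#' @param m a \code{\link{umi_matrix}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_umi_matrix <- function(m, dir) {
  stopifnot(inherits(m, "umi_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(m$gene_meta[, c("gene_id", "symbol")],
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$nucleus_meta$barcode, file.path(dir, "barcodes.tsv"))
  utils::write.csv(m$nucleus_meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a UMI matrix from a 10x-style directory
#'
#' @param dir directory holding \code{matrix.mtx}, \code{genes.tsv},
#'   \code{barcodes.tsv} and optionally \code{metadata.csv}.
#' @return A \code{\link{umi_matrix}}.
#' @export
read_umi_matrix <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             col.names = c("gene_id", "symbol"),
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.csv")
  nucleus_meta <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  else data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  umi_matrix(counts, nucleus_meta, genes)
}

#' Write simulation truth as JSON
#'
#' @param truth truth list from \code{\link{simulate_umi_matrix}} or
#'   \code{\link{simulate_histology_counts}}.
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  truth$section_effects <- NULL  # named vectors round-trip poorly
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a histology cell-count table from CSV
#'
#' Expected columns: \code{stack_id}, \code{individual}, \code{age},
#'   \code{region}, \code{section}, one or more \code{*_count} columns,
#'   \code{dapi_count}, \code{area_mm2}.
#'
#' @param path CSV path.
#' @return data.frame; count columns validated non-negative and bounded by
#'   \code{dapi_count} where applicable, areas positive.
#' @export
read_cell_counts <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "age", "area_mm2")
  if (!all(need %in% names(t)))
    stop("missing columns: ", paste(setdiff(need, names(t)), collapse = ", "))
  if (any(t$area_mm2 <= 0)) stop("areas must be positive")
  cnt <- grep("_count$", names(t), value = TRUE)
  for (cc in cnt) if (any(t[[cc]] < 0)) stop("negative count in ", cc)
  if ("dapi_count" %in% names(t))
    for (cc in setdiff(cnt, "dapi_count"))
      if (any(t[[cc]] > t$dapi_count))
        stop(cc, " exceeds dapi_count in some rows")
  t
}
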