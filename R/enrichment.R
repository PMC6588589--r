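# Gene-set overrepresentation testing: one-sided hypergeometric tail
# against user-supplied gene sets (GMT), BH-FDR across tested terms.

#' Read a GMT gene-set file
#'
#' Tab-separated lines: term id, description, then gene ids. The
#' description column is retained (term name).
#'
#' @param path GMT file path.
#' @return Named list of class \code{gene_set_collection}; each element has
#'   \code{name} and \code{genes}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    list(name = f[2], genes = unique(f[-(1:2)]))
  })
  ids <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' Build a gene-set collection from a named list
#'
#' @param sets named list of character vectors (term id -> genes).
#' @param names optional character vector of term descriptions.
#' @return A \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  stopifnot(!is.null(base::names(sets)), !anyDuplicated(base::names(sets)))
  if (is.null(names)) names <- base::names(sets)
  out <- mapply(function(g, nm) list(name = nm, genes = unique(g)),
                sets, names, SIMPLIFY = FALSE)
  if (any(vapply(out, function(s) length(s$genes) == 0, logical(1))))
    stop("gene sets must be non-empty")
  structure(out, class = "gene_set_collection")
}

#' Hypergeometric overrepresentation test
#'
#' For each term, intersects its gene set with the background and computes
#' the one-sided hypergeometric tail probability
#' P(X >= overlap) of drawing at least the observed overlap when
#' \code{length(foreground)} genes are sampled from the background. Terms
#' with no background overlap are skipped. BH-FDR across the tested terms;
#' rows with \code{fdr < fdr_thresh} are returned sorted by fdr.
#'
#' @param foreground character vector of selected genes (must be a subset
#'   of the background).
#' @param background character vector: all genes that could have been
#'   selected (e.g. all genes tested for differential expression).
#' @param sets a \code{\link{gene_set_collection}}.
#' @param fdr_thresh FDR threshold (default 0.05).
#' @param all return all tested terms, not only those passing the
#'   threshold.
#' @return data.frame: \code{term, name, overlap, term_size, fg_size,
#'   bg_size, fold_enrichment, p_value, fdr}.
#' @export
test_overrepresentation <- function(foreground, background, sets,
                                    fdr_thresh = 0.05, all = FALSE) {
  foreground <- unique(foreground); background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  N <- length(background); n_fg <- length(foreground)
  rows <- lapply(names(sets), function(id) {
    term_genes <- intersect(sets[[id]]$genes, background)
    m <- length(term_genes)
    if (m == 0) return(NULL)
    ov <- length(intersect(term_genes, foreground))
    p <- stats::phyper(ov - 1, m, N - m, n_fg, lower.tail = FALSE)
    data.frame(term = id, name = sets[[id]]$name, overlap = ov,
               term_size = m, fg_size = n_fg, bg_size = N,
               fold_enrichment = (ov / n_fg) / (m / N), p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term overlaps the background")
  res$fdr <- bh_fdr(res$p_value)
  res <- res[order(res$fdr, res$p_value), ]
  if (!all) res <- res[res$fdr < fdr_thresh, ]
  rownames(res) <- NULL
  res
}
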