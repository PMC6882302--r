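# Rank-based single-sample gene-set enrichment scores (used for mitotic
# cell-cycle signatures). A ssGSEA-style running-sum statistic is computed
# per sample; it captures the rank-ordering signal that kernel-based
# single-sample scorers (GSVA) detect, without reproducing their estimator.

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one signature per line, tab-separated name, description,
#' then member genes.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (unique member genes);
#'   descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("GMT lines must have at least 3 fields (name, description, genes)",
         call. = FALSE)
  }
  sigs <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sigs) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sigs))) {
    stop("duplicate signature name(s) in ", path, call. = FALSE)
  }
  attr(sigs, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1), 2L), names(sigs))
  sigs
}

#' Single-sample running-sum enrichment score
#'
#' Kolmogorov-Smirnov-like statistic on one sample's gene ranks: genes are
#' walked in decreasing-abundance order (ties broken lexicographically by
#' gene identifier for determinism), stepping up by `1/k` for each of the `k`
#' signature genes present and down by `1/(N - k)` otherwise; the score is
#' the running sum at its maximum absolute deviation, keeping its sign.
#' Scores lie in `[-1, 1]`: near +1 when signature genes occupy the top
#' ranks, near -1 when they occupy the bottom. Being rank-based, the score
#' is invariant under strictly increasing transforms of the abundances.
#'
#' @param x Named numeric vector: one sample's normalized abundances (at
#'   least 10 genes, unique names).
#' @param genes Character vector: the signature's member genes.
#' @return Score in `[-1, 1]`, or `NA` when no signature gene is present
#'   (missing-signature sentinel).
#' @export
sample_enrichment_score <- function(x, genes) {
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("`x` must be named by unique gene identifiers", call. = FALSE)
  }
  if (length(x) < 10L) {
    stop("the expression vector must contain at least 10 genes",
         call. = FALSE)
  }
  ord <- order(-x, names(x), method = "radix")
  inset <- names(x)[ord] %in% genes
  k <- sum(inset)
  if (k == 0L) return(NA_real_)
  n_out <- length(x) - k
  steps <- ifelse(inset, 1 / k, if (n_out > 0L) -1 / n_out else 0)
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Enrichment score matrix
#'
#' Applies [sample_enrichment_score()] to every (signature, sample) pair.
#'
#' @param expr Normalized abundance matrix (genes x samples).
#' @param signatures Named list of gene identifier vectors (e.g. from
#'   [read_gmt()]).
#' @return Numeric matrix (signatures x samples); `NA` entries mark
#'   signatures with no gene present.
#' @export
enrichment_matrix <- function(expr, signatures) {
  stopifnot(is.matrix(expr), is.list(signatures), length(signatures) > 0L)
  out <- vapply(seq_len(ncol(expr)), function(j) {
    x <- stats::setNames(expr[, j], rownames(expr))
    vapply(signatures, function(s) sample_enrichment_score(x, s), numeric(1))
  }, numeric(length(signatures)))
  out <- matrix(out, nrow = length(signatures),
                dimnames = list(names(signatures), colnames(expr)))
  out
}
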