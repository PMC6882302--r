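# Count-matrix and sample-design I/O, library-size normalization, and the
# expressed-gene filter.

#' Read a gene-level count matrix
#'
#' Expects an HTSeq-count style TSV: a header row of sample identifiers, a
#' first column of gene identifiers, and non-negative numeric cells. HTSeq
#' summary rows (identifiers beginning `"__"`, e.g. `__no_feature`) are
#' dropped and counted in a message.
#'
#' @param path Path to the counts TSV.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  summary_rows <- startsWith(ids, "__")
  if (any(summary_rows)) {
    message("read_counts: dropped ", sum(summary_rows),
            " HTSeq summary row(s): ",
            paste(ids[summary_rows], collapse = ", "))
    df <- df[!summary_rows, , drop = FALSE]
    ids <- ids[!summary_rows]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells in ", path, call. = FALSE)
  if (any(m < 0)) stop("negative count value(s) in ", path, call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a count (or normalized abundance) matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: `sample_id`, `procedure` (surgical procedure label), `timepoint_h`
#' (hours post surgery), `replicate`, `is_reference` (0/1 flag marking the
#' normal/reference group used for the tolerance interval).
#'
#' @param path Path to the design TSV.
#' @return A tibble with `is_reference` as logical.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "procedure", "timepoint_h", "replicate",
                "is_reference")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("design file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$is_reference <- as.logical(as.integer(df$is_reference))
  validate_design(tibble::as_tibble(df))
}

#' Write a sample design table
#'
#' @param design Design tibble (see [read_design()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  design <- as.data.frame(design)
  design$is_reference <- as.integer(design$is_reference)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_design <- function(design, m = NULL) {
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  if (sum(design$is_reference) < 2L) {
    stop("the design must flag at least 2 reference samples ",
         "(needed for a tolerance interval)", call. = FALSE)
  }
  if (!is.null(m)) {
    if (!setequal(colnames(m), design$sample_id)) {
      stop("samples in the matrix and the design do not match", call. = FALSE)
    }
  }
  design
}

#' Normalize a count matrix for library size
#'
#' `cpm` scales every column to counts per million (column sums of 10^6);
#' `median_ratio` scales each column by the median of per-gene ratios to a
#' geometric-mean pseudo-reference (computed over genes with all-positive
#' counts); `none` returns the input unchanged. The PAS statistic depends
#' only on case-to-reference expression ratios, which `cpm` preserves up to
#' library-size factors.
#'
#' @param m Counts matrix (genes x samples).
#' @param method One of `"cpm"`, `"median_ratio"`, `"none"`.
#' @return Normalized matrix, same shape and dimnames.
#' @export
normalize_counts <- function(m, method = c("cpm", "median_ratio", "none")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), is.numeric(m))
  if (method == "none") return(m)
  if (method == "cpm") {
    cs <- colSums(m)
    if (any(cs <= 0)) {
      stop("cpm normalization is undefined for an all-zero column: ",
           paste(colnames(m)[cs <= 0], collapse = ", "), call. = FALSE)
    }
    return(sweep(m, 2L, cs, "/") * 1e6)
  }
  # median_ratio
  pos <- rowSums(m <= 0) == 0L
  if (!any(pos)) {
    stop("median-ratio normalization needs at least one gene with ",
         "all-positive counts", call. = FALSE)
  }
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / ref, 2L, stats::median)
  sweep(m, 2L, sf, "/")
}

#' Filter to expressed genes
#'
#' Keeps genes with at least `min_count` in at least `min_samples` samples;
#' row order is preserved. Idempotent.
#'
#' @param m Counts matrix (genes x samples).
#' @param min_count Minimum count, default 10 (the conventional "expressed"
#'   read-count threshold).
#' @param min_samples Minimum number of samples reaching `min_count`.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(m, min_count = 10, min_samples = 1) {
  stopifnot(is.matrix(m), min_count >= 0, min_samples >= 1)
  if (min_samples > ncol(m)) {
    stop("`min_samples` (", min_samples, ") exceeds the number of samples (",
         ncol(m), ")", call. = FALSE)
  }
  m[rowSums(m >= min_count) >= min_samples, , drop = FALSE]
}
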