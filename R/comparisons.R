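# Cross-condition structure: Venn partitions of significant-pathway sets,
# PAS ratios, hierarchical clustering, PCA, correlation matrices, and
# per-pathway time profiles.

#' Venn partition of named sets
#'
#' Splits the union of 2-4 named sets into the disjoint regions of the Venn
#' diagram. Region keys name the sets whose intersection (minus all other
#' sets) they represent, joined by `"\u2229"`; every element of every input
#' appears in exactly one region.
#'
#' @param sets Named list of 2-4 character vectors; labels must be unique.
#' @return Object of class `venn_partition`: list with `sets` (labels),
#'   `regions` (named list of members per non-empty label combination) and
#'   `counts`.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L) {
    stop("`sets` must be a named list of 2 to 4 character vectors",
         call. = FALSE)
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("set labels must be non-empty and unique", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  elements <- unique(unlist(sets, use.names = FALSE))
  membership <- matrix(FALSE, nrow = length(elements), ncol = length(sets),
                       dimnames = list(elements, labels))
  for (lab in labels) membership[, lab] <- elements %in% sets[[lab]]
  key_of <- apply(membership, 1L, function(row) {
    paste(labels[row], collapse = "\u2229")
  })
  regions <- split(elements, key_of)
  # order regions: singletons in input-label order, then larger combinations
  k <- length(labels)
  combos <- unlist(lapply(seq_len(k), function(sz) {
    apply(utils::combn(labels, sz), 2L, paste, collapse = "\u2229")
  }))
  regions <- regions[intersect(combos, names(regions))]
  structure(
    list(sets = labels, regions = regions,
         counts = vapply(regions, length, integer(1))),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> of", length(x$sets), "sets:",
      paste(x$sets, collapse = ", "), "\n")
  for (k in names(x$counts)) cat("  ", k, ": ", x$counts[[k]], "\n", sep = "")
  invisible(x)
}

#' Members of one Venn region
#'
#' @param vp A [venn_partition()].
#' @param labels Character vector of set labels defining the region (the
#'   element belongs to exactly these sets).
#' @return Character vector of members (empty if the region is empty).
#' @export
venn_region <- function(vp, labels) {
  stopifnot(inherits(vp, "venn_partition"), all(labels %in% vp$sets))
  key <- paste(vp$sets[vp$sets %in% labels], collapse = "\u2229")
  if (key %in% names(vp$regions)) vp$regions[[key]] else character()
}

#' Ratio of PAS values between two conditions
#'
#' Signed ratio `PAS(numerator column) / PAS(denominator column)` for one
#' pathway of a per-condition PAS table. A zero denominator yields `NA` (an
#' undefined-ratio sentinel) with a warning.
#'
#' @param table Data frame with a `pathway` column and one numeric column
#'   per condition.
#' @param pathway Pathway key (row) to compare.
#' @param numerator,denominator Names of the two condition columns.
#' @return Numeric scalar, or `NA` when undefined.
#' @export
pas_ratio <- function(table, pathway, numerator, denominator) {
  stopifnot(is.data.frame(table), "pathway" %in% names(table))
  row <- which(table$pathway == pathway)
  if (length(row) != 1L) {
    stop("pathway '", pathway, "' does not identify exactly one row",
         call. = FALSE)
  }
  a <- table[[numerator]][row]
  b <- table[[denominator]][row]
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (b == 0) {
    warning("zero denominator PAS for '", pathway, "'; ratio undefined",
            call. = FALSE)
    return(NA_real_)
  }
  a / b
}

#' Hierarchical clustering of a PAS (or expression) matrix
#'
#' Average-linkage agglomerative clustering of the matrix columns (or rows),
#' with Pearson distance (1 - Pearson correlation) or Euclidean distance.
#' Constant vectors have undefined correlation; their Pearson distance is set
#' to the maximum (2) with a message. Ties in the distance matrix are broken
#' deterministically by original column index (the order [stats::hclust()]
#' scans pairs).
#'
#' @param m Numeric matrix.
#' @param metric `"pearson"` or `"euclidean"`.
#' @param linkage Agglomeration method; default (and the intended use)
#'   `"average"`.
#' @param margin Cluster `"columns"` (default) or `"rows"`.
#' @return An [stats::hclust()] tree (merge heights, merge order, labels).
#' @export
hierarchical_cluster <- function(m, metric = c("pearson", "euclidean"),
                                 linkage = "average",
                                 margin = c("columns", "rows")) {
  metric <- match.arg(metric)
  margin <- match.arg(margin)
  stopifnot(is.matrix(m), is.numeric(m))
  if (margin == "rows") m <- t(m)
  if (ncol(m) < 2L) {
    stop("clustering needs at least 2 ", margin, call. = FALSE)
  }
  if (metric == "pearson") {
    cc <- suppressWarnings(stats::cor(m))
    if (anyNA(cc)) {
      message("hierarchical_cluster: constant column(s); Pearson distance ",
              "set to the maximum (2)")
      cc[is.na(cc)] <- -1
    }
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(t(m))
  }
  stats::hclust(d, method = linkage)
}

#' Principal component analysis of samples in pathway (or gene) space
#'
#' Column-centered PCA of the samples (matrix columns). For a deterministic
#' output each component's loading vector is oriented so that its
#' largest-magnitude element is positive.
#'
#' @param m Numeric matrix (features x samples).
#' @param n_components Number of components to return; at most
#'   `min(n_samples, n_features)`.
#' @return List with `coordinates` (tibble: sample, PC1..PCk),
#'   `variance_explained` (fractions of total variance, non-increasing,
#'   summing to at most 1), and `rotation` (feature loadings).
#' @export
pca_transform <- function(m, n_components = 2) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (n_components < 1L || n_components > min(dim(m))) {
    stop("`n_components` must lie in [1, ", min(dim(m)), "]", call. = FALSE)
  }
  x <- t(m)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::as_tibble(scores)
  coords <- tibble::add_column(coords, sample = colnames(m), .before = 1L)
  list(coordinates = coords, variance_explained = ve[seq_len(k)],
       rotation = rot, center = pc$center)
}

#' Pearson (or Kendall) correlation matrix, cluster-ordered
#'
#' Pairwise correlations between matrix columns (samples) or rows
#' (pathways); symmetric with unit diagonal. Correlations involving a
#' constant vector are undefined and set to 0 with a warning. When
#' `order = TRUE` rows/columns are reordered by the leaf order of an
#' average-linkage Pearson-distance clustering.
#'
#' @param m Numeric matrix.
#' @param margin Correlate `"columns"` (default) or `"rows"`.
#' @param method `"pearson"` (default) or `"kendall"`.
#' @param order Reorder by hierarchical clustering? Default `TRUE`.
#' @return Correlation matrix.
#' @export
correlation_matrix <- function(m, margin = c("columns", "rows"),
                               method = c("pearson", "kendall"),
                               order = TRUE) {
  margin <- match.arg(margin)
  method <- match.arg(method)
  stopifnot(is.matrix(m), is.numeric(m))
  if (margin == "rows") m <- t(m)
  if (nrow(m) < 2L) {
    stop("correlation needs at least 2 observations per vector",
         call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(m, method = method))
  if (anyNA(cc)) {
    warning("constant vector(s); undefined correlations set to 0",
            call. = FALSE)
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  if (order && ncol(cc) > 2L) {
    hc <- hierarchical_cluster(m, metric = "pearson")
    cc <- cc[hc$order, hc$order]
  }
  cc
}

#' Group PAS time profiles
#'
#' Mean PAS per pathway for every (procedure, timepoint) cell of the design,
#' ordered by increasing timepoint within each procedure.
#'
#' @param pas PAS matrix (pathways x samples).
#' @param design Sample design tibble (see [read_design()]).
#' @return Tibble with columns `pathway`, `procedure`, `timepoint_h`,
#'   `group_pas`.
#' @export
time_profiles <- function(pas, design) {
  stopifnot(is.matrix(pas))
  idx <- match(design$sample_id, colnames(pas))
  if (anyNA(idx)) {
    stop("design sample(s) missing from the PAS matrix", call. = FALSE)
  }
  cells <- dplyr::distinct(design, .data$procedure, .data$timepoint_h)
  cells <- dplyr::arrange(cells, .data$procedure, .data$timepoint_h)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ids <- design$sample_id[design$procedure == cells$procedure[i] &
                              design$timepoint_h == cells$timepoint_h[i]]
    tibble::tibble(
      pathway = rownames(pas),
      procedure = cells$procedure[i],
      timepoint_h = cells$timepoint_h[i],
      group_pas = unname(rowMeans(pas[, ids, drop = FALSE]))
    )
  })
  dplyr::bind_rows(out)
}
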