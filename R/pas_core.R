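# The PAS engine: case-to-normal ratios (CNR), beyond-tolerance-interval
# flags (BTIF), and pathway activation strength
#   PAS(p, s) = sum over member genes n of ARR(n, p) * BTIF(n, s) * log10(CNR(n, s)).

reference_samples_of <- function(m, design) {
  design <- validate_design(design, m)
  ref <- design$sample_id[design$is_reference]
  match(ref, colnames(m))
}

#' Case-to-normal expression ratios
#'
#' For every gene and sample, the ratio of the (pseudocounted) expression
#' value to the mean over the reference group. Reference samples are scored
#' against the full reference set (leave-self-in), so a reference group whose
#' samples all equal their mean yields CNR = 1 everywhere. A positive
#' pseudocount guarantees finite, strictly positive ratios; it is applied
#' symmetrically to case and reference values.
#'
#' @param m Normalized expression matrix (genes x samples).
#' @param design Sample design tibble (see [read_design()]); at least 2
#'   samples must carry `is_reference = TRUE`.
#' @param pseudocount Non-negative value added to every cell before taking
#'   ratios; default 1 on the normalized scale.
#' @return CNR matrix, same shape and dimnames as `m`.
#' @export
compute_cnr <- function(m, design, pseudocount = 1) {
  stopifnot(is.matrix(m), is.numeric(m), pseudocount >= 0)
  ref <- reference_samples_of(m, design)
  mp <- m + pseudocount
  ref_mean <- rowMeans(mp[, ref, drop = FALSE])
  mp / ref_mean
}

#' Beyond-tolerance-interval flags
#'
#' A gene is flagged (1) in a sample only when both criteria demarking
#' significantly perturbed expression hold: the CNR leaves the fold band
#' (`CNR <= fold_low` or `CNR >= fold_high`, inclusive) and the expression
#' value falls outside the reference tolerance interval, i.e. the two-sided
#' Gaussian tail probability of `log2(value + pseudocount)` under the
#' reference log2 mean and standard deviation is below `alpha`. The reference
#' standard deviation is floored at `sd_floor` log2 units to keep the test
#' defined for small reference groups and zero-variance genes.
#'
#' @inheritParams compute_cnr
#' @param cnr CNR matrix from [compute_cnr()] (same shape as `m`).
#' @param alpha Tolerance-interval significance level in (0, 1); default 0.05.
#' @param fold_low,fold_high Fold-band bounds; defaults 0.66 and 1.5.
#' @param sd_floor Lower bound on the reference log2 standard deviation.
#' @return 0/1 matrix, same shape and dimnames as `m`.
#' @export
compute_btif <- function(m, cnr, design, alpha = 0.05, fold_low = 0.66,
                         fold_high = 1.5, pseudocount = 1, sd_floor = 0.1) {
  stopifnot(is.matrix(m), identical(dim(m), dim(cnr)))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (fold_low >= fold_high) {
    stop("`fold_low` must be below `fold_high`", call. = FALSE)
  }
  ref <- reference_samples_of(m, design)
  l2 <- log2(m + pseudocount)
  mu <- rowMeans(l2[, ref, drop = FALSE])
  sd_ref <- pmax(apply(l2[, ref, drop = FALSE], 1L, stats::sd), sd_floor)
  z <- (l2 - mu) / sd_ref
  p <- 2 * stats::pnorm(-abs(z))
  flag <- (cnr <= fold_low | cnr >= fold_high) & (p < alpha)
  storage.mode(flag) <- "double"
  flag
}

#' Pathway activation strength
#'
#' For every pathway and sample, the signed sum over member genes of
#' `arr * btif * log10(cnr)`. Genes absent from the expression matrix are
#' skipped (and counted in a message); a pathway with no member gene present
#' is returned as an `NA` row (missing, not zero) and listed in the
#' `"missing_pathways"` attribute. By default PAS is not divided by pathway
#' size; `scale_by_size = TRUE` divides by the number of member genes
#' present, giving a size-normalized variant.
#'
#' @param cnr CNR matrix from [compute_cnr()].
#' @param btif Flag matrix from [compute_btif()]; same shape as `cnr`.
#' @param db A [pathway_collection()].
#' @param scale_by_size Divide each PAS by the number of member genes
#'   present? Default `FALSE`.
#' @return Numeric matrix (pathways x samples); rownames are pathway display
#'   names, colnames the sample identifiers.
#' @export
compute_pas <- function(cnr, btif, db, scale_by_size = FALSE) {
  stopifnot(is.matrix(cnr), identical(dim(cnr), dim(btif)),
            inherits(db, "pathway_collection"))
  contrib <- btif * log10(cnr)
  out <- matrix(NA_real_, nrow = length(db), ncol = ncol(cnr),
                dimnames = list(pathway_names(db), colnames(cnr)))
  missing_pathways <- character()
  skipped_genes <- character()
  for (i in seq_along(db$pathways)) {
    p <- db$pathways[[i]]
    idx <- match(names(p$roles), rownames(cnr))
    present <- !is.na(idx)
    skipped_genes <- c(skipped_genes, names(p$roles)[!present])
    if (!any(present)) {
      missing_pathways <- c(missing_pathways, pathway_name(p))
      next
    }
    v <- colSums(contrib[idx[present], , drop = FALSE] * p$roles[present])
    if (scale_by_size) v <- v / sum(present)
    out[i, ] <- v
  }
  if (length(skipped_genes)) {
    message("compute_pas: skipped ", length(unique(skipped_genes)),
            " pathway gene(s) absent from the expression matrix")
  }
  attr(out, "missing_pathways") <- missing_pathways
  out
}

#' Full PAS profile from counts
#'
#' Convenience wrapper chaining [normalize_counts()], [compute_cnr()],
#' [compute_btif()] and [compute_pas()].
#'
#' @param counts Raw counts matrix (genes x samples).
#' @param design Sample design tibble.
#' @param db A [pathway_collection()].
#' @param normalization Normalization method (see [normalize_counts()]).
#' @inheritParams compute_btif
#' @inheritParams compute_pas
#' @return List with elements `pas`, `cnr`, `btif`, `normalized`, and
#'   `params` (the parameter values used).
#' @export
pas_profile <- function(counts, design, db, normalization = "cpm",
                        pseudocount = 1, alpha = 0.05, fold_low = 0.66,
                        fold_high = 1.5, sd_floor = 0.1,
                        scale_by_size = FALSE) {
  norm <- normalize_counts(counts, normalization)
  cnr <- compute_cnr(norm, design, pseudocount)
  btif <- compute_btif(norm, cnr, design, alpha, fold_low, fold_high,
                       pseudocount, sd_floor)
  pas <- compute_pas(cnr, btif, db, scale_by_size)
  list(
    pas = pas, cnr = cnr, btif = btif, normalized = norm,
    params = list(
      normalization = normalization, pseudocount = pseudocount,
      alpha = alpha, fold_low = fold_low, fold_high = fold_high,
      sd_floor = sd_floor, scale_by_size = scale_by_size,
      reference_samples = design$sample_id[design$is_reference]
    )
  )
}

#' Write a PAS matrix with a parameter sidecar
#'
#' Writes the pathways x samples matrix as TSV (missing pathways as `NA`) and
#' the run parameters as a YAML sidecar at `<path>.yaml`.
#'
#' @param pas PAS matrix from [compute_pas()].
#' @param path Output TSV path.
#' @param params Named list of parameters to record (e.g. the `params`
#'   element of [pas_profile()]).
#' @return `path`, invisibly.
#' @export
write_pas <- function(pas, path, params = list()) {
  df <- data.frame(pathway = rownames(pas), pas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(params)) yaml::write_yaml(params, paste0(path, ".yaml"))
  invisible(path)
}
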