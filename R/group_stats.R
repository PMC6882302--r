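# Significance machinery: per-sample Gaussian pathway p-values against the
# reference PAS distribution, Wilcoxon rank-sum group tests, and the
# significance/stringency selection of intracellular signaling pathways.

#' Per-sample Gaussian pathway p-values
#'
#' For each pathway, the PAS distribution over the reference samples is
#' summarized by its mean and standard deviation (assumed Gaussian; sd
#' floored at `sd_floor`), and every sample's PAS is converted to the
#' two-sided tail probability of arising from that distribution. Reference
#' columns are scored too (their PAS was computed leave-self-in).
#'
#' @param pas PAS matrix (pathways x samples).
#' @param reference_samples Character vector of reference sample ids (at
#'   least 2) present among the columns of `pas`.
#' @param sd_floor Lower bound on the reference PAS standard deviation.
#' @return Matrix of p-values in `[0, 1]`, same shape as `pas`; `NA` rows
#'   (missing pathways) propagate.
#' @export
gaussian_sample_pvalues <- function(pas, reference_samples, sd_floor = 0.1) {
  stopifnot(is.matrix(pas))
  idx <- match(reference_samples, colnames(pas))
  if (anyNA(idx)) {
    stop("reference sample(s) not found in the PAS matrix: ",
         paste(reference_samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) < 2L) {
    stop("at least 2 reference samples are required", call. = FALSE)
  }
  ref <- pas[, idx, drop = FALSE]
  mu <- rowMeans(ref)
  sd_ref <- pmax(apply(ref, 1L, stats::sd), sd_floor)
  2 * stats::pnorm(-abs((pas - mu) / sd_ref))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For a combined sample size up to `exact_limit` the p-value is computed by
#' exact enumeration of all assignments of the (mid)ranks to the two groups:
#' `p = P(|W - E[W]| >= |w - E[W]|)` over all `choose(n, n_x)` splits, which
#' handles ties exactly as a permutation test on the rank-sum statistic.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction. Fully tied inputs return `p = 1` with a warning.
#'
#' @param x,y Numeric vectors (both non-empty; `NA`s dropped).
#' @param exact_limit Largest combined size for exact enumeration; default 12.
#' @return Two-sided p-value.
#' @export
wilcoxon_group_test <- function(x, y, exact_limit = 12) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("both groups must contain at least one non-missing value",
         call. = FALSE)
  }
  nx <- length(x)
  n <- nx + length(y)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(1)
  }
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_limit) {
    splits <- utils::combn(n, nx)
    wperm <- colSums(matrix(r[splits], nrow = nx))
    mean(abs(wperm - mu) >= abs(w - mu) - 1e-9)
  } else {
    ny <- n - nx
    nties <- table(r)
    sigma <- sqrt((nx * ny / 12) *
                    ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
    d <- w - mu
    z <- (d - sign(d) * 0.5) / sigma
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Pathway significance table for one contrast
#'
#' For every pathway: the group PAS (mean over case samples, signed), the
#' two-sided Wilcoxon rank-sum p-value of case vs. control PAS values, the
#' smallest per-case-sample Gaussian p-value against the control PAS
#' distribution, and the derived selection flags. `passes_alpha` marks
#' `p_wilcoxon < alpha`; `passes_stringency` additionally requires
#' `|group_pas| >= min_pas`.
#'
#' Multiple testing: raw p-values are reported by default;
#' `p_adjust_method = "BH"` (or any [stats::p.adjust()] method) applies the
#' correction to the Wilcoxon p-values before flagging.
#'
#' @param pas PAS matrix (pathways x samples).
#' @param case_samples,control_samples Character vectors of column ids; the
#'   control group doubles as the Gaussian reference.
#' @param alpha Significance level; default 0.05.
#' @param min_pas Stringency threshold on `|group_pas|`; default 0.1.
#' @param sd_floor Passed to [gaussian_sample_pvalues()].
#' @param p_adjust_method Multiple-testing correction; default `"none"`.
#' @return Tibble with columns `pathway`, `group_pas`, `p_wilcoxon`,
#'   `p_sample_min`, `passes_alpha`, `passes_stringency`.
#' @export
pathway_significance <- function(pas, case_samples, control_samples,
                                 alpha = 0.05, min_pas = 0.1, sd_floor = 0.1,
                                 p_adjust_method = "none") {
  stopifnot(is.matrix(pas))
  ci <- match(case_samples, colnames(pas))
  ki <- match(control_samples, colnames(pas))
  if (anyNA(ci) || anyNA(ki)) {
    stop("case/control sample id(s) not found in the PAS matrix",
         call. = FALSE)
  }
  group_pas <- unname(rowMeans(pas[, ci, drop = FALSE]))
  p_w <- rep(NA_real_, nrow(pas))
  complete <- !is.na(group_pas) & !apply(is.na(pas[, ki, drop = FALSE]), 1, any)
  for (i in which(complete)) {
    p_w[i] <- suppressWarnings(wilcoxon_group_test(pas[i, ci], pas[i, ki]))
  }
  gp <- gaussian_sample_pvalues(pas, control_samples, sd_floor)
  p_min <- unname(apply(gp[, ci, drop = FALSE], 1L, function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }))
  p_w <- stats::p.adjust(p_w, method = p_adjust_method)
  tibble::tibble(
    pathway = rownames(pas),
    group_pas = group_pas,
    p_wilcoxon = p_w,
    p_sample_min = p_min,
    passes_alpha = !is.na(p_w) & p_w < alpha,
    passes_stringency = !is.na(p_w) & p_w < alpha &
      abs(group_pas) >= min_pas
  )
}

#' Select significant pathways
#'
#' Returns the pathway keys with group p-value below `alpha` and
#' `|group_pas| >= min_pas`. `min_pas = 0` reproduces the plain significant
#' sets; `min_pas = 0.1` the stringent sets (the threshold is applied to the
#' absolute value, since repressed pathways carry negative PAS). Monotone:
#' raising `min_pas` or lowering `alpha` never adds pathways.
#'
#' @param sig Significance tibble from [pathway_significance()].
#' @param alpha Significance level; default 0.05.
#' @param min_pas Minimum `|group_pas|`; default 0.
#' @return Character vector of pathway keys.
#' @export
select_significant <- function(sig, alpha = 0.05, min_pas = 0) {
  stopifnot(is.data.frame(sig), min_pas >= 0, alpha > 0, alpha <= 1)
  keep <- !is.na(sig$p_wilcoxon) & sig$p_wilcoxon < alpha &
    !is.na(sig$group_pas) & abs(sig$group_pas) >= min_pas
  sig$pathway[keep]
}
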