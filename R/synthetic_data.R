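# Synthetic data with the statistical structure the analysis assumes:
# a pathway knowledge base with mixed activator/repressor roles, a surgical
# procedure x timepoint x replicate design, negative-binomial counts with
# log-normal library sizes, and planted pathway activations that respect the
# ARR sign so that a planted "activated" pathway has positive true PAS.

#' Build a procedure x timepoint x replicate design grid
#'
#' Defaults emulate the mouse liver-regeneration study design: sham,
#' transection, PVL (portal vein ligation), LLLx (left lateral lobectomy),
#' ALPPS and 68% hepatectomy at 0.5, 1, 4, 8 and 12 h post surgery with 3
#' replicates per cell; the sham samples form the reference group.
#'
#' @param procedures Character vector of procedure labels.
#' @param timepoints Numeric vector of hours post surgery.
#' @param replicates Replicates per (procedure, timepoint) cell.
#' @param reference Procedure whose samples carry `is_reference = TRUE`.
#' @return Design tibble (see [read_design()]).
#' @export
design_grid <- function(procedures = c("sham", "transection", "PVL", "LLLx",
                                       "ALPPS", "hx68"),
                        timepoints = c(0.5, 1, 4, 8, 12),
                        replicates = 3,
                        reference = "sham") {
  stopifnot(replicates >= 1, length(procedures) >= 1,
            reference %in% procedures)
  g <- expand.grid(replicate = seq_len(replicates), timepoint_h = timepoints,
                   procedure = procedures, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%gh_r%d", g$procedure, g$timepoint_h,
                        g$replicate),
    procedure = g$procedure,
    timepoint_h = g$timepoint_h,
    replicate = g$replicate,
    is_reference = g$procedure == reference
  )
}

#' Generate a synthetic pathway knowledge base
#'
#' Pathways of random size with mixed ARR roles (a controlled fraction of
#' activators) and controlled pairwise gene overlap: a fraction
#' `overlap_fraction` of each pathway's genes is drawn from a shared pool,
#' the rest are private, so `overlap_fraction = 0` yields pairwise-disjoint
#' pathways. Pathways are organized into main-pathway families with branch
#' labels, mirroring the "main pathway + branch" structure of curated
#' signaling knowledge bases.
#'
#' @param n_pathways Number of pathways; default 378 (the size of a full
#'   signaling knowledge base).
#' @param size_range Integer range of member-gene counts per pathway.
#' @param overlap_fraction Fraction of each pathway drawn from the shared
#'   pool, in `[0, 1)`.
#' @param prop_activators Expected fraction of genes with positive ARR;
#'   default 0.6.
#' @param shared_pool_size Size of the shared gene pool; must be at least
#'   `round(size_range[2] * overlap_fraction)`.
#' @param seed Optional integer seed (byte-identical output for an identical
#'   seed).
#' @return A [pathway_collection()].
#' @export
generate_pathway_db <- function(n_pathways = 378, size_range = c(10, 60),
                                overlap_fraction = 0.2,
                                prop_activators = 0.6,
                                shared_pool_size = 200, seed = NULL) {
  stopifnot(n_pathways >= 1, length(size_range) == 2,
            size_range[1] >= 1, size_range[1] <= size_range[2],
            overlap_fraction >= 0, overlap_fraction < 1,
            prop_activators >= 0, prop_activators <= 1)
  if (round(size_range[2] * overlap_fraction) > shared_pool_size) {
    stop("infeasible overlap: the shared pool is smaller than the largest ",
         "shared draw", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                  replace = TRUE)
  n_shared <- round(sizes * overlap_fraction)
  n_private <- sizes - n_shared
  pool <- if (overlap_fraction > 0) sprintf("SG%04d", seq_len(shared_pool_size))
          else character()
  total_private <- sum(n_private)
  private_ids <- sprintf("PG%06d", seq_len(total_private))
  offsets <- c(0L, cumsum(n_private))
  arr_probs <- c(prop_activators / 2, prop_activators / 2,
                 (1 - prop_activators) / 2, (1 - prop_activators) / 2)
  # main-pathway families of up to 3 branches
  family <- cumsum(c(TRUE, stats::runif(n_pathways - 1) < 1 / 3)) # new family ~1/3
  branch_idx <- stats::ave(seq_len(n_pathways), family,
                           FUN = seq_along)
  pws <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    genes <- c(
      if (n_shared[i] > 0) sample(pool, n_shared[i]) else character(),
      private_ids[(offsets[i] + 1):(offsets[i] + n_private[i])]
    )
    arr <- sample(c(1, 0.5, -0.5, -1), length(genes), replace = TRUE,
                  prob = arr_probs)
    pws[[i]] <- pathway_def(
      main_pathway = sprintf("SP%03d pathway", family[i]),
      branch = if (branch_idx[i] == 1L) "main"
               else sprintf("branch %d", branch_idx[i] - 1L),
      roles = stats::setNames(arr, genes)
    )
  }
  pathway_collection(pws)
}

#' Specify planted pathway perturbations
#'
#' Ground truth for the simulator: in each named (procedure, timepoint)
#' cell, the listed pathways are perturbed in the given direction with the
#' given fold.
#'
#' @param procedure,timepoint_h,pathway,direction,fold Vectors (recycled to
#'   a common length): procedure label, hours, pathway display name,
#'   `"activated"` or `"repressed"`, and a fold strictly above 1.
#' @return Truth tibble.
#' @export
truth_spec <- function(procedure, timepoint_h, pathway,
                       direction = "activated", fold = 3) {
  tr <- tibble::tibble(procedure = procedure, timepoint_h = timepoint_h,
                       pathway = pathway, direction = direction, fold = fold)
  if (!all(tr$direction %in% c("activated", "repressed"))) {
    stop("`direction` must be 'activated' or 'repressed'", call. = FALSE)
  }
  if (!all(tr$fold > 1)) stop("all folds must exceed 1", call. = FALSE)
  tr
}

#' Simulate a negative-binomial count matrix with planted activations
#'
#' Counts are drawn gene-wise from a negative binomial with per-gene
#' baseline means (log-normal by default), a common dispersion, and per
#' sample log-normal library-size factors. For a sample in a perturbed
#' (procedure, timepoint) cell, the mean of each member gene of a planted
#' pathway is multiplied by `fold^(sign(arr))` for `direction = "activated"`
#' and `fold^(-sign(arr))` for `"repressed"`, so activators rise and
#' repressors fall under activation (and conversely). Genes with ARR 0 are
#' untouched; genes in several planted pathways multiply their effects.
#' Reference samples are never perturbed.
#'
#' @param db A [pathway_collection()]; its gene universe defines the
#'   simulated genes.
#' @param design Design tibble, e.g. from [design_grid()].
#' @param truth Optional truth tibble from [truth_spec()]; `NULL` for a
#'   no-signal dataset.
#' @param baseline_means Optional per-gene baseline means; defaults to
#'   log-normal draws (meanlog `log(200)`, sdlog 1).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   default 0.05 (tight, pooled-sample-like); 0 gives Poisson counts.
#' @param libsize_sd Standard deviation of the log-normal library-size
#'   factors; default 0.2.
#' @param n_background_genes Extra genes outside every pathway; default 0.
#' @param seed Optional integer seed.
#' @return List with `counts` (genes x samples integer-valued matrix),
#'   `design`, `truth`, and `baseline_means`.
#' @export
simulate_counts <- function(db, design = design_grid(), truth = NULL,
                            baseline_means = NULL, dispersion = 0.05,
                            libsize_sd = 0.2, n_background_genes = 0,
                            seed = NULL) {
  stopifnot(inherits(db, "pathway_collection"), dispersion >= 0,
            libsize_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  genes <- pathway_universe(db)
  if (n_background_genes > 0) {
    genes <- c(genes, sprintf("BG%06d", seq_len(n_background_genes)))
  }
  n_genes <- length(genes)
  if (is.null(baseline_means)) {
    baseline_means <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
  }
  stopifnot(length(baseline_means) == n_genes, all(baseline_means > 0))
  names(baseline_means) <- genes
  if (!is.null(truth)) {
    known <- truth$pathway %in% pathway_names(db)
    if (!all(known)) {
      stop("truth names pathway(s) absent from the collection: ",
           paste(truth$pathway[!known], collapse = ", "), call. = FALSE)
    }
  }
  # per-cell log multipliers
  cell_key <- function(p, t) paste(p, t, sep = "@")
  log_mult <- list()
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth))) {
      key <- cell_key(truth$procedure[i], truth$timepoint_h[i])
      if (is.null(log_mult[[key]])) log_mult[[key]] <- rep(0, n_genes)
      p <- db$pathways[[truth$pathway[i]]]
      idx <- match(names(p$roles), genes)
      eff <- sign(p$roles) * if (truth$direction[i] == "activated") 1 else -1
      log_mult[[key]][idx] <- log_mult[[key]][idx] + eff * log(truth$fold[i])
    }
  }
  lib <- stats::rlnorm(nrow(design), meanlog = 0, sdlog = libsize_sd)
  counts <- matrix(0, nrow = n_genes, ncol = nrow(design),
                   dimnames = list(genes, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- baseline_means * lib[j]
    key <- cell_key(design$procedure[j], design$timepoint_h[j])
    if (!design$is_reference[j] && !is.null(log_mult[[key]])) {
      mu <- mu * exp(log_mult[[key]])
    }
    counts[, j] <- if (dispersion > 0) {
      stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    } else {
      stats::rpois(n_genes, lambda = mu)
    }
  }
  list(counts = counts, design = design, truth = truth,
       baseline_means = baseline_means)
}

#' Published reference PAS tables
#'
#' The two printed PAS tables of the mouse ALPPS liver-regeneration study,
#' transcribed to all printed digits and shipped as plain-text fixtures:
#' the 46-row comparison of standard (68%) hepatectomy and ALPPS 4 h after
#' surgery, and the procedure-exclusive activated/repressed ISPs
#' (transection, ALPPS, PVL) 4 h after surgery.
#'
#' @return List with `hx68_vs_alpps_4h` (tibble: `pathway`, `pas_hx68`,
#'   `pas_alpps`) and `exclusive_isps_4h` (tibble: `procedure`, `pathway`,
#'   `pas`).
#' @export
reference_pas_tables <- function() {
  f1 <- system.file("extdata", "pas_hx68_vs_alpps_4h.tsv", package = "pasway",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "exclusive_isps_4h.tsv", package = "pasway",
                    mustWork = TRUE)
  t1 <- tibble::as_tibble(utils::read.delim(f1, stringsAsFactors = FALSE))
  t2 <- tibble::as_tibble(utils::read.delim(f2, stringsAsFactors = FALSE))
  list(hx68_vs_alpps_4h = t1, exclusive_isps_4h = t2)
}
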