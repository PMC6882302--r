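# Independent oracles and small generators used across the suite.

# Term-by-term PAS summation, written as the defining triple loop.
brute_pas <- function(cnr, btif, db) {
  out <- matrix(NA_real_, length(db), ncol(cnr),
                dimnames = list(pathway_names(db), colnames(cnr)))
  for (i in seq_along(db$pathways)) {
    p <- db$pathways[[i]]
    any_present <- FALSE
    for (s in seq_len(ncol(cnr))) {
      acc <- 0
      for (g in names(p$roles)) {
        if (g %in% rownames(cnr)) {
          any_present <- TRUE
          acc <- acc + p$roles[[g]] * btif[g, s] * log10(cnr[g, s])
        }
      }
      out[i, s] <- acc
    }
    if (!any_present) out[i, ] <- NA_real_
  }
  out
}

# Random valid pathway collection for round-trip properties.
rand_collection <- function(n_pathways = 5, gene_pool = sprintf("G%03d", 1:60)) {
  pws <- lapply(seq_len(n_pathways), function(i) {
    size <- sample(2:10, 1)
    genes <- sample(gene_pool, size)
    arr <- sample(ARR_LEVELS, size, replace = TRUE)
    pathway_def(sprintf("path%02d", i),
                sample(c("main", "branch a", "branch b"), 1),
                stats::setNames(arr, genes))
  })
  pathway_collection(pws)
}

# Random toy CNR/BTIF/collection instance for the PAS oracle.
rand_pas_instance <- function(n_genes = 10, n_samples = 3, n_pathways = 3) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%d", seq_len(n_samples))
  cnr <- matrix(exp(stats::rnorm(n_genes * n_samples)), n_genes, n_samples,
                dimnames = list(genes, samples))
  btif <- matrix(stats::rbinom(n_genes * n_samples, 1, 0.5), n_genes,
                 n_samples, dimnames = list(genes, samples))
  pws <- lapply(seq_len(n_pathways), function(i) {
    size <- sample(2:n_genes, 1)
    pathway_def(sprintf("p%d", i), "main",
                stats::setNames(sample(ARR_LEVELS, size, replace = TRUE),
                                sample(genes, size)))
  })
  list(cnr = cnr, btif = btif, db = pathway_collection(pws))
}

# UPGMA merge heights computed from the original distance matrix: the
# distance between two clusters is the mean of all original cross-pair
# distances. Returns the sorted merge heights.
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Running-sum enrichment statistic re-derived with an explicit walk.
brute_running_sum <- function(x, genes) {
  ord <- order(-x, names(x), method = "radix")
  ids <- names(x)[ord]
  k <- sum(ids %in% genes)
  if (k == 0) return(NA_real_)
  n_out <- length(ids) - k
  best <- 0
  run <- 0
  for (g in ids) {
    run <- run + (if (g %in% genes) 1 / k else -1 / n_out)
    if (abs(run) > abs(best) + 1e-15) best <- run
  }
  best
}

# Rank-statistic AUROC of a score for recovering a logical truth vector.
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small design with an explicit reference group for unit tests.
toy_design <- function(samples, reference) {
  tibble::tibble(
    sample_id = samples,
    procedure = ifelse(samples %in% reference, "sham", "case"),
    timepoint_h = 4,
    replicate = seq_along(samples),
    is_reference = samples %in% reference
  )
}
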