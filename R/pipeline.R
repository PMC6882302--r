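# End-to-end orchestration: counts + design + pathway DB (+ optional
# signatures and miRNA tables) -> PAS matrix, per-contrast significance
# tables, Venn report, time profiles, PCA, cluster order, miRNA patterns,
# enrichment scores, and a run manifest.

default_params <- function() {
  list(normalization = "cpm", pseudocount = 1, alpha = 0.05,
       fold_low = 0.66, fold_high = 1.5, sd_floor = 0.1, min_pas = 0.1,
       min_reads = 10, cluster_metric = "pearson",
       venn_procedures = NULL, venn_timepoint = 4)
}

#' Read a pipeline run configuration
#'
#' YAML with input paths (`counts`, `design`, `pathway_db`, and optionally
#' `signatures`, `mirna_counts`, `mirna_targets`), a `params` block
#' overriding the analysis defaults, and a `seed`.
#'
#' @param path Path to the YAML config.
#' @return Config list as accepted by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

stage_error <- function(stage, parent) {
  stop(structure(
    class = c("pasway_stage_error", "error", "condition"),
    list(message = sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(parent)),
         call = NULL, stage = stage)
  ))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "pasway_stage_error")) stop(e)
    stage_error(stage, e)
  })
}

#' Run the full PAS analysis pipeline
#'
#' Validates the configuration, computes the PAS profile, the per-contrast
#' significance tables (every non-reference (procedure, timepoint) cell
#' against the reference group), the Venn partition of significant-pathway
#' sets across procedures, PAS time profiles, sample PCA coordinates, the
#' hierarchical clustering leaf order, miRNA presence patterns (when miRNA
#' inputs are configured), enrichment scores (when signatures are
#' configured), and a manifest recording parameters, input checksums and the
#' artifact list. Identical config and seed produce identical numeric
#' outputs. A stage failure aborts with a stage-named condition after
#' writing a manifest marked incomplete.
#'
#' @param config Config list (see [read_run_config()]) or path to a YAML
#'   config.
#' @param out_dir Output directory (created if absent).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  params <- utils::modifyList(default_params(), config$params %||% list())
  required <- c("counts", "design", "pathway_db")
  for (key in required) {
    if (is.null(config[[key]]) || !file.exists(config[[key]])) {
      stop(structure(
        class = c("pasway_input_error", "error", "condition"),
        list(message = paste0("missing or nonexistent input: ", key),
             call = NULL)
      ))
    }
  }
  optional <- c("signatures", "mirna_counts", "mirna_targets")
  for (key in optional) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop(structure(
        class = c("pasway_input_error", "error", "condition"),
        list(message = paste0("configured input does not exist: ", key),
             call = NULL)
      ))
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- Filter(Negate(is.null), config[c(required, optional)])
  manifest <- list(
    package = as.character(utils::packageVersion("pasway")),
    parameters = params,
    seed = config$seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    artifacts = character(),
    status = "incomplete"
  )
  finish <- function() {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  on.exit(finish())

  art <- function(name) {
    manifest$artifacts <<- c(manifest$artifacts, name)
    file.path(out_dir, name)
  }

  counts <- run_stage("read_counts", read_counts(config$counts))
  design <- run_stage("read_design", read_design(config$design))
  run_stage("read_design", validate_design(design, counts))
  db <- run_stage("parse_pathway_db", parse_pathway_db(config$pathway_db))

  prof <- run_stage("pas", pas_profile(
    counts, design, db,
    normalization = params$normalization, pseudocount = params$pseudocount,
    alpha = params$alpha, fold_low = params$fold_low,
    fold_high = params$fold_high, sd_floor = params$sd_floor
  ))
  write_pas(prof$pas, art("pas_matrix.tsv"), prof$params)

  ref_ids <- design$sample_id[design$is_reference]
  cells <- dplyr::distinct(design[!design$is_reference, ],
                           .data$procedure, .data$timepoint_h)
  sig_all <- run_stage("stats", {
    dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
      ids <- design$sample_id[design$procedure == cells$procedure[i] &
                                design$timepoint_h == cells$timepoint_h[i]]
      s <- pathway_significance(prof$pas, ids, ref_ids,
                                alpha = params$alpha,
                                min_pas = params$min_pas,
                                sd_floor = params$sd_floor)
      tibble::add_column(s, procedure = cells$procedure[i],
                         timepoint_h = cells$timepoint_h[i], .before = 1L)
    }))
  })
  utils::write.table(sig_all, art("significance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  run_stage("compare", {
    venn_procs <- params$venn_procedures %||%
      utils::head(unique(cells$procedure), 4L)
    venn_procs <- intersect(venn_procs, cells$procedure)
    if (length(venn_procs) >= 2L) {
      sets <- lapply(venn_procs, function(p) {
        s <- sig_all[sig_all$procedure == p &
                       sig_all$timepoint_h == params$venn_timepoint, ]
        select_significant(s, alpha = params$alpha)
      })
      names(sets) <- venn_procs
      vp <- venn_partition(sets)
      jsonlite::write_json(
        list(sets = vp$sets, regions = vp$regions,
             counts = as.list(vp$counts)),
        art("venn.json"), auto_unbox = TRUE, pretty = TRUE
      )
    }
    tp <- time_profiles(prof$pas, design)
    utils::write.table(tp, art("time_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    complete <- prof$pas[rowSums(is.na(prof$pas)) == 0L, , drop = FALSE]
    pca <- pca_transform(complete, n_components = min(3L, min(dim(complete))))
    pca_path <- art("pca_coordinates.csv")
    utils::write.table(as.data.frame(pca$coordinates), pca_path, sep = ",",
                       quote = FALSE, row.names = FALSE)
    cat("variance_explained,",
        paste(format(pca$variance_explained, digits = 15), collapse = ","),
        "\n", sep = "", file = pca_path, append = TRUE)
    hc <- hierarchical_cluster(complete, metric = params$cluster_metric)
    writeLines(hc$labels[hc$order], art("cluster_order.txt"))
  })

  if (!is.null(config$mirna_counts)) {
    run_stage("mirna", {
      mir <- read_counts(config$mirna_counts)
      pat <- presence_patterns(mir, design, threshold = params$min_reads)
      write_presence_patterns(pat, art("mirna_patterns.tsv"))
      if (!is.null(config$mirna_targets)) {
        targ <- read_mirna_targets(config$mirna_targets)
        true_targ <- filter_true_targets(targ, counts,
                                         min_reads = params$min_reads)
        utils::write.table(true_targ, art("mirna_true_targets.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  if (!is.null(config$signatures)) {
    run_stage("enrich", {
      sigs <- read_gmt(config$signatures)
      es <- enrichment_matrix(prof$normalized, sigs)
      df <- data.frame(signature = rownames(es), es, check.names = FALSE)
      utils::write.table(df, art("enrichment_scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  manifest$artifacts <- c(manifest$artifacts, "manifest.yaml")
  manifest$status <- "complete"
  invisible(manifest)
}
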