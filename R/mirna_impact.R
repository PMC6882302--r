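# miRNA target-table handling, the read-count >= 10 "true target" filter,
# and procedure x timepoint presence/exclusivity pattern detection.

#' Read a miRNA target table
#'
#' TSV with columns `mirna_id`, `target_gene`, `evidence` (free-text evidence
#' label, e.g. the experimental validation category of a miRTarBase-style
#' resource). Duplicate (mirna, target) pairs are an error.
#'
#' @param path Path to the target-table TSV.
#' @return Tibble with the three columns.
#' @export
read_mirna_targets <- function(path) {
  if (!file.exists(path)) stop("target table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("mirna_id", "target_gene", "evidence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("target table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[c("mirna_id", "target_gene")])) {
    stop("duplicate (mirna_id, target_gene) pair(s) in ", path, call. = FALSE)
  }
  tibble::as_tibble(df[required])
}

#' Filter a target table to expressed ("true") targets
#'
#' Keeps records whose target gene reaches at least `min_reads` raw reads in
#' at least one sample; targets absent from the count matrix are dropped.
#' Idempotent, and monotone in `min_reads` (a larger threshold keeps a
#' subset).
#'
#' @param targets Target tibble (see [read_mirna_targets()]).
#' @param expr Raw counts matrix (genes x samples).
#' @param min_reads Detection threshold; default 10 reads.
#' @return The filtered target tibble.
#' @export
filter_true_targets <- function(targets, expr, min_reads = 10) {
  stopifnot(is.data.frame(targets), is.matrix(expr), min_reads >= 0)
  max_count <- apply(expr, 1L, max)
  expressed <- rownames(expr)[max_count >= min_reads]
  targets[targets$target_gene %in% expressed, , drop = FALSE]
}

#' miRNA presence patterns over the (procedure, timepoint) grid
#'
#' A miRNA is called present in a design cell when any replicate of that
#' (procedure, timepoint) reaches the read-count threshold. Cells with no
#' samples are marked absent with a warning. The grid covers every
#' (procedure, timepoint) combination appearing in the design exactly once.
#'
#' @param mirna_expr Raw counts matrix indexed by miRNA (precursor)
#'   identifiers.
#' @param design Sample design tibble (see [read_design()]).
#' @param threshold Detection threshold in reads; default 10.
#' @return Tibble with columns `mirna`, `procedure`, `timepoint_h`,
#'   `present`; the detection threshold is stored in the `"threshold"`
#'   attribute.
#' @export
presence_patterns <- function(mirna_expr, design, threshold = 10) {
  stopifnot(is.matrix(mirna_expr), threshold >= 0)
  cells <- dplyr::arrange(
    dplyr::distinct(design, .data$procedure, .data$timepoint_h),
    .data$procedure, .data$timepoint_h
  )
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ids <- design$sample_id[design$procedure == cells$procedure[i] &
                              design$timepoint_h == cells$timepoint_h[i]]
    ids <- intersect(ids, colnames(mirna_expr))
    if (!length(ids)) {
      warning("design cell (", cells$procedure[i], ", ",
              cells$timepoint_h[i], " h) has no samples; marked absent",
              call. = FALSE)
      present <- rep(FALSE, nrow(mirna_expr))
    } else {
      present <- apply(mirna_expr[, ids, drop = FALSE], 1L, max) >= threshold
    }
    tibble::tibble(
      mirna = rownames(mirna_expr),
      procedure = cells$procedure[i],
      timepoint_h = cells$timepoint_h[i],
      present = unname(present)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "threshold") <- threshold
  res
}

#' Procedure-exclusive miRNAs and earlier-appearance report
#'
#' A miRNA is exclusive to `procedure` when it is present in at least one of
#' that procedure's timepoints and absent at every timepoint of every other
#' procedure. For miRNAs shared between procedures, the report gives the
#' earliest timepoint of presence per procedure, so that earlier appearance
#' under one procedure (e.g. 4 h after ALPPS vs. 8 h after PVL) can be read
#' off directly.
#'
#' @param patterns Presence tibble from [presence_patterns()]; must cover at
#'   least 2 procedures.
#' @param procedure Procedure label of interest.
#' @return List with `exclusive` (tibble: `mirna`, `first_timepoint_h`) and
#'   `first_appearance` (tibble: `mirna`, `procedure`, `first_timepoint_h`
#'   for miRNAs present in `procedure` and in at least one other procedure).
#' @export
exclusive_mirnas <- function(patterns, procedure) {
  stopifnot(is.data.frame(patterns))
  procs <- unique(patterns$procedure)
  if (length(procs) < 2L) {
    stop("patterns must cover at least 2 procedures", call. = FALSE)
  }
  if (!procedure %in% procs) {
    stop("procedure '", procedure, "' not present in the patterns",
         call. = FALSE)
  }
  pres <- patterns[patterns$present, , drop = FALSE]
  firsts <- dplyr::summarise(
    dplyr::group_by(pres, .data$mirna, .data$procedure),
    first_timepoint_h = min(.data$timepoint_h), .groups = "drop"
  )
  in_target <- unique(firsts$mirna[firsts$procedure == procedure])
  in_other <- unique(firsts$mirna[firsts$procedure != procedure])
  exclusive <- firsts[firsts$procedure == procedure &
                        firsts$mirna %in% setdiff(in_target, in_other), ,
                      drop = FALSE]
  shared <- intersect(in_target, in_other)
  list(
    exclusive = dplyr::arrange(exclusive[c("mirna", "first_timepoint_h")],
                               .data$mirna),
    first_appearance = dplyr::arrange(
      firsts[firsts$mirna %in% shared, , drop = FALSE],
      .data$mirna, .data$procedure
    )
  )
}

#' Write a presence-pattern grid as a wide TSV
#'
#' One row per miRNA, one `procedure@timepoint` column per design cell,
#' cells 0/1.
#'
#' @param patterns Presence tibble from [presence_patterns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_patterns <- function(patterns, path) {
  key <- paste0(patterns$procedure, "@", patterns$timepoint_h, "h")
  wide <- tapply(as.integer(patterns$present),
                 list(patterns$mirna, factor(key, levels = unique(key))),
                 identity)
  df <- data.frame(mirna = rownames(wide), wide, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
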