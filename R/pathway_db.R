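# Pathway knowledge base: named pathways (main pathway + branch) whose member
# genes carry a discrete activator/repressor role (ARR) weight.

#' Permitted activator/repressor role (ARR) weights
#'
#' The ARR weight encodes the functional role of a gene product within a
#' pathway on a five-level discrete scale: -1 (repressor), -0.5 (weak
#' repressor), 0 (neutral/scaffold), 0.5 (weak activator), 1 (activator).
#'
#' @export
ARR_LEVELS <- c(-1, -0.5, 0, 0.5, 1)

#' Construct a pathway definition
#'
#' A pathway is identified by its parent (main) pathway name and a branch
#' label; `branch = "main"` denotes the main pathway itself. Member genes are
#' given as a named numeric vector mapping gene identifiers to ARR weights.
#'
#' @param main_pathway Parent pathway name (non-empty string).
#' @param branch Branch label; `"main"` for the main pathway entry.
#' @param roles Named numeric vector of ARR weights, one per member gene.
#'   Every value must be one of [ARR_LEVELS]; gene names must be non-empty
#'   and unique within the pathway.
#' @return An object of class `pathway_def`.
#' @examples
#' pathway_def("ILK pathway", "wound healing", c(GENE1 = 1, GENE2 = -1))
#' @export
pathway_def <- function(main_pathway, branch = "main", roles = numeric()) {
  if (!is.character(main_pathway) || length(main_pathway) != 1L ||
      !nzchar(main_pathway)) {
    stop("`main_pathway` must be a single non-empty string", call. = FALSE)
  }
  if (!is.character(branch) || length(branch) != 1L || !nzchar(branch)) {
    stop("`branch` must be a single non-empty string", call. = FALSE)
  }
  if (length(roles) == 0L) {
    stop("pathway '", main_pathway, "' has no member genes", call. = FALSE)
  }
  genes <- names(roles)
  if (is.null(genes) || any(!nzchar(genes))) {
    stop("all ARR weights must be named by a non-empty gene identifier",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene(s) within pathway '", main_pathway, " / ", branch,
         "': ", paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(roles %in% ARR_LEVELS)) {
    bad <- roles[!(roles %in% ARR_LEVELS)]
    stop("ARR weight(s) outside the permitted set {-1, -0.5, 0, 0.5, 1}: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(
    list(main_pathway = main_pathway, branch = branch,
         roles = stats::setNames(as.numeric(roles), genes)),
    class = "pathway_def"
  )
}

#' @export
print.pathway_def <- function(x, ...) {
  cat("<pathway_def> ", pathway_name(x), ": ", length(x$roles), " genes (",
      sum(x$roles > 0), " activators, ", sum(x$roles < 0), " repressors)\n",
      sep = "")
  invisible(x)
}

#' Display name of a pathway
#'
#' `"<main>"` when the branch is `"main"`, otherwise `"<main> (<branch>)"`,
#' mirroring the conventional "ILK pathway (wound healing)" presentation.
#'
#' @param p A [pathway_def()].
#' @return A single string.
#' @export
pathway_name <- function(p) {
  stopifnot(inherits(p, "pathway_def"))
  if (identical(p$branch, "main")) p$main_pathway
  else sprintf("%s (%s)", p$main_pathway, p$branch)
}

#' Member genes of a pathway
#'
#' @param p A [pathway_def()].
#' @return Character vector of gene identifiers.
#' @export
pathway_genes <- function(p) {
  stopifnot(inherits(p, "pathway_def"))
  names(p$roles)
}

#' Construct a pathway collection
#'
#' An ordered set of [pathway_def()]s with unique `(main_pathway, branch)`
#' keys. The gene universe of a collection is the union of all member genes.
#'
#' @param pathways List of [pathway_def()] objects.
#' @return An object of class `pathway_collection`; pathway order is
#'   preserved and the list is named by [pathway_name()].
#' @export
pathway_collection <- function(pathways) {
  if (!is.list(pathways) ||
      !all(vapply(pathways, inherits, logical(1), "pathway_def"))) {
    stop("`pathways` must be a list of pathway_def objects", call. = FALSE)
  }
  keys <- vapply(pathways, function(p) paste0(p$main_pathway, "\r", p$branch),
                 character(1))
  if (anyDuplicated(keys)) {
    dup <- pathways[[which(duplicated(keys))[1]]]
    stop("duplicate pathway key: '", dup$main_pathway, "' / '", dup$branch,
         "'", call. = FALSE)
  }
  names(pathways) <- vapply(pathways, pathway_name, character(1))
  structure(list(pathways = pathways), class = "pathway_collection")
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' @export
print.pathway_collection <- function(x, ...) {
  cat("<pathway_collection> ", length(x), " pathways, ",
      length(pathway_universe(x)), " genes in universe\n", sep = "")
  invisible(x)
}

#' Pathway display names of a collection
#'
#' @param coll A [pathway_collection()].
#' @return Character vector in collection order.
#' @export
pathway_names <- function(coll) {
  stopifnot(inherits(coll, "pathway_collection"))
  names(coll$pathways)
}

#' Gene universe of a collection
#'
#' @param coll A [pathway_collection()].
#' @return Sorted character vector: the union of all member gene identifiers.
#' @export
pathway_universe <- function(coll) {
  stopifnot(inherits(coll, "pathway_collection"))
  sort(unique(unlist(lapply(coll$pathways, pathway_genes), use.names = FALSE)))
}

format_arr <- function(a) {
  vapply(a, function(x) formatC(x, format = "fg"), character(1))
}

#' Read a pathway knowledge base file
#'
#' The on-disk format is a GMT-inspired UTF-8 TSV, one pathway per line:
#' `<main_pathway>\t<branch>\t<gene>:<arr>[\t<gene>:<arr>]...`, with ARR
#' weights written as `-1`, `-0.5`, `0`, `0.5` or `1`. Lines starting with
#' `#` are comments. Standard GMT has no role weights, hence the
#' `gene:arr` token dialect.
#'
#' @param path Path to the pathway DB file.
#' @return A [pathway_collection()]; pathway order as in the file.
#' @seealso [write_pathway_db()]
#' @export
parse_pathway_db <- function(path) {
  if (!file.exists(path)) stop("pathway DB file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  pws <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    lineno <- keep[k]
    fields <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("line ", lineno, ": expected at least 3 tab-separated fields ",
           "(main_pathway, branch, gene:arr...)", call. = FALSE)
    }
    tokens <- fields[-(1:2)]
    parts <- strsplit(tokens, ":", fixed = TRUE)
    ok <- lengths(parts) == 2L
    if (!all(ok)) {
      stop("line ", lineno, ": malformed gene:arr token '",
           tokens[!ok][1], "'", call. = FALSE)
    }
    genes <- vapply(parts, `[`, character(1), 1L)
    arr <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
    if (anyNA(arr) || !all(arr %in% ARR_LEVELS)) {
      bad <- tokens[is.na(arr) | !(arr %in% ARR_LEVELS)][1]
      stop("line ", lineno, ": ARR value in token '", bad,
           "' is not one of {-1, -0.5, 0, 0.5, 1}", call. = FALSE)
    }
    pws[[k]] <- tryCatch(
      pathway_def(fields[1], fields[2], stats::setNames(arr, genes)),
      error = function(e) {
        stop("line ", lineno, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  pathway_collection(pws)
}

#' Write a pathway collection to the knowledge base format
#'
#' Inverse of [parse_pathway_db()]: `parse_pathway_db(write_pathway_db(x))`
#' reproduces `x` exactly.
#'
#' @param coll A [pathway_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_db <- function(coll, path) {
  stopifnot(inherits(coll, "pathway_collection"))
  lines <- vapply(coll$pathways, function(p) {
    paste(c(p$main_pathway, p$branch,
            paste0(names(p$roles), ":", format_arr(p$roles))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Jaccard similarity between the gene sets of two pathways
#'
#' Size of the intersection of the member gene sets divided by the size of
#' their union. Symmetric in its arguments; 1 for identical gene content and
#' 0 for disjoint pathways.
#'
#' @param a,b [pathway_def()] objects.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  ga <- pathway_genes(a)
  gb <- pathway_genes(b)
  if (length(ga) == 0L || length(gb) == 0L) {
    stop("Jaccard similarity is undefined for an empty pathway", call. = FALSE)
  }
  length(intersect(ga, gb)) / length(union(ga, gb))
}
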