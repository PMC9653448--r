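#' Restrict expression matrices to one-to-one orthologs
#'
#' Cross-species expression comparisons are only meaningful on genes with an
#' unambiguous counterpart in each species.  Given one matrix per species and
#' pairwise orthology tables against a reference species, this keeps only
#' gene pairs in which each identifier maps to exactly one partner
#' (one-to-one orthologs), renames every matrix to the reference species'
#' gene identifiers, and aligns all matrices to a common gene ordering.
#'
#' @param matrices named list (one entry per species) of
#'   SummarizedExperiments or genes x cells matrices.
#' @param maps list of orthology tables.  Each table is a two-column
#'   data.frame whose column names are the two species it relates (as
#'   produced by [readOrthology()]); every non-reference species must appear
#'   in exactly one table together with the reference.
#' @param reference species whose gene identifiers become the shared names
#'   (default: first species in \code{matrices}).
#' @return list with \code{matrices} (inputs subset and renamed to the
#'   shared gene space, reference gene order) and \code{report}, a
#'   data.frame of dropped map rows / genes with columns \code{species},
#'   \code{gene_id}, \code{reason} (\code{many_to_many}, \code{unmapped},
#'   \code{absent_elsewhere}).
#' @export
restrictToOrthologs <- function(matrices, maps,
                                reference = names(matrices)[1]) {
  if (length(matrices) < 2L || is.null(names(matrices))) {
    stop("need a named list of matrices for at least two species")
  }
  if (!reference %in% names(matrices)) {
    stop("reference species '", reference, "' not among the matrices")
  }
  if (is.data.frame(maps)) maps <- list(maps)
  rows_of <- function(m) rownames(.getAssay(m, "counts", "restrictToOrthologs"))
  others <- setdiff(names(matrices), reference)
  report <- list()
  # per non-reference species: reference gene -> that species' gene
  pairings <- list()
  for (sp in others) {
    hit <- Filter(function(m) all(c(reference, sp) %in% colnames(m)[1:2]) &&
                    ncol(m) >= 2, maps)
    if (length(hit) != 1L) {
      stop("expected exactly one orthology table relating '", reference,
           "' and '", sp, "'; found ", length(hit))
    }
    map <- hit[[1]][, c(reference, sp)]
    map[] <- lapply(map, as.character)
    many <- duplicated(map[[reference]]) | duplicated(map[[reference]],
                                                      fromLast = TRUE) |
            duplicated(map[[sp]]) | duplicated(map[[sp]], fromLast = TRUE)
    if (any(many)) {
      report[[length(report) + 1L]] <- data.frame(
        species = sp, gene_id = map[[sp]][many], reason = "many_to_many")
    }
    map <- map[!many, , drop = FALSE]
    present <- map[[reference]] %in% rows_of(matrices[[reference]]) &
               map[[sp]] %in% rows_of(matrices[[sp]])
    if (any(!present)) {
      report[[length(report) + 1L]] <- data.frame(
        species = sp, gene_id = map[[sp]][!present], reason = "unmapped")
    }
    map <- map[present, , drop = FALSE]
    pairings[[sp]] <- stats::setNames(map[[sp]], map[[reference]])
  }
  # genes of the reference that survive in every pairwise map
  shared <- rows_of(matrices[[reference]])
  unmapped_ref <- setdiff(shared, Reduce(union, lapply(pairings, names)))
  if (length(unmapped_ref)) {
    report[[length(report) + 1L]] <- data.frame(
      species = reference, gene_id = unmapped_ref, reason = "unmapped")
  }
  for (sp in others) shared <- intersect(shared, names(pairings[[sp]]))
  if (!length(shared)) {
    stop("no genes remain after one-to-one ortholog restriction")
  }
  dropped_elsewhere <- setdiff(Reduce(union, lapply(pairings, names)), shared)
  if (length(dropped_elsewhere)) {
    report[[length(report) + 1L]] <- data.frame(
      species = reference, gene_id = dropped_elsewhere,
      reason = "absent_elsewhere")
  }
  out <- matrices
  out[[reference]] <- matrices[[reference]][shared, , drop = FALSE]
  for (sp in others) {
    m <- matrices[[sp]][pairings[[sp]][shared], , drop = FALSE]
    rownames(m) <- shared
    out[[sp]] <- m
  }
  report <- if (length(report)) {
    unique(do.call(rbind, report))
  } else {
    data.frame(species = character(), gene_id = character(),
               reason = character())
  }
  rownames(report) <- NULL
  list(matrices = out, report = report)
}
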