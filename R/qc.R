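#' Filter cells on detected features and mitochondrial content
#'
#' Removes cells with fewer than \code{min_genes} detected genes (count > 0)
#' or with a mitochondrial count fraction above \code{max_mito_frac}.  These
#' are the standard droplet-QC gates for cortical single-nucleus/single-cell
#' data: empty or lysed droplets carry few detected features, and stressed
#' or broken cells carry high mitochondrial content.
#'
#' @param x a SingleCellExperiment/SummarizedExperiment with a \code{counts}
#'   assay, or a genes x cells count matrix (dense or sparse).
#' @param mito_gene_ids character vector of mitochondrial gene identifiers;
#'   identifiers absent from the matrix are ignored with a warning.
#' @param min_genes minimum number of detected genes to keep a cell
#'   (default 200).
#' @param max_mito_frac maximum mitochondrial count fraction to keep a cell
#'   (default 0.30).
#' @param allowEmpty keep going (with a warning) if no cell survives.
#' @return a list with \code{filtered} (same type as \code{x}, failing cells
#'   removed) and \code{report}, a data.frame of removed cells with columns
#'   \code{cell_id}, \code{reason} (\code{low_genes}, \code{high_mito} or
#'   \code{low_genes;high_mito}), \code{n_genes} and \code{mito_frac}.
#' @examples
#' fx <- simulateQCFixture(10, 3, 2, seed = 1)
#' res <- qcFilterCells(fx$counts, mito_gene_ids = fx$mito_genes)
#' nrow(res$report)  # 5
#' @export
qcFilterCells <- function(x, mito_gene_ids = character(), min_genes = 200,
                          max_mito_frac = 0.30, allowEmpty = FALSE) {
  .assertCount(min_genes, "min_genes", min = 0L)
  .assertFlag(allowEmpty, "allowEmpty")
  if (!is.numeric(max_mito_frac) || max_mito_frac < 0 || max_mito_frac > 1) {
    stop("'max_mito_frac' must be in [0, 1]")
  }
  counts <- .getAssay(x, "counts", "qcFilterCells")
  if (is.null(colnames(counts))) {
    stop("count matrix must have cell identifiers as column names")
  }
  missing_mito <- setdiff(mito_gene_ids, rownames(counts))
  if (length(missing_mito)) {
    warning(length(missing_mito),
            " mitochondrial gene id(s) not present in the matrix")
  }
  mito <- intersect(mito_gene_ids, rownames(counts))

  n_genes <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mito_counts <- if (length(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mito_frac <- ifelse(totals > 0, mito_counts / totals, 0)

  low <- n_genes < min_genes
  high <- mito_frac > max_mito_frac
  drop <- low | high
  reason <- character(sum(drop))
  reason[] <- paste0(ifelse(low[drop], "low_genes;", ""),
                     ifelse(high[drop], "high_mito;", ""))
  reason <- sub(";$", "", reason)
  report <- data.frame(cell_id = colnames(counts)[drop], reason = reason,
                       n_genes = as.integer(n_genes[drop]),
                       mito_frac = as.numeric(mito_frac[drop]),
                       stringsAsFactors = FALSE, row.names = NULL)
  if (all(drop) && !allowEmpty) {
    stop("all cells removed by QC; set allowEmpty = TRUE to permit this")
  }
  filtered <- if (is(x, "SummarizedExperiment")) {
    x[, !drop]
  } else {
    x[, !drop, drop = FALSE]
  }
  list(filtered = filtered, report = report)
}

#' Filter genes detected in too few cells
#'
#' Removes genes detected (count > 0) in fewer than \code{min_cells} cells.
#'
#' @inheritParams qcFilterCells
#' @param min_cells minimum number of cells in which a gene must be detected
#'   (default 10).
#' @return a list with \code{filtered} and \code{report} (data.frame with
#'   \code{gene_id}, \code{n_cells_detected}).
#' @export
qcFilterGenes <- function(x, min_cells = 10, allowEmpty = FALSE) {
  .assertCount(min_cells, "min_cells", min = 0L)
  .assertFlag(allowEmpty, "allowEmpty")
  counts <- .getAssay(x, "counts", "qcFilterGenes")
  if (is.null(rownames(counts))) {
    stop("count matrix must have gene identifiers as row names")
  }
  n_cells <- Matrix::rowSums(counts > 0)
  drop <- n_cells < min_cells
  report <- data.frame(gene_id = rownames(counts)[drop],
                       n_cells_detected = as.integer(n_cells[drop]),
                       stringsAsFactors = FALSE, row.names = NULL)
  if (all(drop) && !allowEmpty) {
    stop("all genes removed by QC; set allowEmpty = TRUE to permit this")
  }
  filtered <- if (is(x, "SummarizedExperiment")) {
    x[!drop, ]
  } else {
    x[!drop, , drop = FALSE]
  }
  list(filtered = filtered, report = report)
}
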