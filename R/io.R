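#' Read / write 10x-style Matrix Market count directories
#'
#' A count directory holds \code{matrix.mtx} (genes x cells, Matrix Market),
#' \code{features.tsv} (gene id, gene name) and \code{barcodes.tsv} (cell
#' ids), optionally gzipped.  An \code{annotation.csv} with per-cell labels
#' (cell_id, species, sample, class, subclass, native_cluster) is read into
#' \code{colData} when present.
#'
#' @param dir directory to read from / write into.
#' @return \code{readCountsMTX}: a [SingleCellExperiment::SingleCellExperiment]
#'   with a \code{counts} assay (and colData when an annotation file is
#'   present).
#' @export
readCountsMTX <- function(dir) {
  pick <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing ", base, "(.gz) in ", dir)
  }
  m <- as(Matrix::readMM(pick("matrix.mtx")), "CsparseMatrix")
  feats <- read.delim(pick("features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- read.delim(pick("barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  rownames(m) <- feats[[1]]
  colnames(m) <- barcodes
  ann_file <- file.path(dir, "annotation.csv")
  cd <- if (file.exists(ann_file)) {
    ann <- read.csv(ann_file, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(ann)) stop("annotation.csv needs a cell_id column")
    rownames(ann) <- ann$cell_id
    S4Vectors::DataFrame(ann[barcodes, setdiff(names(ann), "cell_id"),
                             drop = FALSE])
  } else {
    S4Vectors::DataFrame(row.names = barcodes)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}

#' @rdname readCountsMTX
#' @param x a SingleCellExperiment (its \code{counts} assay and colData are
#'   written) or a genes x cells matrix.
#' @export
writeCountsMTX <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- .getAssay(x, "counts", "writeCountsMTX")
  Matrix::writeMM(as(as(counts, "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(rownames(counts), rownames(counts),
                         "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (is(x, "SummarizedExperiment") &&
      ncol(SummarizedExperiment::colData(x))) {
    ann <- as.data.frame(SummarizedExperiment::colData(x))
    ann <- cbind(cell_id = colnames(x), ann)
    write.csv(ann, file.path(dir, "annotation.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(dir)
}

#' Read / write GMT gene-set collections
#'
#' GMT is one set per line: \code{set_id <TAB> description <TAB> gene ...}.
#' Duplicate genes within a set are removed on load; empty sets are dropped
#' with a warning.
#'
#' @param file path to a .gmt file.
#' @return named list of character gene-id vectors, with a
#'   \code{description} attribute (named character vector).
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped: ",
            paste(head(ids[empty], 5), collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set identifiers")
  attr(sets, "description") <- stats::setNames(desc, names(sets))
  sets
}

#' @rdname readGMT
#' @param sets named list of gene-id vectors.
#' @export
writeGMT <- function(sets, file) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

#' Read / write two-species orthology tables
#'
#' Tab-separated, two columns, header row giving the two species names.
#'
#' @param file path to a .tsv file.
#' @return data.frame with two character columns named by species.
#' @export
readOrthology <- function(file) {
  m <- read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(m) != 2L) stop("orthology table must have exactly two columns")
  m
}

#' @rdname readOrthology
#' @param map two-column data.frame named by species.
#' @export
writeOrthology <- function(map, file) {
  write.table(map, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write current-clamp sweep sets
#'
#' The sweep CSV has a \code{time_ms} column followed by one voltage column
#' (mV) per sweep; the JSON sidecar maps each sweep id to its protocol:
#' \code{{"sweep1": {"current_pA": -50, "onset_ms": 200, "offset_ms": 800}}}.
#' An optional top-level \code{units} entry is validated against
#' mV / ms / pA.
#'
#' @param csv path of the sweep CSV.
#' @param json path of the protocol sidecar.
#' @return a [SweepSet-class].
#' @export
readSweepSet <- function(csv, json) {
  tab <- read.csv(csv, check.names = FALSE)
  if (names(tab)[1] != "time_ms") stop("first CSV column must be time_ms")
  t <- tab[[1]]
  dts <- diff(t)
  if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts)))) {
    stop("time_ms must be uniformly sampled")
  }
  side <- jsonlite::read_json(json)
  if (!is.null(side$units)) {
    u <- side$units
    ok <- identical(u$voltage, "mV") && identical(u$time, "ms") &&
      identical(u$current, "pA")
    if (!ok) stop("protocol sidecar units must be mV / ms / pA")
    side$units <- NULL
  }
  ids <- setdiff(names(tab), "time_ms")
  if (!all(ids %in% names(side))) {
    stop("protocol sidecar missing sweeps: ",
         paste(setdiff(ids, names(side)), collapse = ", "))
  }
  proto <- do.call(rbind, lapply(ids, function(id) {
    p <- side[[id]]
    data.frame(sweep_id = id, current_pA = as.numeric(p$current_pA),
               onset_ms = as.numeric(p$onset_ms),
               offset_ms = as.numeric(p$offset_ms))
  }))
  v <- as.matrix(tab[ids])
  # traces are stored relative to t[1]; shift windows accordingly
  proto$onset_ms <- proto$onset_ms - t[1]
  proto$offset_ms <- proto$offset_ms - t[1]
  SweepSet(v, proto, dt = dts[1])
}

#' @rdname readSweepSet
#' @param x a SweepSet.
#' @param digits significant digits for voltages in the CSV.
#' @export
writeSweepSet <- function(x, csv, json, digits = 7) {
  v <- sweepVoltages(x)
  tab <- data.frame(time_ms = sweepTimes(x), v, check.names = FALSE)
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  p <- sweepProtocol(x)
  side <- stats::setNames(lapply(seq_len(nrow(p)), function(i) {
    list(current_pA = p$current_pA[i], onset_ms = p$onset_ms[i],
         offset_ms = p$offset_ms[i])
  }), p$sweep_id)
  side$units <- list(voltage = "mV", time = "ms", current = "pA")
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read / write joint-membership tables
#'
#' CSV with columns cell_id, species, native_cluster, joint_cluster; the
#' input of [clusterOverlap()].
#'
#' @param file CSV path.
#' @return data.frame with the four membership columns.
#' @export
readMembership <- function(file) {
  m <- read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cell_id", "species", "native_cluster", "joint_cluster")
  if (!all(need %in% names(m))) {
    stop("membership CSV needs columns: ", paste(need, collapse = ", "))
  }
  m[need]
}

#' @rdname readMembership
#' @param members membership data.frame.
#' @export
writeMembership <- function(members, file) {
  write.csv(members, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write an overlap matrix as labelled CSV
#'
#' @param x an [OverlapMatrix-class].
#' @param file CSV path.
#' @param digits significant digits.
#' @export
writeOverlap <- function(x, file, digits = 10) {
  m <- as.matrix(x)
  out <- data.frame(cluster = rownames(m), signif(m, digits),
                    check.names = FALSE)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
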