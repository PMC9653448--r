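#' Counts-per-10k normalization
#'
#' Scales each cell so that its counts sum to \code{scale} (default 10,000):
#' \code{NC[g, c] = counts[g, c] / total[c] * scale}, i.e. counts per 10k,
#' one hundredth of counts per million.
#'
#' @param x a SingleCellExperiment/SummarizedExperiment with a \code{counts}
#'   assay, or a genes x cells count matrix.
#' @param scale target per-cell total (default 10,000).
#' @param dropZero drop cells with zero total counts instead of erroring.
#' @return for a SummarizedExperiment input, the object with a new
#'   \code{cp10k} assay; for a matrix input, the normalized matrix.
#' @examples
#' m <- matrix(c(2, 3, 5), nrow = 3, dimnames = list(paste0("g", 1:3), "c1"))
#' normalizeCP10K(m)[, 1]  # 2000 3000 5000
#' @export
normalizeCP10K <- function(x, scale = 10000, dropZero = FALSE) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  .assertFlag(dropZero, "dropZero")
  counts <- .getAssay(x, "counts", "normalizeCP10K")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    if (!dropZero) {
      stop(sum(zero), " cell(s) have zero total counts; ",
           "set dropZero = TRUE to remove them")
    }
    x <- if (is(x, "SummarizedExperiment")) x[, !zero] else
      x[, !zero, drop = FALSE]
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  nc <- if (is(counts, "sparseMatrix")) {
    counts %*% Matrix::Diagonal(x = scale / totals)
  } else {
    sweep(counts, 2, totals / scale, "/")
  }
  dimnames(nc) <- dimnames(counts)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "cp10k") <- nc
    x
  } else {
    nc
  }
}

#' Log2 transformation of normalized counts
#'
#' Computes \code{log2(NC + 1)} elementwise on counts-per-10k values.
#'
#' @param x a SummarizedExperiment carrying a \code{cp10k} assay (the result
#'   is stored as \code{logcounts}), or a matrix of cp10k values.
#' @return same type as \code{x}.
#' @export
logTransform <- function(x) {
  nc <- .getAssay(x, "cp10k", "logTransform")
  lg <- if (is(nc, "sparseMatrix")) {
    out <- nc
    out@x <- log2(out@x + 1)  # log2(0 + 1) = 0, sparsity preserved
    out
  } else {
    log2(nc + 1)
  }
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "logcounts") <- lg
    x
  } else {
    lg
  }
}

#' Per-gene z-scoring across cells
#'
#' Centers and scales each gene across cells of the log-normalized matrix.
#' The default divisor is N (population standard deviation); set
#' \code{denominator = "sample"} for N - 1.  Genes with zero variance are
#' mapped to all-zero rows rather than NaN so that downstream correlations
#' stay defined.
#'
#' @param x a SummarizedExperiment carrying a \code{logcounts} assay (result
#'   stored as dense \code{zscore} assay), or a matrix of logcounts.
#' @param denominator "population" (divide by N, default) or "sample"
#'   (divide by N - 1).
#' @return same type as \code{x}.
#' @export
zscoreGenes <- function(x, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  lg <- as.matrix(.getAssay(x, "logcounts", "zscoreGenes"))
  n <- ncol(lg)
  mu <- rowMeans(lg)
  cen <- lg - mu
  ss <- rowSums(cen^2)
  sdv <- sqrt(ss / if (denominator == "population") n else max(n - 1L, 1L))
  z <- cen / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "zscore") <- z
    x
  } else {
    z
  }
}

#' Select highly variable genes
#'
#' Ranks genes by the dispersion (variance / mean) of log-normalized
#' expression, normalized within 20 equal-frequency mean bins (a gene is
#' compared against genes of similar abundance, as mean and variance are
#' coupled on the log scale).  Ties are broken lexicographically by gene id
#' so that selection is invariant to gene order.
#'
#' @param x a SummarizedExperiment carrying a \code{logcounts} assay or a
#'   genes x cells matrix of logcounts.
#' @param n number of genes to return; if fewer genes exist, all are
#'   returned ("up to n").
#' @param nbins number of mean bins for dispersion normalization.
#' @return character vector of selected gene ids, ranked.
#' @export
selectHVG <- function(x, n = 2000, nbins = 20) {
  .assertCount(n, "n", min = 1L)
  lg <- .getAssay(x, "logcounts", "selectHVG")
  if (is.null(rownames(lg))) stop("matrix must have gene row names")
  ncell <- ncol(lg)
  mu <- as.numeric(Matrix::rowMeans(lg))
  ss <- as.numeric(Matrix::rowSums(lg^2))
  v <- (ss - ncell * mu^2) / max(ncell - 1L, 1L)
  v <- pmax(v, 0)
  disp <- ifelse(mu > 0, v / mu, 0)

  nbins <- max(1L, min(nbins, floor(length(mu) / 5)))  # >= ~5 genes per bin
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nbins + 1)))
  bin <- if (length(breaks) > 2) {
    cut(mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(mu))
  }
  norm_disp <- disp
  for (b in unique(bin)) {
    i <- bin == b
    med <- stats::median(disp[i])
    scl <- stats::mad(disp[i])
    if (scl == 0) scl <- stats::sd(disp[i])
    if (is.na(scl) || scl == 0) scl <- 1
    norm_disp[i] <- (disp[i] - med) / scl
  }
  ord <- order(-norm_disp, rownames(lg), method = "radix")
  head(rownames(lg)[ord], min(n, nrow(lg)))
}

#' Subsample cells per cluster
#'
#' Draws at most \code{n} cells per cluster without replacement (clusters
#' smaller than \code{n} keep all their cells), equalizing cluster sizes
#' before integration or overlap computations.  Each cluster consumes an
#' independent child RNG stream derived from \code{(seed, cluster label)},
#' so adding or removing a cluster does not perturb the cells drawn for the
#' others.
#'
#' @param x a SummarizedExperiment whose \code{colData} carries
#'   \code{cluster_key}.
#' @param cluster_key name of the colData column holding cluster labels.
#' @param n maximum cells per cluster (default 500).
#' @param seed integer seed.
#' @return \code{x} restricted to the sampled cells (original column order).
#' @export
subsamplePerCluster <- function(x, cluster_key, n = 500, seed = 1) {
  .assertCount(n, "n", min = 1L)
  if (!is(x, "SummarizedExperiment")) {
    stop("subsamplePerCluster expects a SummarizedExperiment with colData")
  }
  cd <- SummarizedExperiment::colData(x)
  if (!cluster_key %in% names(cd)) {
    stop("unknown cluster_key: '", cluster_key, "'")
  }
  labels <- as.character(cd[[cluster_key]])
  keep <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) > n) {
      idx <- .withSeed(.childSeed(seed, paste0("subsample:", cl)),
                       sort(sample(idx, n)))
    }
    keep <- c(keep, idx)
  }
  x[, sort(keep)]
}
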