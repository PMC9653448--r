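#' Cross-species co-clustering overlap
#'
#' Quantifies how well a native cluster of one species corresponds to a
#' native cluster of another species through a joint (integrated)
#' clustering of the pooled cells.  For native clusters \eqn{a} (species A)
#' and \eqn{b} (species B), let \eqn{p_a(h)} be the fraction of \eqn{a}'s
#' cells assigned to joint cluster \eqn{h}, and likewise \eqn{p_b(h)}.
#' The overlap is
#' \deqn{\mathrm{overlap}(a, b) = \sum_h \min\{p_a(h), p_b(h)\},}
#' the sum of the minimum co-membership proportions over joint clusters.
#' This equals one minus the total-variation distance between the two
#' proportion vectors: 1 for identical joint-cluster profiles, 0 for
#' disjoint support.
#'
#' @param members data.frame with columns \code{cell_id}, \code{species},
#'   \code{native_cluster}, \code{joint_cluster}; each cell appears once.
#' @param species_a,species_b the two species to compare (rows of the result
#'   are species-A clusters, columns species-B clusters).
#' @return an [OverlapMatrix-class].
#' @examples
#' members <- data.frame(
#'   cell_id = paste0("c", 1:20),
#'   species = rep(c("human", "macaque"), each = 10),
#'   native_cluster = "L2/3-IT",
#'   joint_cluster = c(rep("h1", 6), rep("h2", 4), rep("h1", 5), rep("h2", 5)))
#' as.matrix(clusterOverlap(members, "human", "macaque"))  # 0.9
#' @export
clusterOverlap <- function(members, species_a, species_b) {
  need <- c("cell_id", "species", "native_cluster", "joint_cluster")
  if (!all(need %in% names(members))) {
    stop("membership table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(members$cell_id)) {
    stop("each cell must appear exactly once in the membership table")
  }
  if (any(is.na(members$joint_cluster))) {
    stop("every cell needs a joint_cluster label")
  }
  props <- function(sp) {
    sub <- members[members$species == sp, ]
    if (!nrow(sub)) stop("species '", sp, "' absent from membership table")
    tab <- table(factor(sub$native_cluster),
                 factor(sub$joint_cluster,
                        levels = sort(unique(members$joint_cluster))))
    if (any(rowSums(tab) == 0)) stop("empty native cluster for '", sp, "'")
    tab / rowSums(tab)
  }
  pa <- props(species_a)
  pb <- props(species_b)
  ov <- matrix(0, nrow(pa), nrow(pb),
               dimnames = list(rownames(pa), rownames(pb)))
  for (i in seq_len(nrow(pa))) {
    # sum_h min(p_a(h), p_b(h)), vectorized over b
    ov[i, ] <- colSums(pmin(t(pb), as.numeric(pa[i, ])))
  }
  new("OverlapMatrix", overlap = pmin(pmax(ov, 0), 1),
      speciesA = species_a, speciesB = species_b)
}

#' Order an overlap matrix for display
#'
#' Reorders rows and columns by average-linkage hierarchical clustering of
#' overlap dissimilarity (cosmetic only; values are untouched).  Ties are
#' resolved by the lexicographic cluster order used to build the matrix.
#'
#' @param x an [OverlapMatrix-class].
#' @return an OverlapMatrix with permuted rows/columns.
#' @export
orderOverlap <- function(x) {
  m <- as.matrix(x)
  ord <- function(d) {
    if (nrow(d) < 3) return(seq_len(nrow(d)))
    stats::hclust(stats::dist(d), method = "average")$order
  }
  new("OverlapMatrix", overlap = m[ord(m), ord(t(m)), drop = FALSE],
      speciesA = x@speciesA, speciesB = x@speciesB)
}

#' Cross-species homology pipeline
#'
#' End-to-end wrapper from per-species counts to an overlap matrix:
#' one-to-one ortholog restriction, per-cluster subsampling (500 cells per
#' cluster by default), cp10k/log2 normalization, HVG selection, and the
#' overlap statistic on a joint clustering.  Joint cluster labels from a
#' dedicated integration tool (e.g. Harmony or scVI followed by Louvain) are
#' the intended input; when none are supplied, a plumbing fallback derives
#' joint labels by per-species z-scoring, PCA on the pooled HVG matrix and
#' k-means.  The fallback is not an integration method and is labelled as
#' such in the run report.
#'
#' @param matrices named list of two SingleCellExperiments (counts assay +
#'   colData with the \code{cluster_key} column).
#' @param maps orthology table(s); see [restrictToOrthologs()].
#' @param cluster_key colData column holding the native (subclass-level)
#'   cluster labels (default "subclass").
#' @param n_subsample cells kept per native cluster (default 500).
#' @param hvg_n number of highly variable genes (default 2000).
#' @param joint_labels optional named character vector (names = cell ids)
#'   of joint cluster labels covering all retained cells.
#' @param fallback_k number of k-means clusters for the fallback path;
#'   required when \code{joint_labels} is NULL.
#' @param n_pcs principal components for the fallback embedding.
#' @param seed integer seed (subsampling and k-means).
#' @return list with \code{overlap} (an [OverlapMatrix-class]),
#'   \code{members} (the membership table), and \code{report} (path used,
#'   gene/cell counts, parameters).
#' @export
homologyPipeline <- function(matrices, maps, cluster_key = "subclass",
                             n_subsample = 500, hvg_n = 2000,
                             joint_labels = NULL, fallback_k = NULL,
                             n_pcs = 50, seed = 1) {
  if (length(matrices) != 2L || is.null(names(matrices))) {
    stop("homologyPipeline needs a named list of exactly two species")
  }
  if (is.null(joint_labels) && is.null(fallback_k)) {
    stop("supply joint_labels, or fallback_k for the k-means fallback")
  }
  species <- names(matrices)
  restr <- restrictToOrthologs(matrices, maps, reference = species[1])
  sub <- lapply(species, function(sp) {
    subsamplePerCluster(restr$matrices[[sp]], cluster_key, n = n_subsample,
                        seed = .childSeed(seed, paste0("subsample-", sp)))
  })
  names(sub) <- species

  cells <- unlist(lapply(sub, colnames), use.names = FALSE)
  if (anyDuplicated(cells)) stop("cell identifiers collide across species")

  if (is.null(joint_labels)) {
    path <- "fallback_kmeans (plumbing only, not an integration method)"
    zs <- lapply(sub, function(s) {
      zscoreGenes(logTransform(normalizeCP10K(
        .getAssay(s, "counts", "homologyPipeline"))))
    })
    pooled_log <- do.call(cbind, lapply(sub, function(s) {
      logTransform(normalizeCP10K(.getAssay(s, "counts", "homologyPipeline")))
    }))
    hvg <- selectHVG(pooled_log, n = hvg_n)
    pooled_z <- t(as.matrix(do.call(cbind, lapply(zs, function(z)
      z[hvg, , drop = FALSE]))))
    k_pcs <- min(n_pcs, dim(pooled_z) - 1L)
    pcs <- stats::prcomp(pooled_z, rank. = k_pcs, center = TRUE,
                         scale. = FALSE)$x
    km <- .withSeed(.childSeed(seed, "kmeans"),
                    stats::kmeans(pcs, centers = min(fallback_k, nrow(pcs)),
                                  nstart = 10, iter.max = 100))
    joint <- stats::setNames(paste0("joint", km$cluster), rownames(pooled_z))
  } else {
    path <- "external_joint_labels"
    hvg <- character()
    missing <- setdiff(cells, names(joint_labels))
    if (length(missing)) {
      stop(length(missing), " retained cell(s) lack a joint label")
    }
    joint <- joint_labels
  }

  members <- do.call(rbind, lapply(species, function(sp) {
    s <- sub[[sp]]
    data.frame(cell_id = colnames(s), species = sp,
               native_cluster = as.character(
                 SummarizedExperiment::colData(s)[[cluster_key]]),
               joint_cluster = as.character(joint[colnames(s)]),
               stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  ov <- clusterOverlap(members, species[1], species[2])
  list(overlap = ov, members = members,
       report = list(path = path, species = species,
                     n_genes_shared = nrow(restr$matrices[[1]]),
                     n_cells = vapply(sub, ncol, 0L),
                     n_hvg = length(hvg), n_subsample = n_subsample,
                     cluster_key = cluster_key, seed = seed))
}
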