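#' Cross-species gene-set divergence pipeline
#'
#' End-to-end wrapper from per-species annotated counts to gene-set
#' correlation records and their distributional comparison: one-to-one
#' ortholog restriction, cp10k/log2/z-score normalization per species,
#' collapse to class-level profiles (mean-of-means over subclasses), and
#' Spearman correlation of each gene set's profiles between species pairs,
#' followed by Kruskal-Wallis + Dunn comparison of the correlation
#' distributions across class x pair groups.
#'
#' @param matrices named list of SingleCellExperiments (counts assay +
#'   colData with subclass and class columns), one per species; the first
#'   is the ortholog reference.
#' @param maps orthology table(s); see [restrictToOrthologs()].
#' @param sets named list of gene-id vectors on the reference gene space.
#' @param classes,pairs forwarded to [genesetCorrelations()].
#' @param collapse within-subclass collapse statistic ("mean" or
#'   "median").
#' @param zscore_before_restriction compute per-gene z-scores on each
#'   species' full gene space before ortholog restriction (default FALSE:
#'   restrict first, then z-score on the shared space).
#' @param compare also run [compareRhoDistributions()] when at least two
#'   (class, pair) groups have two or more records.
#' @return list with \code{profiles} (per-species [ClassProfile-class]),
#'   \code{records} (correlation table), \code{comparison} (KW/Dunn result
#'   or NULL) and \code{report}.
#' @export
divergencePipeline <- function(matrices, maps, sets, classes = NULL,
                               pairs = NULL,
                               collapse = c("mean", "median"),
                               zscore_before_restriction = FALSE,
                               compare = TRUE) {
  collapse <- match.arg(collapse)
  .assertFlag(zscore_before_restriction, "zscore_before_restriction")
  if (zscore_before_restriction) {
    matrices <- lapply(matrices, function(m)
      zscoreGenes(logTransform(normalizeCP10K(m))))
  }
  restr <- restrictToOrthologs(matrices, maps)
  profiles <- lapply(names(restr$matrices), function(sp) {
    m <- restr$matrices[[sp]]
    ann <- if (is(m, "SummarizedExperiment")) {
      cd <- SummarizedExperiment::colData(m)
      data.frame(cell_id = colnames(m),
                 subclass = as.character(cd$subclass),
                 class = as.character(cd$class),
                 stringsAsFactors = FALSE)
    } else {
      attr(m, "annotation")
    }
    # run the normalization chain on the bare matrix: identical numerics,
    # without intermediate copies of the container
    assay_name <- if (zscore_before_restriction) "zscore" else "counts"
    z <- .getAssay(m, assay_name, "divergencePipeline")
    if (!zscore_before_restriction) {
      z <- zscoreGenes(logTransform(normalizeCP10K(z)))
    } else {
      z <- as.matrix(z)
    }
    collapseToClassProfile(z, annotation = ann, species = sp,
                           collapse = collapse)
  })
  names(profiles) <- names(restr$matrices)
  records <- genesetCorrelations(profiles, sets, classes = classes,
                                 pairs = pairs)
  comparison <- NULL
  if (compare) {
    grp <- paste(records$class, records$species_a, records$species_b,
                 sep = "|")
    sizes <- table(grp)
    if (length(sizes) >= 2 && all(sizes >= 2)) {
      comparison <- compareRhoDistributions(records)
    }
  }
  list(profiles = profiles, records = records, comparison = comparison,
       report = list(n_shared_genes = nrow(profileMatrix(profiles[[1]])),
                     collapse = collapse,
                     zscore_before_restriction = zscore_before_restriction,
                     dropped = restr$report,
                     skipped_sets = attr(records, "skipped")))
}
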