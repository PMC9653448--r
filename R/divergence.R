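#' Collapse a z-score matrix to class-level profiles
#'
#' Implements the two-stage, sampling-bias-aware collapse used for
#' cross-species expression comparison: for each gene, first the
#' within-subclass statistic of z-scores (mean by default; median
#' optionally), then the unweighted mean of those subclass values across the
#' subclasses of each class.  Equal subclass weighting prevents abundant
#' populations from dominating a class profile.
#'
#' @param x a SummarizedExperiment carrying a \code{zscore} assay and
#'   colData columns \code{subclass} and \code{class}, or a genes x cells
#'   z-score matrix plus an \code{annotation} data.frame.
#' @param annotation for matrix input: data.frame with \code{cell_id},
#'   \code{subclass}, \code{class} (and optionally \code{species}).
#' @param species species label stored in the result (taken from the
#'   annotation when present).
#' @param collapse within-subclass statistic: "mean" (default) or "median".
#' @return a [ClassProfile-class].
#' @export
collapseToClassProfile <- function(x, annotation = NULL, species = NULL,
                                   collapse = c("mean", "median")) {
  collapse <- match.arg(collapse)
  if (is(x, "SummarizedExperiment")) {
    z <- as.matrix(.getAssay(x, "zscore", "collapseToClassProfile"))
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("subclass", "class") %in% names(cd))) {
      stop("colData needs 'subclass' and 'class' columns")
    }
    annotation <- data.frame(cell_id = colnames(x),
                             subclass = as.character(cd$subclass),
                             class = as.character(cd$class),
                             stringsAsFactors = FALSE)
    if (is.null(species) && "species" %in% names(cd)) {
      species <- unique(as.character(cd$species))
    }
  } else {
    z <- as.matrix(x)
    if (is.null(annotation)) stop("matrix input requires an annotation table")
    annotation <- annotation[match(colnames(z), annotation$cell_id), ]
    if (anyNA(annotation$subclass)) stop("every cell needs subclass/class labels")
  }
  if (is.null(species)) species <- "unknown"
  if (length(species) != 1L) stop("cells from more than one species supplied")

  sub2class <- unique(annotation[, c("subclass", "class")])
  if (anyDuplicated(sub2class$subclass)) {
    stop("subclass -> class mapping must be many-to-one")
  }
  f <- factor(annotation$subclass)
  sub_means <- if (collapse == "mean") {
    t(rowsum(t(z), f) / as.integer(table(f)))
  } else {
    matrix(vapply(levels(f), function(s) {
      apply(z[, f == s, drop = FALSE], 1, stats::median)
    }, numeric(nrow(z))), nrow = nrow(z))
  }
  colnames(sub_means) <- levels(f)
  classes <- sort(unique(sub2class$class))
  prof <- matrix(vapply(classes, function(cl) {
    subs <- sub2class$subclass[sub2class$class == cl]
    rowMeans(sub_means[, subs, drop = FALSE])
  }, numeric(nrow(z))), nrow = nrow(z))
  dimnames(prof) <- list(rownames(z), classes)
  nsub <- vapply(classes, function(cl)
    sum(sub2class$class == cl), 0L)
  new("ClassProfile", species = species, profile = prof,
      nSubclasses = stats::setNames(nsub, classes), collapse = collapse)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the Pearson correlation of average-tied ranks, with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' An exact permutation p-value (all n! permutations) is available for
#' n <= 8.  A constant input makes rho undefined; the result is flagged,
#' never silently zero.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @param exact compute the permutation p-value (n <= 8 only).
#' @return list with \code{rho}, \code{p}, \code{n} and \code{defined}
#'   (FALSE, with rho/p NA, when either input is constant).
#' @export
spearmanRho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (exact) {
    if (n > 8) stop("exact permutation p only supported for n <= 8")
    perms <- .permutations(n)
    rmy <- ry - mean(ry)
    rmx <- rx - mean(rx)
    denom <- sqrt(sum(rmx^2) * sum(rmy^2))
    rhos <- apply(perms, 1, function(p) sum(rmx * rmy[p])) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

# all permutations of 1..n as an n! x n matrix (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Gene-set correlations between species' class profiles
#'
#' For every (gene set, class, species pair), correlates the two species'
#' class-level z-score profiles over the genes of the set (Spearman).  Gene
#' sets are intersected with the shared (post-ortholog) gene space; genes
#' missing from it are dropped and counted, and sets with fewer than 3
#' usable genes are skipped with a reason.
#'
#' @param profiles named list of [ClassProfile-class] objects, one per
#'   species, on a common gene space.
#' @param sets named list of gene-id vectors (see [readGMT()]).
#' @param classes classes to correlate (default: classes common to all
#'   profiles).
#' @param pairs species pairs as a list of length-2 character vectors, or
#'   strings "A:B" (default: all pairs against the first species).
#' @return data.frame with columns \code{set_id}, \code{class},
#'   \code{species_a}, \code{species_b}, \code{rho}, \code{p},
#'   \code{n_genes}, \code{n_dropped}; skipped sets are recorded in the
#'   \code{skipped} attribute.
#' @export
genesetCorrelations <- function(profiles, sets, classes = NULL,
                                pairs = NULL) {
  if (length(profiles) < 2L || is.null(names(profiles))) {
    stop("need a named list of at least two ClassProfiles")
  }
  gene_space <- rownames(profileMatrix(profiles[[1]]))
  for (p in profiles) {
    if (!identical(rownames(profileMatrix(p)), gene_space)) {
      stop("profiles must share one gene space (run ortholog restriction first)")
    }
  }
  if (is.null(classes)) {
    classes <- Reduce(intersect, lapply(profiles, function(p)
      colnames(profileMatrix(p))))
  }
  if (is.null(pairs)) {
    pairs <- lapply(names(profiles)[-1], function(s)
      c(names(profiles)[1], s))
  }
  pairs <- lapply(pairs, function(p) {
    if (length(p) == 1L) strsplit(p, ":", fixed = TRUE)[[1]] else p
  })
  n_max <- length(sets) * length(classes) * length(pairs)
  acc <- list(set_id = character(n_max), class = character(n_max),
              species_a = character(n_max), species_b = character(n_max),
              rho = numeric(n_max), p = numeric(n_max),
              n_genes = integer(n_max), n_dropped = integer(n_max))
  i <- 0L
  skipped <- list()
  for (set_id in names(sets)) {
    genes <- intersect(sets[[set_id]], gene_space)
    n_drop <- length(sets[[set_id]]) - length(genes)
    if (length(genes) < 3L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        set_id = set_id, reason = "fewer_than_3_usable_genes",
        n_usable = length(genes))
      next
    }
    for (cl in classes) {
      for (pr in pairs) {
        pa <- profileMatrix(profiles[[pr[1]]])[genes, cl]
        pb <- profileMatrix(profiles[[pr[2]]])[genes, cl]
        sr <- spearmanRho(pa, pb)
        i <- i + 1L
        acc$set_id[i] <- set_id; acc$class[i] <- cl
        acc$species_a[i] <- pr[1]; acc$species_b[i] <- pr[2]
        acc$rho[i] <- sr$rho; acc$p[i] <- sr$p
        acc$n_genes[i] <- length(genes); acc$n_dropped[i] <- n_drop
      }
    }
  }
  if (i == 0L) stop("no gene set produced a correlation record")
  out <- data.frame(lapply(acc, `[`, seq_len(i)), stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(set_id = character(), reason = character(),
               n_usable = integer())
  out
}

# Kruskal-Wallis H with tie correction, plus the pooled tie term needed by
# Dunn's test.  values: numeric; groups: factor.
.kruskalH <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values, ties.method = "average")
  Rbar <- tapply(r, groups, mean)
  n <- as.integer(table(groups))
  H <- 12 / (N * (N + 1)) * sum(n * Rbar^2) - 3 * (N + 1)
  ties <- table(r)
  tie_sum <- sum(ties^3 - ties)
  C <- 1 - tie_sum / (N^3 - N)
  list(H = if (C > 0) H / C else NA_real_,
       df = nlevels(groups) - 1L,
       mean_ranks = Rbar, n = stats::setNames(n, levels(groups)),
       tie_sum = tie_sum, N = N)
}

#' Compare correlation distributions across groups
#'
#' Kruskal-Wallis test (with tie correction) on values grouped by label,
#' followed by Dunn's pairwise z-tests on mean ranks with Bonferroni
#' adjustment over all pairwise comparisons of the run (capped at 1).  Used
#' to compare gene-set rho distributions across class x species-pair
#' groups.
#'
#' @param values numeric vector (e.g. rho values), or the data.frame
#'   returned by [genesetCorrelations()].
#' @param groups group labels (same length as \code{values}); for
#'   data.frame input, the grouping columns (default class + species pair)
#'   are pasted instead.
#' @param grouping for data.frame input: columns pasted to form groups.
#' @return list with \code{H}, \code{df}, \code{p} (KW), and \code{dunn}, a
#'   symmetric matrix of Bonferroni-adjusted pairwise p-values with 1 on
#'   the diagonal; raw z statistics in attribute \code{z}.
#' @export
compareRhoDistributions <- function(values, groups = NULL,
                                    grouping = c("class", "species_a",
                                                 "species_b")) {
  if (is.data.frame(values)) {
    df <- values
    if (!all(grouping %in% names(df))) {
      stop("grouping columns missing from records")
    }
    groups <- do.call(paste, c(df[grouping], sep = "|"))
    values <- df$rho
  }
  keep <- is.finite(values)
  values <- values[keep]
  groups <- factor(as.character(groups)[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")

  kw <- .kruskalH(values, groups)
  p_kw <- stats::pchisq(kw$H, df = kw$df, lower.tail = FALSE)

  lev <- levels(groups)
  k <- length(lev)
  dunn <- matrix(1, k, k, dimnames = list(lev, lev))
  zmat <- matrix(0, k, k, dimnames = list(lev, lev))
  n_comp <- k * (k - 1) / 2
  sigma2_base <- kw$N * (kw$N + 1) / 12 - kw$tie_sum / (12 * (kw$N - 1))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(sigma2_base * (1 / kw$n[i] + 1 / kw$n[j]))
      z <- (kw$mean_ranks[i] - kw$mean_ranks[j]) / se
      p <- min(2 * stats::pnorm(-abs(z)) * n_comp, 1)
      dunn[i, j] <- dunn[j, i] <- p
      zmat[i, j] <- z
      zmat[j, i] <- -z
    }
  }
  attr(dunn, "z") <- zmat
  list(H = kw$H, df = kw$df, p = p_kw, dunn = dunn,
       group_sizes = kw$n, mean_ranks = kw$mean_ranks)
}

#' Genes farthest from the cross-species regression line
#'
#' Fits ordinary least squares of species-B profile values on species-A
#' values over the genes of one set and class, and returns the k genes with
#' the largest absolute residual (vertical distance to the regression line;
#' orthogonal distance optionally).  These are the set's most divergent
#' genes relative to its overall cross-species trend.
#'
#' @param profile_a,profile_b [ClassProfile-class] objects on a shared gene
#'   space.
#' @param genes gene ids of the set (>= 3 usable).
#' @param class class column to use.
#' @param k how many genes to return (default 3); if k exceeds the set
#'   size the whole set is returned.
#' @param distance "vertical" (OLS residual, default) or "orthogonal".
#' @return data.frame with \code{gene_id}, \code{residual},
#'   \code{abs_distance}, ordered by decreasing distance (ties broken by
#'   gene id).
#' @export
topResidualGenes <- function(profile_a, profile_b, genes, class, k = 3,
                             distance = c("vertical", "orthogonal")) {
  distance <- match.arg(distance)
  .assertCount(k, "k", min = 1L)
  shared <- intersect(genes, rownames(profileMatrix(profile_a)))
  shared <- intersect(shared, rownames(profileMatrix(profile_b)))
  if (length(shared) < 3L) stop("need at least 3 usable genes")
  a <- profileMatrix(profile_a)[shared, class]
  b <- profileMatrix(profile_b)[shared, class]
  if (stats::var(a) == 0) stop("degenerate fit: zero variance in species-A values")
  fit <- stats::lm(b ~ a)
  res <- stats::residuals(fit)
  d <- if (distance == "vertical") {
    abs(res)
  } else {
    abs(res) / sqrt(1 + coef(fit)[["a"]]^2)
  }
  # round away numeric fuzz so exact ties fall back to the gene-id order
  ord <- order(-round(d, 10), shared, method = "radix")
  out <- data.frame(gene_id = shared, residual = as.numeric(res),
                    abs_distance = as.numeric(d),
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  head(out, min(k, nrow(out)))
}

#' Flag genes with at least a given fold change between species
#'
#' Computes per-gene fold changes between two mean expression vectors on the
#' linear (counts-per-10k) scale and flags genes at or beyond the threshold
#' in either direction.
#'
#' @param mean_a,mean_b named non-negative mean expression vectors on a
#'   shared gene space (linear NC scale).
#' @param threshold fold-change threshold (default 2, i.e. "twofold").
#' @param pseudocount added to both means before the ratio (default 0).
#' @return data.frame with \code{gene_id}, \code{mean_a}, \code{mean_b},
#'   \code{fold_change} (a over b), \code{flagged}, \code{direction}
#'   ("higher_in_a", "higher_in_b" or "").
#' @export
foldChangeGenes <- function(mean_a, mean_b, threshold = 2.0,
                            pseudocount = 0) {
  if (is.null(names(mean_a)) || is.null(names(mean_b))) {
    stop("mean expression vectors must be named by gene")
  }
  if (!identical(names(mean_a), names(mean_b))) {
    shared <- intersect(names(mean_a), names(mean_b))
    if (!length(shared)) stop("no shared genes")
    mean_a <- mean_a[shared]
    mean_b <- mean_b[shared]
  }
  if (any(mean_a < 0) || any(mean_b < 0)) stop("mean expression must be >= 0")
  if (threshold < 1) stop("threshold must be >= 1")
  fc <- (mean_a + pseudocount) / (mean_b + pseudocount)
  fc[(mean_a + pseudocount) == 0 & (mean_b + pseudocount) == 0] <- 1
  up <- fc >= threshold
  dn <- fc <= 1 / threshold
  data.frame(gene_id = names(mean_a), mean_a = as.numeric(mean_a),
             mean_b = as.numeric(mean_b), fold_change = as.numeric(fc),
             flagged = up | dn,
             direction = ifelse(up, "higher_in_a",
                                ifelse(dn, "higher_in_b", "")),
             stringsAsFactors = FALSE, row.names = NULL)
}
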