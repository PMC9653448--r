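# Negative binomial multi-species count simulator with hierarchical
# class/subclass structure and controlled cross-species divergence.
# Counts are drawn NB(mu, size) with mu = library_size * softmax(2^eta),
# where the latent log2 mean eta of gene g in subclass u of species s is
#   eta = base_g + classEffect_{g, class(u)} + subclassEffect_{g, u}
#         + deviation_{g, class(u), s}.
# Deviations are zero for the reference species and Normal(0, sigma) per
# (gene set, class, species pair) otherwise, so the expected decorrelation
# of class-level z-score profiles between species grows monotonically with
# sigma -- the recovery target of the divergence analyses.

#' Configuration for the multi-species count simulator
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: three species (the first is the divergence reference), 40
#' gene sets of 20 genes, two neuronal classes with four subclasses of 200
#' cells each, and mean library size 20,000.
#'
#' @param species species names; the first is the reference (zero
#'   deviations).
#' @param genes_per_set genes per gene set (>= 3; Spearman is undefined
#'   below 3 genes).
#' @param n_gene_sets number of disjoint gene sets.
#' @param subclasses_per_class named integer vector: subclasses per class.
#' @param cells_per_subclass cells per subclass per species (> 0).
#' @param library_size_mean,library_size_sigma lognormal library-size
#'   factor (mean counts per cell; sdlog).
#' @param nb_dispersion negative binomial size (shape) parameter; smaller
#'   values give more overdispersion.
#' @param base_sd,class_effect_sd,subclass_effect_sd standard deviations of
#'   the latent log2-scale gene, gene-by-class and gene-by-subclass
#'   effects.
#' @param divergence data.frame with columns \code{class},
#'   \code{species_a}, \code{species_b}, \code{set_id}, \code{sigma}
#'   (z-units on the latent log2 scale, >= 0).  \code{class} and
#'   \code{set_id} accept the wildcard \code{"*"}; each pair must include
#'   the reference species.  Missing combinations default to sigma 0.
#' @return a validated config list of class "simulationConfig".
#' @export
simulationConfig <- function(species = c("human", "macaque", "mouse"),
                             genes_per_set = 20, n_gene_sets = 40,
                             subclasses_per_class = c(Exc = 4, Inh = 4,
                                                      Astro = 2),
                             cells_per_subclass = 200,
                             library_size_mean = 20000,
                             library_size_sigma = 0.3,
                             nb_dispersion = 2,
                             base_sd = 1, class_effect_sd = 1.2,
                             subclass_effect_sd = 0.5,
                             divergence = NULL) {
  cfg <- as.list(environment())
  if (length(species) < 1L || anyDuplicated(species)) {
    stop("species must be distinct names")
  }
  if (genes_per_set < 3) {
    stop("genes_per_set must be >= 3 (rank correlation undefined below 3)")
  }
  .assertCount(n_gene_sets, "n_gene_sets", min = 1L)
  .assertCount(cells_per_subclass, "cells_per_subclass", min = 1L)
  if (is.null(names(subclasses_per_class)) ||
      any(subclasses_per_class < 1)) {
    stop("subclasses_per_class must be a named vector of positive counts")
  }
  for (nm in c("library_size_mean", "library_size_sigma", "nb_dispersion",
               "base_sd", "class_effect_sd", "subclass_effect_sd")) {
    if (cfg[[nm]] <= 0 && nm != "library_size_sigma") {
      stop("'", nm, "' must be positive")
    }
  }
  if (!is.null(divergence)) {
    need <- c("class", "species_a", "species_b", "set_id", "sigma")
    if (!all(need %in% names(divergence))) {
      stop("divergence needs columns: ", paste(need, collapse = ", "))
    }
    if (any(divergence$sigma < 0)) stop("divergence sigma must be >= 0")
    ref <- species[1]
    ok_sp <- divergence$species_a %in% species &
      divergence$species_b %in% species
    if (any(!ok_sp)) stop("divergence refers to undeclared species")
    if (any(divergence$species_a != ref & divergence$species_b != ref)) {
      stop("each divergence pair must include the reference species '",
           ref, "' (deviations are parameterized against it)")
    }
  }
  structure(cfg, class = "simulationConfig")
}

#' Canonical divergence structure for validation studies
#'
#' The divergence table used throughout the package's validation
#' experiments: excitatory neurons diverge twice as much as inhibitory
#' neurons, the distant species pair (human-mouse) twice as much as the
#' close pair (human-macaque), and glia half as much as inhibitory
#' neurons -- the qualitative structure reported for primate visual
#' cortex.  \code{sigma_inh} sets the scale (latent log2 z-units) of the
#' inhibitory/close-pair cell; all other cells are fixed ratios of it.
#'
#' @param sigma_inh sigma for (Inh, human-macaque); default 0.5.
#' @param species three species names (reference first).
#' @return data.frame suitable for [simulationConfig()]'s
#'   \code{divergence} argument.
#' @export
studyDivergence <- function(sigma_inh = 0.5,
                            species = c("human", "macaque", "mouse")) {
  div <- expand.grid(class = c("Exc", "Inh", "Astro"),
                     species_b = species[-1], stringsAsFactors = FALSE)
  div$species_a <- species[1]
  div$set_id <- "*"
  class_mult <- c(Exc = 2, Inh = 1, Astro = 0.5)
  pair_mult <- stats::setNames(c(1, 2), species[-1])
  div$sigma <- sigma_inh * class_mult[div$class] *
    pair_mult[div$species_b]
  rownames(div) <- NULL
  div[c("class", "species_a", "species_b", "set_id", "sigma")]
}

# sigma for (class, non-reference species, set); most specific rule wins.
.resolveSigma <- function(divergence, class, sp, set_id) {
  if (is.null(divergence)) return(0)
  d <- divergence
  hit <- (d$species_a == sp | d$species_b == sp) &
    (d$class == class | d$class == "*") &
    (d$set_id == set_id | d$set_id == "*")
  if (!any(hit)) return(0)
  d <- d[hit, , drop = FALSE]
  spec <- (d$class != "*") + (d$set_id != "*")
  d$sigma[which.max(spec)]
}

#' Simulate multi-species count matrices with known divergence structure
#'
#' Draws one annotated count matrix per species from the shared latent
#' model of [simulationConfig()], together with the gene-set collection,
#' pairwise one-to-one orthology tables (species-specific gene identifiers
#' against the reference), and an expression-truth record holding the
#' latent profiles, the per-species deviations, and the divergence ranking
#' implied by the configured sigmas.
#'
#' @param config a [simulationConfig()] list.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @param sparse store counts as a sparse CsparseMatrix (the on-disk 10x
#'   format is always sparse); default FALSE because at the simulated
#'   sequencing depth nearly every entry is nonzero, making the sparse
#'   representation slower and larger in memory.
#' @return list with \code{species} (named list of
#'   [SingleCellExperiment::SingleCellExperiment]; counts assay + colData
#'   species/sample/class/subclass/native_cluster), \code{gene_sets}
#'   (named list of reference gene ids), \code{orthology} (named list of
#'   two-column tables reference vs other species), and \code{truth}
#'   (list: \code{base_profile} gene x class, \code{deviations} gene x
#'   class x species array with an all-zero reference slice,
#'   \code{sigma_table}, \code{divergence_ranking} ordered by decreasing
#'   mean sigma).
#' @export
simulateMultiSpeciesCounts <- function(config = simulationConfig(),
                                       seed = 1, sparse = FALSE) {
  cfg <- if (inherits(config, "simulationConfig")) config else
    do.call(simulationConfig, config)
  n_genes <- cfg$genes_per_set * cfg$n_gene_sets
  genes <- sprintf("G%05d", seq_len(n_genes))
  set_ids <- sprintf("set%03d", seq_len(cfg$n_gene_sets))
  set_of_gene <- rep(set_ids, each = cfg$genes_per_set)
  gene_sets <- split(genes, set_of_gene)[set_ids]

  classes <- names(cfg$subclasses_per_class)
  subclasses <- unlist(lapply(classes, function(cl)
    paste0(cl, "_", seq_len(cfg$subclasses_per_class[[cl]]))))
  class_of_sub <- rep(classes, cfg$subclasses_per_class)
  names(class_of_sub) <- subclasses

  # shared latents
  lat <- .withSeed(.childSeed(seed, "latents"), {
    list(base = rnorm(n_genes, 0, cfg$base_sd),
         class_eff = matrix(rnorm(n_genes * length(classes), 0,
                                  cfg$class_effect_sd),
                            n_genes, length(classes),
                            dimnames = list(genes, classes)),
         sub_eff = matrix(rnorm(n_genes * length(subclasses), 0,
                                cfg$subclass_effect_sd),
                          n_genes, length(subclasses),
                          dimnames = list(genes, subclasses)))
  })

  ref <- cfg$species[1]
  dev <- array(0, dim = c(n_genes, length(classes), length(cfg$species)),
               dimnames = list(genes, classes, cfg$species))
  sigma_rows <- list()
  for (sp in setdiff(cfg$species, ref)) {
    dev[, , sp] <- .withSeed(.childSeed(seed, paste0("dev-", sp)), {
      m <- matrix(0, n_genes, length(classes),
                  dimnames = list(genes, classes))
      for (cl in classes) {
        for (k in set_ids) {
          s <- .resolveSigma(cfg$divergence, cl, sp, k)
          idx <- set_of_gene == k
          if (s > 0) m[idx, cl] <- rnorm(sum(idx), 0, s)
          sigma_rows[[length(sigma_rows) + 1L]] <- data.frame(
            class = cl, species_a = ref, species_b = sp, set_id = k,
            sigma = s)
        }
      }
      m
    })
  }
  sigma_table <- if (length(sigma_rows)) do.call(rbind, sigma_rows) else
    data.frame(class = character(), species_a = character(),
               species_b = character(), set_id = character(),
               sigma = numeric())
  ranking <- if (nrow(sigma_table)) {
    agg <- stats::aggregate(sigma ~ class + species_a + species_b,
                            data = sigma_table, FUN = mean)
    agg[order(-agg$sigma, agg$class, agg$species_b), ]
  } else {
    data.frame(class = character(), species_a = character(),
               species_b = character(), sigma = numeric())
  }
  rownames(ranking) <- NULL

  out_species <- list()
  orthology <- list()
  for (sp in cfg$species) {
    # the reference species carries the canonical identifiers (as human
    # symbols do for public gene-set catalogs); other species get
    # species-qualified identifiers resolved through the orthology table
    sp_genes <- if (sp == ref) genes else paste0(sp, "_", genes)
    counts <- .withSeed(.childSeed(seed, paste0("cells-", sp)), {
      ncell <- cfg$cells_per_subclass * length(subclasses)
      mu <- matrix(0, n_genes, ncell)
      for (k in seq_along(subclasses)) {
        su <- subclasses[k]
        cl <- class_of_sub[[su]]
        eta <- lat$base + lat$class_eff[, cl] + lat$sub_eff[, su] +
          dev[, cl, sp]
        p <- 2^(eta - max(eta))
        p <- p / sum(p)
        lib <- rlnorm(cfg$cells_per_subclass,
                      log(cfg$library_size_mean) -
                        cfg$library_size_sigma^2 / 2,
                      cfg$library_size_sigma)
        mu[, (k - 1L) * cfg$cells_per_subclass + seq_len(cfg$cells_per_subclass)] <-
          outer(p, lib)
      }
      matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
             n_genes, ncell)
    })
    sub_vec <- rep(subclasses, each = cfg$cells_per_subclass)
    cell_ids <- sprintf("%s_%s_c%04d", sp, sub_vec,
                        stats::ave(seq_along(sub_vec), sub_vec,
                                   FUN = seq_along))
    dimnames(counts) <- list(sp_genes, cell_ids)
    cd <- S4Vectors::DataFrame(
      species = sp,
      sample = paste0(sp, "_s", 1 + seq_along(sub_vec) %% 2),
      class = class_of_sub[sub_vec],
      subclass = sub_vec,
      native_cluster = sub_vec,
      row.names = cell_ids)
    if (sparse) {
      counts <- as(counts, "CsparseMatrix")
    }
    out_species[[sp]] <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts), colData = cd)
    if (sp != ref) {
      map <- data.frame(genes, sp_genes, stringsAsFactors = FALSE)
      names(map) <- c(ref, sp)
      orthology[[paste0(ref, ":", sp)]] <- map
    }
  }

  base_profile <- lat$base + lat$class_eff
  truth <- list(base_profile = base_profile, deviations = dev,
                sigma_table = sigma_table, divergence_ranking = ranking,
                subclass_effects = lat$sub_eff)
  list(species = out_species, gene_sets = gene_sets,
       orthology = orthology, truth = truth,
       config = c(unclass(cfg), list(seed = seed)))
}

#' Generate a QC fixture with a known removal record
#'
#' Builds a small count matrix in which exactly \code{n_low_genes} cells
#' fall below 200 detected genes, exactly \code{n_high_mito} cells exceed
#' 30 percent mitochondrial content (with enough detected genes to pass the
#' first gate), and \code{n_pass} cells pass both filters; the expected
#' removal record is returned alongside.
#'
#' @param n_pass,n_low_genes,n_high_mito cell counts per category (>= 0).
#' @param seed integer seed.
#' @param n_genes total genes in the matrix (>= 260).
#' @param n_mito number of mitochondrial genes among them.
#' @param mito_prefix prefix naming mitochondrial genes (default "MT-").
#' @return list with \code{counts} (sparse genes x cells),
#'   \code{expected} (data.frame cell_id, reason), \code{mito_genes}.
#' @export
simulateQCFixture <- function(n_pass, n_low_genes = 0, n_high_mito = 0,
                              seed = 1, n_genes = 320, n_mito = 25,
                              mito_prefix = "MT-") {
  .assertCount(n_pass, "n_pass")
  .assertCount(n_low_genes, "n_low_genes")
  .assertCount(n_high_mito, "n_high_mito")
  if (n_genes - n_mito < 230) stop("need at least 230 non-mito genes")
  mito_genes <- paste0(mito_prefix, seq_len(n_mito))
  reg_genes <- sprintf("G%04d", seq_len(n_genes - n_mito))
  genes <- c(reg_genes, mito_genes)
  n_cells <- n_pass + n_low_genes + n_high_mito
  kinds <- rep(c("pass", "low_genes", "high_mito"),
               c(n_pass, n_low_genes, n_high_mito))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  m <- .withSeed(.childSeed(seed, "qc-fixture"), {
    m <- matrix(0L, length(genes), max(n_cells, 1L),
                dimnames = list(genes, if (n_cells) cell_ids else "empty"))
    for (i in seq_len(n_cells)) {
      if (kinds[i] == "low_genes") {
        # 150 detected genes, low mito: fails only the feature gate
        m[sample(reg_genes, 145), i] <- 1L
        m[sample(mito_genes, 5), i] <- 1L
      } else if (kinds[i] == "high_mito") {
        # 225 detected genes but ~40% mito counts
        m[sample(reg_genes, 215), i] <- 1L
        m[sample(mito_genes, 10), i] <- 15L
      } else {
        # 235 detected genes, ~6% mito counts
        m[sample(reg_genes, 230), i] <- sample(1:3, 230, replace = TRUE)
        m[sample(mito_genes, 5), i] <- 5L
      }
    }
    m
  })
  if (n_cells == 0) m <- m[, 0, drop = FALSE]
  expected <- data.frame(
    cell_id = cell_ids[kinds != "pass"],
    reason = kinds[kinds != "pass"],
    stringsAsFactors = FALSE)
  list(counts = as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
       expected = expected, mito_genes = mito_genes)
}
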