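# Independent oracles used across the suite.  These deliberately use
# naive, per-element algorithms so they share no code path with the
# package implementations they check.

# Brute-force co-clustering overlap: per-cell tallies for every
# (native a, native b, joint h) triple; shares no code with the
# implementation (no contingency tables, no vectorized pmin).
bruteForceOverlap <- function(members, species_a, species_b) {
  joints <- sort(unique(members$joint_cluster))
  ca <- members[members$species == species_a, ]
  cb <- members[members$species == species_b, ]
  rows <- sort(unique(ca$native_cluster))
  cols <- sort(unique(cb$native_cluster))
  out <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (a in rows) {
    in_a <- ca$native_cluster == a
    for (b in cols) {
      in_b <- cb$native_cluster == b
      tot <- 0
      for (h in joints) {
        pa <- sum(in_a & ca$joint_cluster == h) / sum(in_a)
        pb <- sum(in_b & cb$joint_cluster == h) / sum(in_b)
        tot <- tot + min(pa, pb)
      }
      out[a, b] <- tot
    }
  }
  out
}

# Random membership tables: <= 6 joint clusters, <= 50 cells per native
# cluster, 2 species with 1-4 native clusters each.
randomMembership <- function(seed) {
  set.seed(seed)
  n_joint <- sample(1:6, 1)
  mk <- function(sp) {
    n_nat <- sample(1:4, 1)
    do.call(rbind, lapply(seq_len(n_nat), function(k) {
      n <- sample(1:50, 1)
      data.frame(cell_id = paste0(sp, "_", k, "_", seq_len(n)),
                 species = sp, native_cluster = paste0(sp, "_c", k),
                 joint_cluster = paste0("j", sample(n_joint, n,
                                                    replace = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(mk("A"), mk("B"))
}

# Closed-form Spearman for distinct values (no ties).
spearmanClosedForm <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A tiny two-species count simulation shared by several tests.
smallSim <- function(seed = 1, divergence = NULL,
                     species = c("human", "macaque")) {
  cfg <- simulationConfig(
    species = species, genes_per_set = 8, n_gene_sets = 6,
    subclasses_per_class = c(Exc = 2, Inh = 2, Astro = 1),
    cells_per_subclass = 40, library_size_mean = 5000,
    divergence = divergence)
  simulateMultiSpeciesCounts(cfg, seed = seed)
}

# A compact sweep configuration to keep unit tests fast.
smallSweepConfig <- function(...) {
  args <- list(total_ms = 700, onset_ms = 150, offset_ms = 500,
               hyper_currents_pA = c(-100, -60, -30),
               depol_currents_pA = c(80, 160), rheobase_pA = 160)
  override <- list(...)
  args[names(override)] <- override
  do.call(sweepSimConfig, args)
}
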