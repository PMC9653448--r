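test_that("the count generator is a pure function of config and seed", {
  s1 <- smallSim(seed = 42)
  s2 <- smallSim(seed = 42)
  expect_identical(
    SummarizedExperiment::assay(s1$species$human, "counts"),
    SummarizedExperiment::assay(s2$species$human, "counts"))
  expect_identical(s1$truth$deviations, s2$truth$deviations)
  s3 <- smallSim(seed = 43)
  expect_false(identical(
    SummarizedExperiment::assay(s1$species$human, "counts"),
    SummarizedExperiment::assay(s3$species$human, "counts")))
})

test_that("reference-species deviations are exactly zero", {
  div <- data.frame(class = "*", species_a = "human",
                    species_b = "macaque", set_id = "*", sigma = 0.7)
  sim <- smallSim(seed = 2, divergence = div)
  expect_true(all(sim$truth$deviations[, , "human"] == 0))
  expect_gt(sd(sim$truth$deviations[, , "macaque"]), 0)
})

test_that("the divergence ranking orders class pairs by sigma", {
  div <- data.frame(class = c("Exc", "Inh"), species_a = "human",
                    species_b = "macaque", set_id = "*",
                    sigma = c(1.0, 0.2))
  sim <- smallSim(seed = 3, divergence = div)
  rk <- sim$truth$divergence_ranking
  i_exc <- which(rk$class == "Exc" & rk$species_b == "macaque")
  i_inh <- which(rk$class == "Inh" & rk$species_b == "macaque")
  expect_lt(i_exc, i_inh)
  expect_equal(rk$sigma[i_exc], 1.0)
})

test_that("per-gene mean counts increase with the latent mean", {
  cfg <- simulationConfig(
    species = "human", genes_per_set = 25, n_gene_sets = 8,
    subclasses_per_class = c(Exc = 1), cells_per_subclass = 1000,
    library_size_mean = 5000)
  sim <- simulateMultiSpeciesCounts(cfg, seed = 5)
  counts <- SummarizedExperiment::assay(sim$species$human, "counts")
  eta <- sim$truth$base_profile[, "Exc"] + sim$truth$subclass_effects[, "Exc_1"]
  expect_gt(cor(rowMeans(counts), eta, method = "spearman"), 0.9)
})

test_that("cell annotations are consistent with the hierarchy", {
  sim <- smallSim(seed = 7)
  cd <- SummarizedExperiment::colData(sim$species$macaque)
  expect_true(all(table(cd$subclass) == 40))
  map <- unique(data.frame(sub = cd$subclass, cls = cd$class))
  expect_false(anyDuplicated(map$sub) > 0)
  expect_identical(as.character(cd$native_cluster),
                   as.character(cd$subclass))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(genes_per_set = 2), "genes_per_set")
  expect_error(simulationConfig(cells_per_subclass = 0),
               "cells_per_subclass")
  expect_error(simulationConfig(nb_dispersion = -1), "positive")
  expect_error(
    simulationConfig(divergence = data.frame(
      class = "*", species_a = "human", species_b = "rat",
      set_id = "*", sigma = 1)),
    "undeclared")
  expect_error(
    simulationConfig(divergence = data.frame(
      class = "*", species_a = "macaque", species_b = "mouse",
      set_id = "*", sigma = 1)),
    "reference")
  expect_error(
    simulationConfig(divergence = data.frame(
      class = "*", species_a = "human", species_b = "macaque",
      set_id = "*", sigma = -0.1)),
    "sigma")
})

test_that("specific divergence rules override wildcards", {
  div <- data.frame(class = c("*", "Exc"), species_a = "human",
                    species_b = c("macaque", "macaque"),
                    set_id = c("*", "*"), sigma = c(0.1, 0.9))
  expect_equal(xspecies:::.resolveSigma(div, "Exc", "macaque", "set001"),
               0.9)
  expect_equal(xspecies:::.resolveSigma(div, "Inh", "macaque", "set001"),
               0.1)
  expect_equal(xspecies:::.resolveSigma(div, "Inh", "mouse", "set001"), 0)
})
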