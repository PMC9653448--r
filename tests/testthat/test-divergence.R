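test_that("class collapse is the unweighted mean of subclass means", {
  # gene g: subclass S1 mean z 0.2 (10 cells), S2 mean z 0.6 (1000 cells)
  z <- matrix(c(rep(0.2, 10), rep(0.6, 1000)), 1,
              dimnames = list("g", paste0("c", 1:1010)))
  ann <- data.frame(cell_id = colnames(z),
                    subclass = rep(c("S1", "S2"), c(10, 1000)),
                    class = "Exc")
  prof <- collapseToClassProfile(z, ann, species = "sp")
  expect_equal(unname(profileMatrix(prof)["g", "Exc"]), 0.4)
  # not the pooled mean (~0.596)
  expect_false(isTRUE(all.equal(profileMatrix(prof)["g", "Exc"],
                                mean(z), tolerance = 1e-3)))
})

test_that("a single-subclass class collapses to the subclass mean", {
  z <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:10)))
  ann <- data.frame(cell_id = colnames(z), subclass = "S1", class = "Inh")
  prof <- collapseToClassProfile(z, ann, species = "sp")
  expect_equal(unname(profileMatrix(prof)[, "Inh"]),
               unname(rowMeans(z)))
})

test_that("median collapse uses the within-subclass median", {
  z <- matrix(c(1, 2, 100, 5, 5, 5), 1,
              dimnames = list("g", paste0("c", 1:6)))
  ann <- data.frame(cell_id = colnames(z),
                    subclass = rep(c("S1", "S2"), each = 3),
                    class = "Exc")
  prof <- collapseToClassProfile(z, ann, species = "sp",
                                 collapse = "median")
  expect_equal(unname(profileMatrix(prof)["g", "Exc"]), (2 + 5) / 2)
})

test_that("spearman handles monotone transforms, reversals and ties", {
  x <- c(0.3, 1.2, 2.5, 4.1, 7.7)
  expect_equal(spearmanRho(x, exp(x))$rho, 1)
  expect_equal(spearmanRho(x, rev(x))$rho, -1)
  sr <- spearmanRho(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(sr$rho, 4.5 / sqrt(22.5), tolerance = 1e-12)
})

test_that("spearman agrees with closed form on permutations of 6 values", {
  x <- c(2, 3, 5, 8, 13, 21)
  set.seed(1)
  for (i in 1:50) {
    y <- sample(x)
    expect_equal(spearmanRho(x, y)$rho, spearmanClosedForm(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman tie handling and p-value match the reference", {
  set.seed(2)
  for (i in 1:25) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    sr <- spearmanRho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(sr$rho, unname(ref$estimate), tolerance = 1e-10)
  }
})

test_that("constant inputs are flagged, not silently zero", {
  sr <- spearmanRho(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_false(sr$defined)
  expect_true(is.na(sr$rho))
})

test_that("exact permutation p agrees with the null construction", {
  x <- c(1, 2, 3, 4, 5)
  sr <- spearmanRho(x, c(2, 1, 4, 3, 5), exact = TRUE)
  # enumerate all 120 permutations by brute force
  perms <- xspecies:::.permutations(5)
  rhos <- apply(perms, 1, function(p) spearmanClosedForm(x, x[p]))
  expect_equal(sr$p, mean(abs(rhos) >= abs(sr$rho) - 1e-12))
  expect_error(spearmanRho(1:9, 9:1, exact = TRUE), "n <= 8")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(15)
  y <- rnorm(15)
  base <- spearmanRho(x, y)$rho
  expect_equal(spearmanRho(exp(x), y)$rho, base)
  expect_equal(spearmanRho(x, atan(y) * 3 + 2)$rho, base)
})

test_that("gene sets below 3 usable genes are skipped with a reason", {
  prof <- function(sp) {
    m <- matrix(rnorm(12), 6, 2,
                dimnames = list(paste0("g", 1:6), c("Exc", "Inh")))
    new("ClassProfile", species = sp, profile = m,
        nSubclasses = c(Exc = 2L, Inh = 2L), collapse = "mean")
  }
  sets <- list(ok = paste0("g", 1:4), tiny = c("g1", "g2"),
               missing = c("g1", "g2", "zz1", "zz2"))
  rec <- genesetCorrelations(list(a = prof("a"), b = prof("b")), sets)
  expect_setequal(unique(rec$set_id), "ok")
  skipped <- attr(rec, "skipped")
  expect_setequal(skipped$set_id, c("tiny", "missing"))
  expect_equal(rec$n_dropped[1], 0)
})

test_that("kruskal-wallis H matches the hand-computed example", {
  cmp <- compareRhoDistributions(c(1, 2, 3, 4, 5, 6),
                                 rep(c("a", "b"), each = 3))
  expect_equal(cmp$H, 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(cmp$H, 3.857142857, tolerance = 1e-8)
})

test_that("identical groups give H = 0", {
  cmp <- compareRhoDistributions(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))
  expect_equal(cmp$H, 0, tolerance = 1e-12)
})

test_that("H with ties matches stats::kruskal.test on random data", {
  set.seed(4)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    values <- round(rnorm(20 * k), sample(0:1, 1))
    groups <- rep(paste0("g", seq_len(k)), each = 20)
    cmp <- compareRhoDistributions(values, groups)
    ref <- kruskal.test(values, factor(groups))
    expect_equal(cmp$H, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(cmp$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("dunn flags the shifted group most strongly", {
  set.seed(5)
  values <- c(rnorm(15), rnorm(15), rnorm(15, mean = 4))
  groups <- rep(c("a", "b", "shifted"), each = 15)
  cmp <- compareRhoDistributions(values, groups)
  d <- cmp$dunn
  expect_true(all(diag(d) == 1))
  expect_equal(d, t(d))
  expect_lt(max(d["shifted", c("a", "b")]), d["a", "b"])
  expect_true(all(d >= 0 & d <= 1))
  expect_error(compareRhoDistributions(1:3, c("a", "a", "b")),
               "at least 2 values")
})

test_that("top residual genes rank by distance to the OLS line", {
  m <- function(v) matrix(v, 4, 1, dimnames = list(paste0("g", 1:4), "Exc"))
  pa <- new("ClassProfile", species = "a", profile = m(c(0, 1, 2, 3)),
            nSubclasses = c(Exc = 1L), collapse = "mean")
  pb <- new("ClassProfile", species = "b", profile = m(c(0, 1, 2, 0)),
            nSubclasses = c(Exc = 1L), collapse = "mean")
  top <- topResidualGenes(pa, pb, paste0("g", 1:4), "Exc", k = 3)
  # independent oracle: stats::lm residuals on the same points
  res <- residuals(lm(c(0, 1, 2, 0) ~ c(0, 1, 2, 3)))
  expect_equal(top$gene_id, paste0("g", order(-abs(res)))[1:3])
  expect_equal(top$abs_distance, sort(abs(res), decreasing = TRUE)[1:3],
               tolerance = 1e-12, ignore_attr = TRUE)
  # perfectly collinear profiles: all residuals zero, lexicographic order
  pc <- new("ClassProfile", species = "c", profile = m(c(1, 3, 5, 7)),
            nSubclasses = c(Exc = 1L), collapse = "mean")
  col <- topResidualGenes(pa, pc, paste0("g", 1:4), "Exc", k = 10)
  expect_equal(max(abs(col$abs_distance)), 0, tolerance = 1e-12)
  expect_equal(col$gene_id, paste0("g", 1:4))
  expect_equal(nrow(col), 4)  # k beyond the set returns the whole set
  # degenerate fit
  pd <- new("ClassProfile", species = "d", profile = m(rep(2, 4)),
            nSubclasses = c(Exc = 1L), collapse = "mean")
  expect_error(topResidualGenes(pd, pb, paste0("g", 1:4), "Exc"),
               "degenerate")
})

test_that("fold-change flagging handles thresholds and degenerate zeros", {
  a <- c(g1 = 10, g2 = 5, g3 = 0)
  b <- c(g1 = 4, g2 = 5, g3 = 0)
  fc <- foldChangeGenes(a, b, threshold = 2, pseudocount = 0)
  expect_equal(fc$fold_change[fc$gene_id == "g1"], 2.5)
  expect_equal(fc$direction[fc$gene_id == "g1"], "higher_in_a")
  expect_false(fc$flagged[fc$gene_id == "g2"])
  fc1 <- foldChangeGenes(a, b, pseudocount = 1)
  expect_equal(fc1$fold_change[fc1$gene_id == "g3"], 1)
  expect_false(fc1$flagged[fc1$gene_id == "g3"])
  expect_error(foldChangeGenes(c(g1 = -1), c(g1 = 2)), ">= 0")
})

test_that("a set with class-specific divergence decorrelates that class", {
  div <- data.frame(class = c("Exc", "Inh"), species_a = "human",
                    species_b = "macaque", set_id = "set001",
                    sigma = c(1.2, 0.2))
  sim <- smallSim(seed = 8, divergence = div)
  res <- divergencePipeline(sim$species, sim$orthology, sim$gene_sets,
                            classes = c("Exc", "Inh"), compare = FALSE)
  rec <- res$records[res$records$set_id == "set001", ]
  expect_lt(rec$rho[rec$class == "Exc"], rec$rho[rec$class == "Inh"])
})
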