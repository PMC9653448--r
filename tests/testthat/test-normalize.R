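test_that("cp10k normalization matches the defining formula", {
  m <- matrix(c(2, 3, 5), 3, dimnames = list(paste0("g", 1:3), "c1"))
  expect_equal(unname(normalizeCP10K(m)[, 1]), c(2000, 3000, 5000))

  single <- matrix(c(0, 7, 0), 3, dimnames = list(paste0("g", 1:3), "c1"))
  expect_equal(unname(normalizeCP10K(single)[, 1]), c(0, 10000, 0))
})

test_that("cp10k cell totals equal the scale factor", {
  set.seed(42)
  m <- matrix(rpois(600, 5), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
  nc <- normalizeCP10K(m)
  expect_lt(max(abs(colSums(nc) - 10000)), 1e-6)
  # sparse input takes the sparse code path
  ncs <- normalizeCP10K(as(m, "CsparseMatrix"))
  expect_lt(max(abs(Matrix::colSums(ncs) - 10000)), 1e-6)
  expect_equal(as.matrix(ncs), nc)
})

test_that("zero-total cells error unless dropped", {
  m <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("g1", "g2"),
                                                c("c1", "c2")))
  expect_error(normalizeCP10K(m), "zero total")
  dropped <- normalizeCP10K(m, dropZero = TRUE)
  expect_equal(colnames(dropped), "c1")
})

test_that("log transform is log2(NC + 1)", {
  nc <- matrix(c(0, 1, 10), 3, dimnames = list(paste0("g", 1:3), "c1"))
  lg <- logTransform(nc)
  expect_equal(unname(lg[, 1]), c(0, 1, log2(11)))
})

test_that("per-gene z-scores use the population standard deviation", {
  lg <- matrix(c(1, 2, 3), 1, 3,
               dimnames = list("g1", paste0("c", 1:3)))
  z <- zscoreGenes(lg)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  # sample-sd variant divides by n - 1
  z2 <- zscoreGenes(lg, denominator = "sample")
  expect_equal(unname(z2[1, ]), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("constant genes z-score to zero and others to mean 0 variance 1", {
  set.seed(9)
  lg <- rbind(matrix(runif(50), 5, 10), const = rep(3, 10))
  rownames(lg) <- c(paste0("g", 1:5), "const")
  colnames(lg) <- paste0("c", 1:10)
  z <- zscoreGenes(lg)
  expect_equal(unname(z["const", ]), rep(0, 10))
  expect_lt(max(abs(rowMeans(z))), 1e-8)
  expect_equal(unname(rowMeans(z[1:5, ]^2)), rep(1, 5), tolerance = 1e-12)
})

test_that("the full normalize-log-zscore chain centers every gene", {
  sim <- smallSim(seed = 4)
  sce <- zscoreGenes(logTransform(normalizeCP10K(sim$species$human)))
  z <- SummarizedExperiment::assay(sce, "zscore")
  expect_lt(max(abs(rowMeans(z))), 1e-8)
  expect_error(logTransform(sim$species$human), "cp10k")
  expect_error(zscoreGenes(sim$species$human), "logcounts")
})

test_that("HVG selection returns up to n genes, most variable first", {
  set.seed(5)
  lg <- matrix(rnorm(200, sd = 0.01), 10, 20,
               dimnames = list(paste0("g", sprintf("%02d", 1:10)),
                               paste0("c", 1:20)))
  lg["g03", ] <- rnorm(20, mean = 5, sd = 10)
  expect_equal(length(selectHVG(lg, n = 2000)), 10)
  expect_equal(selectHVG(lg, n = 1), "g03")

  shuffled <- lg[sample(nrow(lg)), ]
  expect_setequal(selectHVG(lg, n = 5), selectHVG(shuffled, n = 5))
})

test_that("per-cluster subsampling caps cluster sizes deterministically", {
  sim <- smallSim(seed = 2)
  sce <- sim$species$human
  sub <- subsamplePerCluster(sce, "subclass", n = 15, seed = 10)
  expect_true(all(table(sub$subclass) == 15))
  sub_again <- subsamplePerCluster(sce, "subclass", n = 15, seed = 10)
  expect_identical(colnames(sub), colnames(sub_again))
  # clusters below the cap are kept whole
  all_kept <- subsamplePerCluster(sce, "subclass", n = 500, seed = 10)
  expect_equal(ncol(all_kept), ncol(sce))
  # no orphan cells: annotation rows track the retained columns
  expect_identical(rownames(SummarizedExperiment::colData(sub)),
                   colnames(sub))
  expect_error(subsamplePerCluster(sce, "nope", n = 5), "cluster_key")
})
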