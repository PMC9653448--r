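test_that("overlap matches the min-sum of proportions by hand", {
  members <- data.frame(
    cell_id = paste0("c", 1:20),
    species = rep(c("A", "B"), each = 10),
    native_cluster = "x",
    joint_cluster = c(rep("h1", 6), rep("h2", 4),
                      rep("h1", 5), rep("h2", 5)))
  m <- as.matrix(clusterOverlap(members, "A", "B"))
  expect_equal(m["x", "x"], 0.9)
})

test_that("identical proportion vectors give overlap 1, disjoint give 0", {
  members <- data.frame(
    cell_id = paste0("c", 1:12),
    species = rep(c("A", "B"), each = 6),
    native_cluster = rep(c("a1", "b1"), each = 6),
    joint_cluster = c("h1", "h1", "h2", "h2", "h3", "h3",
                      "h1", "h1", "h2", "h2", "h3", "h3"))
  expect_equal(as.matrix(clusterOverlap(members, "A", "B"))["a1", "b1"], 1)

  members$joint_cluster[7:12] <- "h9"
  expect_equal(as.matrix(clusterOverlap(members, "A", "B"))["a1", "b1"], 0)
})

test_that("one shared joint cluster makes every overlap 1", {
  members <- data.frame(
    cell_id = paste0("c", 1:30),
    species = rep(c("A", "B"), each = 15),
    native_cluster = rep(c("a1", "a2", "a3", "b1", "b2", "b3"), each = 5),
    joint_cluster = "all")
  m <- as.matrix(clusterOverlap(members, "A", "B"))
  expect_true(all(m == 1))
})

test_that("overlap is invariant to cell order and symmetric on transpose", {
  members <- randomMembership(100)
  m1 <- as.matrix(clusterOverlap(members, "A", "B"))
  m2 <- as.matrix(clusterOverlap(members[sample(nrow(members)), ], "A", "B"))
  expect_equal(m1, m2)
  m3 <- as.matrix(clusterOverlap(members, "B", "A"))
  expect_equal(m1, t(m3))
})

test_that("overlap equals one minus total-variation distance", {
  for (s in 1:20) {
    members <- randomMembership(s)
    m <- as.matrix(clusterOverlap(members, "A", "B"))
    joints <- sort(unique(members$joint_cluster))
    props <- function(sp, cl) {
      sub <- members[members$species == sp &
                       members$native_cluster == cl, ]
      table(factor(sub$joint_cluster, levels = joints)) / nrow(sub)
    }
    for (a in rownames(m)) {
      for (b in colnames(m)) {
        tv <- sum(abs(props("A", a) - props("B", b))) / 2
        expect_equal(m[a, b], 1 - tv, tolerance = 1e-12)
      }
    }
  }
})

test_that("overlap agrees with a brute-force per-cell tally", {
  for (s in 1:25) {
    members <- randomMembership(200 + s)
    fast <- as.matrix(clusterOverlap(members, "A", "B"))
    slow <- bruteForceOverlap(members, "A", "B")
    expect_lt(max(abs(fast - slow[rownames(fast), colnames(fast)])), 1e-12)
  }
})

test_that("membership validation rejects malformed tables", {
  members <- randomMembership(1)
  dup <- rbind(members, members[1, ])
  expect_error(clusterOverlap(dup, "A", "B"), "exactly once")
  expect_error(clusterOverlap(members, "A", "C"), "absent")
  bad <- members
  bad$joint_cluster[1] <- NA
  expect_error(clusterOverlap(bad, "A", "B"), "joint_cluster")
})

test_that("pipeline with true-subclass joint labels recovers identity", {
  sim <- smallSim(seed = 3)
  labels <- do.call(c, lapply(unname(sim$species), function(s)
    stats::setNames(as.character(s$subclass), colnames(s))))
  res <- homologyPipeline(sim$species, sim$orthology,
                          joint_labels = labels, seed = 1)
  m <- as.matrix(res$overlap)
  expect_equal(unname(diag(m)), rep(1, nrow(m)))
  expect_true(all(rownames(m)[apply(m, 1, which.max)] == rownames(m)))
  expect_equal(res$report$path, "external_joint_labels")
})

test_that("pipeline errors without labels or fallback, runs with fallback", {
  sim <- smallSim(seed = 5)
  expect_error(homologyPipeline(sim$species, sim$orthology),
               "fallback_k")
  res <- homologyPipeline(sim$species, sim$orthology, fallback_k = 10,
                          n_subsample = 30, seed = 2)
  expect_s4_class(res$overlap, "OverlapMatrix")
  expect_match(res$report$path, "fallback")
  m <- as.matrix(res$overlap)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("display ordering permutes but preserves overlap values", {
  members <- randomMembership(7)
  ov <- clusterOverlap(members, "A", "B")
  ord <- orderOverlap(ov)
  m1 <- as.matrix(ov)
  m2 <- as.matrix(ord)
  expect_setequal(rownames(m1), rownames(m2))
  expect_equal(m1[rownames(m2), colnames(m2)], m2)
})
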