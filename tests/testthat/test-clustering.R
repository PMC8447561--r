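test_that("Spearman profile distance matches hand-derived values", {
  z <- cbind(a = c(1, 2, 3, 4), b = c(8, 6, 4, 2), c = c(2, 1, 4, 3))
  rownames(z) <- paste0("f", 1:4)
  d <- spearmanDistance(z)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 2)          # perfectly anti-monotone
  z2 <- cbind(a = c(1, 2, 3), b = c(1, 3, 2))
  rownames(z2) <- paste0("f", 1:3)
  expect_equal(spearmanDistance(z2)["a", "b"], 0.5)  # rho = 0.5
})

test_that("distance matrix invariants hold on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    z <- matrix(rnorm(8 * 12), 8,
                dimnames = list(paste0("f", 1:8), paste0("P", 1:12)))
    d <- spearmanDistance(z)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 12))
    expect_true(all(d >= 0 & d <= 2))
  }
})

test_that("a flat profile is rejected with the patient named", {
  z <- cbind(P1 = c(1, 2, 3), P2 = c(5, 5, 5))
  rownames(z) <- paste0("f", 1:3)
  expect_error(spearmanDistance(z), "P2")
})

test_that("Ward linkage handles forced and degenerate merges", {
  d <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  tr <- wardLinkage(d)
  expect_equal(tr@height, 0.7)
  expect_equal(tr@size, 2L)
  # duplicate patients merge first at height zero
  z <- cbind(P1 = c(1, 2, 3), P2 = c(4, 1, 2), P3 = c(4, 1, 2),
             P4 = c(3, 1, 2))
  rownames(z) <- paste0("f", 1:3)
  tr2 <- wardLinkage(spearmanDistance(z))
  expect_equal(tr2@height[1], 0)
  expect_setequal(treeMembers(tr2)[[1]], c(2, 3))
  expect_error(wardLinkage(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("Ward linkage equals the naive re-scan oracle on random instances", {
  set.seed(37)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("P", 1:n), paste0("P", 1:n))
    mine <- wardLinkage(d)
    orac <- oracleWard(d)
    expect_equal(treeMembers(mine), orac$members)
    expect_equal(mine@height, orac$heights, tolerance = 1e-8)
  }
})

test_that("merge heights agree with hclust's Ward on generic input", {
  set.seed(41)
  d <- as.matrix(dist(matrix(rnorm(60), 20)))
  dimnames(d) <- list(paste0("P", 1:20), paste0("P", 1:20))
  mine <- wardLinkage(d)
  ref <- hclust(as.dist(d), method = "ward.D2")
  expect_equal(sort(mine@height), sort(ref$height), tolerance = 1e-10)
  # heights are monotone non-decreasing
  expect_true(!is.unsorted(mine@height))
})

test_that("tree cuts partition patients with first-appearance indexing", {
  set.seed(43)
  d <- as.matrix(dist(matrix(rnorm(24), 8)))
  dimnames(d) <- list(paste0("P", 1:8), paste0("P", 1:8))
  tr <- wardLinkage(d)
  a1 <- cutClusters(tr, 1)
  expect_equal(unique(a1@cluster), 1L)
  an <- cutClusters(tr, 8)
  expect_equal(sort(an@cluster), 1:8)
  a3 <- cutClusters(tr, 3)
  expect_equal(length(unique(a3@cluster)), 3)
  # indices appear in patient order
  expect_equal(a3@cluster[1], 1L)
  expect_true(all(diff(match(1:3, a3@cluster)) > 0))
  expect_error(cutClusters(tr, 9), "k must")
  expect_error(cutClusters(tr, 0), "k must")
})

test_that("a well-separated planted cohort is recovered at k = 2", {
  cfg <- plantedConfig(n = 100)
  sim <- generateCohort(cfg, seed = 47)
  res <- derivePhenotypes(sim$cohort)
  lab <- clusterLabels(res$assignment)
  expect_gte(ariScore(lab, sim$labels[names(lab)]), 0.9)
})

test_that("recovery strength increases with planted separation", {
  cfg <- defaultDerivationConfig(n = 150, missingRate = 0)
  ari <- sapply(c(0.5, 1.5, 2.5), function(f) {
    cc <- scaleSeparation(cfg, f)
    mean(sapply(1:3, function(s) {
      sim <- generateCohort(cc, seed = 500 + s)
      lab <- clusterLabels(derivePhenotypes(sim$cohort)$assignment)
      ariScore(lab, sim$labels[names(lab)])
    }))
  })
  expect_true(all(diff(ari) >= 0))
})

test_that("Calinski-Harabasz matches the hand-worked fixture", {
  z <- matrix(c(0, 1, 10, 11), 1, dimnames = list("f", paste0("P", 1:4)))
  expect_equal(calinskiHarabasz(z, c(1, 1, 2, 2)), 200)
  # perfectly compact duplicated clusters give the +Inf sentinel
  z2 <- matrix(c(0, 0, 5, 5), 1, dimnames = list("f", paste0("P", 1:4)))
  expect_warning(ch <- calinskiHarabasz(z2, c(1, 1, 2, 2)), "compact")
  expect_identical(ch, Inf)
  expect_error(calinskiHarabasz(z, rep(1, 4)), "k >= 2")
})

test_that("planted structure scores higher CH than random labels", {
  sim <- generateCohort(plantedConfig(n = 80, missingRate = 0), seed = 53)
  res <- derivePhenotypes(sim$cohort)
  chPlanted <- calinskiHarabasz(res$z, res$assignment)
  set.seed(54)
  chRandom <- mean(replicate(10, {
    calinskiHarabasz(res$z, sample(1:2, ncol(res$z), replace = TRUE))
  }))
  expect_gt(chPlanted, chRandom)
})

test_that("elbow curve is non-increasing and vanishes at k = n", {
  set.seed(59)
  z <- matrix(rnorm(3 * 12), 3,
              dimnames = list(paste0("f", 1:3), paste0("P", 1:12)))
  tr <- wardLinkage(spearmanDistance(z))
  q <- elbowCurve(z, tr, 1:12)
  expect_true(all(diff(q$withinSS) <= 1e-10))
  expect_equal(q$withinSS[q$k == 12], 0)
  expect_true(is.na(q$ch[q$k == 1]))
})

test_that("semantic labels anchor on the lower-median cluster", {
  m <- matrix(c(7, 6, 8, 26, 25, 27), 1,
              dimnames = list("hdl_c", paste0("P", 1:6)))
  x <- toyCohort(m)
  asg <- new("ClusterAssignment", patientIds = colnames(m),
             cluster = c(1L, 1L, 1L, 2L, 2L, 2L), k = 2L,
             labels = rep(NA_character_, 2))
  lab <- labelClusters(asg, x)
  expect_equal(unname(clusterLabels(lab)[c("P1", "P4")]),
               c("hypolipoprotein", "normolipoprotein"))
  expect_error(labelClusters(cutClusters(wardLinkage(
    spearmanDistance(matrix(rnorm(12), 3,
      dimnames = list(letters[1:3], paste0("P", 1:4))))), 3), x), "k = 2")
})

test_that("pipeline labelling is invariant to patient row order", {
  sim <- generateCohort(plantedConfig(n = 60), seed = 61)
  res1 <- derivePhenotypes(sim$cohort)
  set.seed(62)
  perm <- sample(ncol(sim$cohort))
  res2 <- derivePhenotypes(sim$cohort[, perm])
  l1 <- clusterLabels(res1$assignment)
  l2 <- clusterLabels(res2$assignment)
  expect_identical(l1[sort(names(l1))], l2[sort(names(l2))])
})

test_that("pair-counting ARI agrees with the mclust reference", {
  expect_equal(ariScore(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  skip_if_not_installed("mclust")
  set.seed(67)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(ariScore(a, b), mclust::adjustedRandIndex(a, b))
  }
})
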