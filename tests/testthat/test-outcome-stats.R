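test_that("test selection follows the cell-count and type rules", {
  df <- data.frame(g = rep(c("a", "b"), each = 10),
                   cont = c(1:10, 11:20) + 0.5,
                   cat = factor(c(rep("x", 3), rep("y", 7),
                                  rep("x", 8), rep("y", 2))))
  res <- groupCompare(df, "g", c("cont", "cat"), familySize = 47)
  expect_equal(res$test[res$variable == "cont"], "wilcoxon_rank_sum")
  # a 2x2 cell of 3 (< 5) triggers Fisher's exact test
  expect_equal(res$test[res$variable == "cat"], "fisher_exact")
  expect_equal(unique(res$threshold), 0.05 / 47)
  big <- data.frame(g = rep(c("a", "b"), each = 40),
                    cat = factor(rep(c("x", "y"), 40)))
  res2 <- groupCompare(big, "g", "cat")
  expect_equal(res2$test, "chi_square")
})

test_that("degenerate and identical-distribution variables give p = 1", {
  df <- data.frame(g = rep(c("a", "b"), each = 3),
                   same = c(1, 2, 3, 1, 2, 3),
                   const = rep(5, 6))
  expect_warning(res <- groupCompare(df, "g", c("same", "const")),
                 "degenerate")
  expect_equal(res$p[res$variable == "same"], 1)
  expect_equal(res$p[res$variable == "const"], 1)
})

test_that("the exact rank-sum branch matches full enumeration", {
  # canonical fixture: {1,2,3} vs {4,5,6} has one-sided tail 1/20
  df <- data.frame(g = rep(c("a", "b"), each = 3), v = c(1, 2, 3, 4, 5, 6))
  res <- groupCompare(df, "g", "v")
  expect_equal(res$p, 0.1)
  expect_equal(enumWilcoxP(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # random tie-free instances, both arms <= 8
  set.seed(103)
  for (i in 1:15) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- sample(100, n1 + n2)
    df <- data.frame(g = rep(c("a", "b"), c(n1, n2)), v = v)
    res <- groupCompare(df, "g", "v")
    expect_equal(res$p, enumWilcoxP(v[seq_len(n1)], v[-seq_len(n1)]),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation branches agree near crossover", {
  set.seed(107)
  v <- sample(1000, 50)  # 25 per arm, tie-free
  g <- rep(c("a", "b"), each = 25)
  pExact <- wilcox.test(v[g == "a"], v[g == "b"], exact = TRUE)$p.value
  pApprox <- wilcox.test(v[g == "a"], v[g == "b"], exact = FALSE,
                         correct = TRUE)$p.value
  expect_lt(abs(pExact - pApprox), 0.01)
})

test_that("Spearman matrices report rho, t-approximation p and pair n", {
  set.seed(109)
  m <- rbind(a = 1:10, b = 10:1, c = rnorm(10))
  colnames(m) <- paste0("P", 1:10)
  x <- toyCohort(m)
  sm <- spearmanMatrix(x, c("a", "b"), c("a", "b", "c"))
  expect_equal(sm$rho["a", "a"], 1)
  expect_equal(sm$rho["a", "b"], -1)
  expect_equal(sm$p["a", "b"], 0)
  expect_equal(sm$n["a", "c"], 10)
  # pairwise-complete handling and the n < 3 rule
  m2 <- m; m2["c", 1:8] <- NA
  x2 <- toyCohort(m2)
  sm2 <- spearmanMatrix(x2, "a", "c")
  expect_true(is.na(sm2$rho["a", "c"]))
  expect_equal(sm2$n["a", "c"], 2)
})

test_that("configured correlation signs are realized in synthetic cohorts", {
  sim <- generateCohort(defaultDerivationConfig(n = 600, missingRate = 0),
                        seed = 113)
  sm <- spearmanMatrix(sim$cohort, c("hdl_c", "triglycerides"), "icam1")
  expect_lt(sm$rho["hdl_c", "icam1"], 0)
  expect_gt(sm$rho["triglycerides", "icam1"], 0)
})

test_that("cluster-outcome percentages follow count/denominator arithmetic", {
  oc <- c(rep("rapid_recovery", 26), rep("cci", 23), rep("early_death", 9),
          rep("rapid_recovery", 33), rep("cci", 19), rep("early_death", 8))
  ids <- sprintf("P%03d", seq_along(oc))
  names(oc) <- ids
  asg <- new("ClusterAssignment", patientIds = ids,
             cluster = rep(1:2, c(58, 60)), k = 2L,
             labels = c("hypolipoprotein", "normolipoprotein"))
  tab <- clusterOutcomeTable(asg, oc)
  hy <- tab[tab$cluster == "hypolipoprotein", ]
  expect_equal(hy$pct, c(44.8, 39.7, 15.5))
  no <- tab[tab$cluster == "normolipoprotein", ]
  expect_equal(no$pct, c(55.0, 31.7, 13.3))
  for (cl in unique(tab$cluster))
    expect_lt(abs(sum(tab$pct[tab$cluster == cl]) - 100), 0.1)
  expect_error(clusterOutcomeTable(asg, oc[-1]), "without adjudicated")
})

test_that("AUC equals brute-force pair counting", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(127)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(round(rnorm(n), 1))  # induces ties
    expect_equal(rocAuc(s, y)$auc, bruteAuc(s, y))
  }
  expect_error(rocAuc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("ROC curves run from (0,0) to (1,1)", {
  set.seed(131)
  r <- rocAuc(rnorm(30), rbinom(30, 1, 0.5))
  expect_equal(unlist(r$points[1, c("fpr", "sensitivity")]),
               c(fpr = 0, sensitivity = 0))
  expect_equal(unlist(r$points[nrow(r$points), c("fpr", "sensitivity")]),
               c(fpr = 1, sensitivity = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
})

test_that("binary predictors give the 2-point ROC identity", {
  set.seed(137)
  y <- rbinom(40, 1, 0.4)
  b <- as.integer(xor(y == 1, runif(40) < 0.25))
  sens <- sum(b == 1 & y == 1) / sum(y == 1)
  spec <- sum(b == 0 & y == 0) / sum(y == 0)
  expect_equal(rocAuc(b, y)$auc, (sens + spec) / 2)
})

test_that("LASSO selection honours the penalty limits", {
  df <- simulateLassoCohort(n = 300, seed = 139)
  cand <- setdiff(names(df), "poor_outcome")
  # huge penalty: empty selection
  fitBig <- lassoSelect(df, cand, lambda = 10)
  expect_length(fitBig@selected, 0)
  expect_equal(nrow(fitBig@refit), 0)
  # zero penalty: coefficients match the unpenalized MLE
  fit0 <- suppressWarnings(lassoSelect(df, cand, lambda = 0))
  ref <- glm(poor_outcome ~ ., data = df, family = binomial())
  est <- setNames(fit0@refit$estimate, fit0@refit$variable)
  expect_equal(est[cand], coef(ref)[cand], tolerance = 1e-6)
})

test_that("selection shrinks as the penalty grows", {
  df <- simulateLassoCohort(n = 300, seed = 149, orPerSD = 0.3)
  cand <- setdiff(names(df), "poor_outcome")
  X <- as.matrix(df[cand]); y <- df$poor_outcome
  fit <- glmnet::glmnet(X, y, family = "binomial")
  sets <- apply(as.matrix(fit$beta) != 0, 2, which, simplify = FALSE)
  lam <- fit$lambda  # decreasing
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("a planted protective effect is selected and protective", {
  df <- simulateLassoCohort(n = 400, seed = 151, orPerSD = 0.2)
  fit <- lassoSelect(df, setdiff(names(df), "poor_outcome"),
                     nFolds = 10, seed = 151)
  expect_true("log_apoa1" %in% fit@selected)
  expect_lt(fit@refit$or[fit@refit$variable == "log_apoa1"], 1)
  expect_true(validObject(fit))
})

test_that("AUC comparison covers cluster, SOFA and APACHE II", {
  ids <- sprintf("P%02d", 1:40)
  oc <- setNames(rep(c("rapid_recovery", "cci"), each = 20), ids)
  asg <- new("ClusterAssignment", patientIds = ids,
             cluster = rep(c(2L, 1L), each = 20), k = 2L,
             labels = c("hypolipoprotein", "normolipoprotein"))
  sofa <- setNames(c(rnorm(20, 4), rnorm(20, 8)), ids)
  apache <- setNames(rnorm(40, 15), ids)
  res <- compareSignatureAuc(asg, sofa, apache, oc)
  expect_named(res, c("cluster", "sofa", "apache"))
  # cluster membership identical to outcome: AUC 1
  expect_equal(res$cluster$auc, 1)
})
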