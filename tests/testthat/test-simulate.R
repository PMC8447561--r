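test_that("default configurations satisfy their own invariants", {
  for (cfg in list(defaultDerivationConfig(), defaultReplicationConfig())) {
    expect_true(validObject(cfg))
    mu <- cfg@featureMeans
    # lower HDL-C location in the hypo phenotype
    expect_lt(mu["hypo", "hdl_c"], mu["normo", "hdl_c"])
    expect_lt(mu["hypo", "apoa1"], mu["normo", "apoa1"])
    expect_gt(mu["hypo", "icam1"], mu["normo", "icam1"])
    expect_equal(rowSums(cfg@outcomeProbs), c(hypo = 1, normo = 1))
  }
  # replication hypo outcome triple comes from the published counts
  expect_equal(unname(defaultReplicationConfig()@outcomeProbs["hypo", ]),
               c(12, 6, 8) / 26)
})

test_that("invalid configurations are rejected", {
  cfg <- defaultDerivationConfig()
  bad <- cfg
  bad@outcomeProbs["hypo", 1] <- bad@outcomeProbs["hypo", 1] + 1e-6
  expect_error(validObject(bad), "sum to 1")
  bad2 <- cfg
  bad2@correlation[1, 2] <- 0.9; bad2@correlation[2, 1] <- 0.9
  bad2@correlation[1, 3] <- 0.9; bad2@correlation[3, 1] <- 0.9
  bad2@correlation[2, 3] <- -0.9; bad2@correlation[3, 2] <- -0.9
  expect_error(validObject(bad2), "positive semidefinite")
  bad3 <- cfg
  bad3@missingRate <- 1
  expect_error(validObject(bad3), "missingRate")
})

test_that("n = 0 yields an empty cohort and empty labels", {
  cfg <- defaultDerivationConfig(n = 0)
  sim <- generateCohort(cfg)
  expect_equal(ncol(sim$cohort), 0)
  expect_length(sim$labels, 0)
})

test_that("the same seed reproduces the cohort byte-for-byte", {
  cfg <- defaultDerivationConfig(n = 30)
  d <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  runSimulate(cfg, d, seed = 5)
  runSimulate(cfg, d2, seed = 5)
  a <- readLines(file.path(d, "cohort.csv"))
  b <- readLines(file.path(d2, "cohort.csv"))
  expect_identical(a, b)
  runSimulate(cfg, d2, seed = 6)
  expect_false(identical(a, readLines(file.path(d2, "cohort.csv"))))
})

test_that("generated clinical fields re-adjudicate to the drawn outcome", {
  sim <- generateCohort(defaultDerivationConfig(n = 300), seed = 21)
  pd <- patientData(sim$cohort)
  re <- adjudicateOutcome(pd$icu_days, pd$disposition, pd$death_day,
                          pd$organ_dysfunction_at_day14)
  expect_identical(re, pd$outcome)
  # every early death is a 28-day death
  expect_true(all(pd$mortality_28d[pd$outcome == "early_death"]))
  # and 28-day deaths are 1-year deaths
  expect_true(all(pd$mortality_1y[pd$mortality_28d]))
})

test_that("marginal missingness converges to the configured rate", {
  rate <- 0.1
  sim <- generateCohort(defaultDerivationConfig(n = 500,
                                                missingRate = rate),
                        seed = 13)
  m <- featureMatrix(sim$cohort)
  m <- m[rownames(m) != "sofa_total", ]  # total SOFA is never masked
  draws <- length(m)
  phat <- mean(is.na(m))
  tol <- 3 * sqrt(rate * (1 - rate) / draws)
  expect_lt(abs(phat - rate), tol)
})

test_that("per-phenotype medians track the configured anchors within 15%", {
  cfg <- defaultDerivationConfig(n = 4000, missingRate = 0)
  sim <- generateCohort(cfg, seed = 17)
  m <- featureMatrix(sim$cohort)
  sch <- featureInfo(sim$cohort)
  logf <- sch$name[sch$transform == "log"]
  for (ph in c("hypo", "normo")) {
    idx <- sim$labels == ph
    for (f in intersect(logf, signaturePanel())) {
      target <- exp(cfg@featureMeans[ph, f])
      expect_lt(abs(median(m[f, idx]) - target) / target, 0.15,
                label = sprintf("%s median, %s phenotype", f, ph))
    }
  }
})

test_that("latent correlations are recovered empirically", {
  cfg <- defaultDerivationConfig(n = 5000, missingRate = 0)
  sim <- generateCohort(cfg, seed = 19)
  m <- featureMatrix(sim$cohort)
  sch <- featureInfo(sim$cohort)
  plain <- setdiff(sch$name[sch$transform == "none"],
                   c("sofa_total", names(cfg@sofaThresholds),
                     names(cfg@binaryThresholds)))
  # conditional on phenotype: the config matrix is the within-phenotype
  # latent correlation
  idx <- sim$labels == "normo"
  emp <- cor(t(m[plain, idx]), method = "spearman")
  expect_lt(max(abs(emp - cfg@correlation[plain, plain])), 0.1)
})

test_that("phenotype-conditional outcome frequencies match the config", {
  cfg <- defaultDerivationConfig(n = 2000, missingRate = 0)
  sim <- generateCohort(cfg, seed = 23)
  pd <- patientData(sim$cohort)
  for (ph in c("hypo", "normo")) {
    idx <- sim$labels == ph
    emp <- table(factor(pd$outcome[idx], levels = colnames(cfg@outcomeProbs)))
    emp <- emp / sum(emp)
    tol <- 3 * sqrt(cfg@outcomeProbs[ph, ] *
                      (1 - cfg@outcomeProbs[ph, ]) / sum(idx))
    expect_true(all(abs(emp - cfg@outcomeProbs[ph, ]) < tol))
  }
})

test_that("separation scaling moves locations as specified", {
  cfg <- defaultDerivationConfig()
  c0 <- scaleSeparation(cfg, 0)
  expect_equal(c0@featureMeans["hypo", ], c0@featureMeans["normo", ])
  c2 <- scaleSeparation(cfg, 2)
  expect_equal(c2@featureMeans["hypo", ] - c2@featureMeans["normo", ],
               2 * (cfg@featureMeans["hypo", ] - cfg@featureMeans["normo", ]))
  expect_equal(unname(phenotypeSeparation(c2)),
               unname(2 * phenotypeSeparation(cfg)))
})
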