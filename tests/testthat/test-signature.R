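# small labelled two-cluster cohort for signature unit tests
mkLabelled <- function(values) {
  n <- ncol(values)
  x <- toyCohort(values, id = "sig")
  asg <- new("ClusterAssignment", patientIds = colnames(values),
             cluster = rep(1:2, each = n / 2), k = 2L,
             labels = c("hypolipoprotein", "normolipoprotein"))
  list(x = x, asg = asg)
}

test_that("Welch t statistics match the hand-derived fixture", {
  m <- rbind(f1 = c(0, 1, 2, 10, 11, 12),
             f2 = c(5, 6, 7, 5, 6, 7))
  colnames(m) <- paste0("P", 1:6)
  mk <- mkLabelled(m)
  sig <- deriveSignature(mk$x, mk$asg, c("f1", "f2"), anchor = "f1")
  st <- signatureStats(sig)
  expect_equal(st$t[st$feature == "f1"], -12.24745, tolerance = 1e-6)
  expect_lt(st$p[st$feature == "f1"], 0.001)
  expect_true(st$tier[st$feature == "f1"] %in% c("p<0.05", "p<0.0001"))
  expect_equal(st$direction[st$feature == "f1"], 1)  # normo > hypo
  # identical per-cluster values: t = 0, p = 1, not significant
  expect_equal(st$t[st$feature == "f2"], 0)
  expect_equal(st$p[st$feature == "f2"], 1)
  expect_equal(st$tier[st$feature == "f2"], "not_significant")
  expect_equal(st$direction[st$feature == "f2"], 0)
})

test_that("t statistics are invariant to per-feature affine rescaling", {
  set.seed(71)
  m <- rbind(f1 = c(rnorm(6, 0), rnorm(6, 2)), f2 = rnorm(12))
  colnames(m) <- paste0("P", 1:12)
  mk1 <- mkLabelled(m)
  m2 <- m * c(100, 0.01) + c(-5, 300)
  mk2 <- mkLabelled(m2)
  for (variant in c("welch", "student")) {
    s1 <- signatureStats(deriveSignature(mk1$x, mk1$asg, c("f1", "f2"),
                                         testVariant = variant,
                                         anchor = "f1"))
    s2 <- signatureStats(deriveSignature(mk2$x, mk2$asg, c("f1", "f2"),
                                         testVariant = variant,
                                         anchor = "f1"))
    expect_equal(s1$t, s2$t, tolerance = 1e-10)
    expect_equal(s1$p, s2$p, tolerance = 1e-10)
  }
})

test_that("significance tiers are nested", {
  sim <- generateCohort(plantedConfig(n = 120), seed = 73)
  res <- derivePhenotypes(sim$cohort)
  st <- signatureStats(res$signature)
  strict <- st$tier == "p<0.0001"
  expect_true(all(st$p[strict] < 1e-4))
  expect_true(all(st$p[st$tier == "p<0.05"] < 0.05))
  expect_true(all(st$p[st$tier == "not_significant"] >= 0.05))
  expect_true(all(selectedFeatures(res$signature) %in%
                    signatureFeatures(res$signature)))
})

test_that("feature ranking is by |t| with deterministic ties", {
  m <- rbind(big = c(0, 1, 2, 30, 31, 32), small = c(0, 1, 2, 3, 4, 5))
  colnames(m) <- paste0("P", 1:6)
  mk <- mkLabelled(m)
  sig <- deriveSignature(mk$x, mk$asg, c("small", "big"), anchor = "big")
  expect_equal(rankFeatures(sig), c("big", "small"))
  sig2 <- deriveSignature(mk$x, mk$asg, c("big", "small"), anchor = "big")
  expect_equal(rankFeatures(sig), rankFeatures(sig2))
})

test_that("the planted top-effect feature ranks first in most seeds", {
  # well-recovered planted structure with one dominant contrast planted
  # on a normal-scale feature (|t| on heavily amplified log-normal
  # features saturates with the multiplicative CV, so a raw-scale
  # feature gives the cleanest single-effect fixture)
  cfg <- scaleSeparation(plantedConfig(n = 120, missingRate = 0), 4,
                         features = "systolic_bp")
  hits <- sapply(1:10, function(s) {
    sim <- generateCohort(cfg, seed = 700 + s)
    res <- derivePhenotypes(sim$cohort)
    rankFeatures(res$signature)[1] == "systolic_bp"
  })
  expect_gte(sum(hits), 9)
})

test_that("signature JSON serialization round-trips losslessly", {
  sim <- generateCohort(defaultDerivationConfig(n = 50), seed = 79)
  res <- derivePhenotypes(sim$cohort)
  path <- file.path(tempdir(), "sig.json")
  writeSignature(res$signature, path)
  s2 <- readSignature(path)
  expect_identical(signatureStats(res$signature), signatureStats(s2))
  expect_identical(res$signature@scaler@mean, s2@scaler@mean)
  expect_identical(res$signature@scaler@sd, s2@scaler@sd)
  expect_identical(res$signature@scaler@median, s2@scaler@median)
  expect_identical(res$signature@anchor, s2@anchor)
})

test_that("self-projection reproduces the derivation labels exactly", {
  sim <- generateCohort(defaultDerivationConfig(n = 80), seed = 83)
  res <- derivePhenotypes(sim$cohort)
  proj <- projectReplication(sim$cohort, res$signature, cap = FALSE)
  a <- clusterLabels(res$assignment)
  b <- clusterLabels(proj@assignment)
  expect_identical(a[sort(names(a))], b[sort(names(b))])
})

test_that("projection applies the eligibility rule with recorded reasons", {
  sim <- generateCohort(defaultDerivationConfig(n = 60, missingRate = 0),
                        seed = 89)
  res <- derivePhenotypes(sim$cohort, features = signaturePanel())
  m <- featureMatrix(sim$cohort)
  # patient P0001 loses 4 of the 15 signature features
  m[signaturePanel()[1:4], "P0001"] <- NA
  x2 <- sim$cohort
  SummarizedExperiment::assay(x2, "features") <- m
  proj <- projectReplication(x2, res$signature)
  expect_true("P0001" %in% proj@excluded$patient_id)
  expect_equal(proj@excluded$reason[proj@excluded$patient_id == "P0001"],
               "missing>20%")
  expect_false("P0001" %in% names(clusterLabels(proj@assignment)))
})

test_that("a signature cannot be projected onto an incompatible schema", {
  sim <- generateCohort(defaultDerivationConfig(n = 40), seed = 97)
  res <- derivePhenotypes(sim$cohort)
  small <- sim$cohort[1:5, ]
  expect_error(projectReplication(small, res$signature), "absent")
})

test_that("matched replication cohorts replicate the signature directions", {
  # "matched-generative": the replication cohort is drawn from the same
  # planted family as the derivation cohort, at replication size
  derCfg <- plantedConfig(n = 172)
  repCfg <- plantedConfig(n = 86)
  agree <- sapply(1:10, function(s) {
    simd <- generateCohort(derCfg, seed = 1100 + s)
    simr <- generateCohort(repCfg, seed = 2100 + s,
                           cohortIdentifier = "replication")
    res <- derivePhenotypes(simd$cohort, features = signaturePanel())
    proj <- projectReplication(simr$cohort, res$signature)
    conc <- signatureConcordance(res$signature, simr$cohort, proj)
    sum(conc$perFeature$agreement)
  })
  expect_true(all(agree >= 14))
})

test_that("concordance uses the exact Bonferroni quotient", {
  simd <- generateCohort(plantedConfig(n = 100), seed = 101)
  simr <- generateCohort(plantedConfig(n = 86), seed = 102)
  res <- derivePhenotypes(simd$cohort, features = signaturePanel())
  proj <- projectReplication(simr$cohort, res$signature)
  conc <- signatureConcordance(res$signature, simr$cohort, proj)
  expect_equal(conc$bonferroniThreshold, 0.05 / 15)
  expect_equal(nrow(conc$perFeature), 15)
})
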