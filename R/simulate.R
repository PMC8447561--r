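#' @include cohort.R clinical.R
NULL

## Features used throughout: snake_case schema names. The 15-feature
## signature set mirrors the cross-cohort comparison panel (lipids and
## lipoproteins, ICAM-1, the six SOFA components plus total, systolic BP,
## temperature).
.SIGNATURE15 <- c("total_cholesterol", "hdl_c", "ldl_c", "pon1_activity",
                  "apoa1", "icam1", "sofa_cardiovascular", "sofa_neurologic",
                  "sofa_coagulation", "sofa_hepatic", "sofa_renal",
                  "sofa_respiratory", "systolic_bp", "temperature",
                  "sofa_total")

.SOFA_COMPONENTS <- c("sofa_cardiovascular", "sofa_neurologic",
                      "sofa_coagulation", "sofa_hepatic", "sofa_renal",
                      "sofa_respiratory")

.BINARY_FEATURES <- c("mech_vent", "vasopressor", "statin")

.LIPOPROTEINS <- c("total_cholesterol", "hdl_c", "ldl_c", "pon1_activity",
                   "apoa1")

#' Standard feature panels
#'
#' \code{signaturePanel} is the default 15-feature signature set (lipids
#' and lipoproteins, ICAM-1, the six SOFA components plus total SOFA,
#' systolic blood pressure, temperature); \code{lipoproteinPanel} the
#' five protective lipoprotein measures defining the phenotype contrast;
#' \code{clusteringPanel} the default derivation clustering set --
#' lipids, clinical variables, endothelial and inflammatory biomarkers,
#' organ-failure severity and vital signs, i.e. the full default schema.
#'
#' @return character vector of schema feature names.
#' @export
signaturePanel <- function() .SIGNATURE15

#' @rdname signaturePanel
#' @export
lipoproteinPanel <- function() .LIPOPROTEINS

#' @rdname signaturePanel
#' @export
clusteringPanel <- function() .defaultSchema()$name

.defaultSchema <- function() {
    rbind(
        featureSchema(.LIPOPROTEINS, "lipid",
                      c("mg/dL", "mg/dL", "mg/dL", "nmol/min/ml", "ng/mL"),
                      transform = "log"),
        featureSchema(c("triglycerides", "hdl_inflammatory_index"), "lipid",
                      c("mg/dL", "index"), transform = "log"),
        featureSchema(c("icam1", "e_selectin"), "endothelial", "ng/mL",
                      transform = "log"),
        featureSchema(c("il6", "il8", "il10", "ip10", "mcp1", "tnfa"),
                      "inflammatory", "pg/mL", transform = "log"),
        featureSchema(.SOFA_COMPONENTS, "sofa_component", "score points"),
        featureSchema("sofa_total", "severity_score", "score points"),
        featureSchema("apache2", "severity_score", "score points"),
        featureSchema(c("lactate"), "clinical", "mmol/L", transform = "log"),
        featureSchema(c("charlson", "age"), "clinical",
                      c("score points", "years")),
        featureSchema(c("systolic_bp", "temperature"), "vital_sign",
                      c("mm Hg", "deg F")),
        featureSchema(.BINARY_FEATURES, "clinical", "0/1")
    )
}

## Per-phenotype median and quartile anchors for continuous features.
## Signature features take the published per-cluster summaries; remaining
## biomarkers use the whole-cohort summaries with poor-outcome-like levels
## in the hypo phenotype. Locations on the log scale are log(median)
## (median of a log-normal = exp(mu)); scales are IQR-based
## (sd = IQR/1.349 on the generation scale).
.derivationAnchors <- function() {
    A <- function(name, mh, q1h, q3h, mn, q1n, q3n)
        data.frame(name = name, medHypo = mh, q1Hypo = q1h, q3Hypo = q3h,
                   medNormo = mn, q1Normo = q1n, q3Normo = q3n)
    rbind(
        A("total_cholesterol", 67, 53, 84, 108, 81, 122),
        A("hdl_c", 7, 5, 16, 26, 16, 33),
        A("ldl_c", 30, 19, 44, 52, 36, 68),
        A("pon1_activity", 35.81, 22.4, 67.87, 65.99, 40.03, 114.6),
        A("apoa1", 754631, 583580, 952226, 1.4e6, 1.0e6, 1.625e6),
        A("icam1", 589.75, 455.82, 750.58, 346.502, 271.251, 485.513),
        A("systolic_bp", 97, 88.25, 114, 113, 100.5, 126.75),
        A("temperature", 98.6, 98.1, 99.8, 99.6, 98.6, 101.3),
        A("triglycerides", 125, 75, 159, 120, 84, 149),
        A("hdl_inflammatory_index", 2.2, 1.3, 3.2, 1.7, 1.2, 3.4),
        A("e_selectin", 58, 35, 90, 83, 51, 160),
        A("il6", 270, 75, 950, 152, 52, 361),
        A("il8", 120, 57, 300, 44, 23, 250),
        A("il10", 90, 45, 300, 64, 29, 161),
        A("ip10", 1200, 500, 2800, 981, 441, 2623),
        A("mcp1", 900, 550, 2000, 669, 441, 1397),
        A("tnfa", 80, 48, 140, 70, 40, 137),
        A("lactate", 2.6, 1.6, 4.2, 2.0, 1.5, 3.0),
        A("apache2", 19, 14, 24, 12, 8, 17),
        A("charlson", 4, 2, 6, 3, 1, 5),
        A("age", 62, 53, 72, 60, 49, 69)
    )
}

.replicationAnchors <- function() {
    a <- .derivationAnchors()
    repl <- data.frame(
        name = c("total_cholesterol", "hdl_c", "ldl_c", "pon1_activity",
                 "apoa1", "icam1", "systolic_bp", "temperature"),
        medHypo = c(87, 10, 41, 46.77, 475785, 649.15, 101, 99.0),
        q1Hypo  = c(70, 5, 29, 23.59, 185360, 516.80, 92, 97.6),
        q3Hypo  = c(102, 30, 68, 104.98, 763480, 929.30, 111, 100.2),
        medNormo = c(101, 34, 46, 89.42, 793130, 351.92, 108, 99.4),
        q1Normo  = c(82, 20, 35, 43.49, 658255, 222.79, 97, 98.4),
        q3Normo  = c(133, 46, 66, 128.59, 1030550, 384.97, 123, 100.5))
    i <- match(repl$name, a$name)
    a[i, ] <- repl
    ## overall higher severity of illness in the replication cohort
    j <- a$name %in% c("apache2", "lactate")
    a[j, c("medHypo", "q1Hypo", "q3Hypo", "medNormo", "q1Normo", "q3Normo")] <-
        a[j, c("medHypo", "q1Hypo", "q3Hypo",
               "medNormo", "q1Normo", "q3Normo")] * 1.2
    a
}

## Latent mean shifts for thresholded ordinal/binary features
## (cutpoints fixed; a score's median equals the number of cutpoints
## below the phenotype's latent mean).
.SOFA_CUTS <- c(0, 0.7, 1.5, 2.2)

.derivationLatentShifts <- function() {
    data.frame(
        name = c(.SOFA_COMPONENTS, .BINARY_FEATURES),
        hypo  = c(0.5, 1.0, -0.3, -0.4, 0.9, 0.9,
                  stats::qnorm(c(0.55, 0.60, 0.35))),
        normo = c(0.05, -0.3, -0.6, -1.2, 0.3, -0.1,
                  stats::qnorm(c(0.25, 0.25, 0.37))))
}

.replicationLatentShifts <- function() {
    data.frame(
        name = c(.SOFA_COMPONENTS, .BINARY_FEATURES),
        hypo  = c(1.0, -0.2, 0.4, 1.0, 0.4, 0.3,
                  stats::qnorm(c(0.60, 0.70, 0.35))),
        normo = c(0.4, 1.0, -0.5, -1.0, 0.5, 1.0,
                  stats::qnorm(c(0.45, 0.45, 0.37))))
}

## Sign-constrained latent correlation structure: lipoproteins correlate
## positively with one another and with blood pressure/temperature,
## negatively with endothelial, inflammatory and organ-failure features;
## triglycerides side with the endothelial/inflammatory block. The
## resulting pattern matrix is projected to the nearest correlation
## matrix (Matrix::nearPD) once, deterministically.
.buildCorrelation <- function(schema, rho = 0.4) {
    feats <- schema$name
    p <- length(feats)
    R <- diag(p)
    dimnames(R) <- list(feats, feats)
    set <- function(a, b, v) {
        a <- intersect(a, feats); b <- intersect(b, feats)
        R[a, b] <<- v; R[b, a] <<- v
    }
    lip <- .LIPOPROTEINS
    endo <- c("icam1", "e_selectin")
    infl <- c("il6", "il8", "il10", "ip10", "mcp1", "tnfa")
    sev <- c(.SOFA_COMPONENTS, "apache2", "lactate")
    set(lip, lip, rho)
    set(endo, endo, rho); set(infl, infl, rho); set(endo, infl, rho)
    set(lip, endo, -rho); set(lip, infl, -rho)
    set("triglycerides", endo, rho)
    set("triglycerides", infl, rho / 2)
    set("hdl_inflammatory_index", lip, -rho / 2)
    set("hdl_inflammatory_index", infl, rho * 0.75)
    set(sev, sev, rho * 0.75)
    set(sev, lip, -rho * 0.75)
    set(sev, c(endo, infl), rho * 0.75)
    set("systolic_bp", lip, rho * 0.75)
    set("systolic_bp", sev, -rho * 0.75)
    set("temperature", lip, rho / 2)
    set("temperature", sev, -rho / 2)
    set(c("mech_vent", "vasopressor"), sev, rho * 0.75)
    set(c("mech_vent", "vasopressor"), lip, -rho / 2)
    diag(R) <- 1
    R["sofa_total", ] <- 0; R[, "sofa_total"] <- 0; R["sofa_total", "sofa_total"] <- 1
    pd <- Matrix::nearPD(R, corr = TRUE, conv.tol = 1e-10)
    R <- as.matrix(pd$mat)
    dimnames(R) <- list(feats, feats)
    (R + t(R)) / 2
}

.IQR_TO_SD <- 2 * stats::qnorm(0.75)  # 1.349: IQR of a normal in SD units

.buildConfig <- function(n, prevalenceHypo, anchors, shifts, outcomeProbs,
                         mortality28Probs, missingRate, seed, rho = 0.4) {
    schema <- .defaultSchema()
    feats <- schema$name
    mu <- matrix(0, 2, length(feats),
                 dimnames = list(c("hypo", "normo"), feats))
    sds <- stats::setNames(rep(1, length(feats)), feats)
    for (i in seq_len(nrow(anchors))) {
        f <- anchors$name[i]
        lg <- schema$transform[schema$name == f] == "log"
        loc <- function(x) if (lg) log(x) else x
        mu["hypo", f] <- loc(anchors$medHypo[i])
        mu["normo", f] <- loc(anchors$medNormo[i])
        sds[f] <- mean(c(loc(anchors$q3Hypo[i]) - loc(anchors$q1Hypo[i]),
                         loc(anchors$q3Normo[i]) - loc(anchors$q1Normo[i]))) /
            .IQR_TO_SD
    }
    for (i in seq_len(nrow(shifts))) {
        f <- shifts$name[i]
        mu["hypo", f] <- shifts$hypo[i]
        mu["normo", f] <- shifts$normo[i]
    }
    outcomeProbs <- outcomeProbs / rowSums(outcomeProbs)
    new("SimulationConfig", n = as.integer(n),
        prevalenceHypo = prevalenceHypo, schema = schema,
        featureMeans = mu, featureSds = sds,
        correlation = .buildCorrelation(schema, rho),
        sofaThresholds = stats::setNames(
            rep(list(.SOFA_CUTS), length(.SOFA_COMPONENTS)),
            .SOFA_COMPONENTS),
        binaryThresholds = stats::setNames(numeric(length(.BINARY_FEATURES)),
                                           .BINARY_FEATURES),
        outcomeProbs = outcomeProbs, mortality28Probs = mortality28Probs,
        missingRate = missingRate, seed = as.integer(seed))
}

#' Default simulation configurations
#'
#' \code{defaultDerivationConfig} encodes the derivation-cohort study
#' conditions: n = 172 with Hypolipoprotein prevalence 58/168,
#' per-phenotype log-normal biomarker locations anchored to the published
#' per-cluster medians and quartiles, ordinal SOFA components thresholded
#' from a latent severity correlated with the biomarker block, and
#' phenotype-conditional outcome probabilities taken from the published
#' outcome counts (hypo: 26/58, 23/58, 9/58; normo: 87/110, 16/110,
#' 7/110 for rapid recovery / CCI / early death).
#' \code{defaultReplicationConfig} encodes the higher-severity replication
#' cohort: n = 86, prevalence 26/86, replication-cluster anchors and
#' outcome probabilities (hypo: 12/26, 6/26, 8/26; normo: 33/60, 19/60,
#' 8/60).
#'
#' @param n cohort size.
#' @param missingRate MCAR per-cell missingness probability.
#' @param seed RNG seed stored in the config.
#' @return a \linkS4class{SimulationConfig}.
#' @export
defaultDerivationConfig <- function(n = 172, missingRate = 0.05,
                                    seed = 20160001) {
    .buildConfig(n, 58 / 168, .derivationAnchors(),
                 .derivationLatentShifts(),
                 matrix(c(26, 23, 9, 87, 16, 7) / c(58, 58, 58, 110, 110, 110),
                        2, 3, byrow = TRUE,
                        dimnames = list(c("hypo", "normo"), .OUTCOMES)),
                 stats::setNames(c(14 / 58, 19 / 110), c("hypo", "normo")),
                 missingRate, seed)
}

#' @rdname defaultDerivationConfig
#' @export
defaultReplicationConfig <- function(n = 86, missingRate = 0.05,
                                     seed = 20170001) {
    .buildConfig(n, 26 / 86, .replicationAnchors(),
                 .replicationLatentShifts(),
                 matrix(c(12, 6, 8, 33, 19, 8) / c(26, 26, 26, 60, 60, 60),
                        2, 3, byrow = TRUE,
                        dimnames = list(c("hypo", "normo"), .OUTCOMES)),
                 stats::setNames(c(11 / 26, 17 / 60), c("hypo", "normo")),
                 missingRate, seed)
}

#' Rescale the between-phenotype separation of a configuration
#'
#' Moves each phenotype's location away from (factor > 1) or towards
#' (factor < 1) the mid-point between phenotypes; \code{factor = 0}
#' removes all planted structure (useful as a null model).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param factor non-negative multiplier on the phenotype contrast.
#' @param features features to rescale (default: all).
#' @return the modified configuration.
#' @export
scaleSeparation <- function(config, factor, features = NULL) {
    mu <- config@featureMeans
    if (is.null(features)) features <- colnames(mu)
    mid <- colMeans(mu[, features, drop = FALSE])
    for (ph in c("hypo", "normo"))
        mu[ph, features] <- mid + factor * (mu[ph, features] - mid)
    config@featureMeans <- mu
    validObject(config)
    config
}

#' Standardized per-feature phenotype separation
#'
#' |mu_hypo - mu_normo| / sd on the generation scale, per feature.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return named numeric vector.
#' @export
phenotypeSeparation <- function(config) {
    d <- abs(config@featureMeans["hypo", ] - config@featureMeans["normo", ])
    sd <- config@featureSds
    stats::setNames(ifelse(sd > 0, d / sd, 0), colnames(config@featureMeans))
}

#' Generate a synthetic sepsis cohort with planted phenotype structure
#'
#' Patients are assigned a latent phenotype (hypo/normo) by a Bernoulli
#' draw; a shared latent Gaussian vector with the configured correlation
#' matrix is drawn per patient and shifted by the phenotype's feature
#' means. Features with \code{transform = "log"} are exponentiated
#' (log-normal biomarkers); SOFA components are obtained by thresholding
#' their latent at the configured cutpoints (ordinal 0-4, total SOFA is
#' the component sum); binary clinical covariates by thresholding at the
#' configured cutpoint. Outcomes are drawn from the phenotype-conditional
#' probability triple, and the clinical fields (ICU days, death day,
#' disposition, day-14 organ dysfunction) are synthesized so that
#' [adjudicateOutcome()] reproduces the drawn label. 28-day mortality is
#' TRUE for all early deaths and drawn for the remainder so the marginal
#' per-phenotype rate matches the configured probability. Cells are
#' finally masked missing i.i.d. at the configured rate (total SOFA and
#' the fields needed for adjudication are never masked). Fully
#' reproducible given the seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed overrides \code{config@seed} when given.
#' @param cohortIdentifier cohort tag for the generated cohort.
#' @return a list with elements \code{cohort} (a
#'   \linkS4class{SepsisCohort} with drawn outcomes filled in) and
#'   \code{labels} (per-patient latent phenotype, \code{"hypo"} /
#'   \code{"normo"}).
#' @export
generateCohort <- function(config, seed = NULL,
                           cohortIdentifier = "synthetic") {
    validObject(config)
    if (is.null(seed)) seed <- config@seed
    set.seed(as.integer(seed))
    n <- config@n
    schema <- config@schema
    feats <- schema$name
    p <- length(feats)
    labels <- if (n > 0)
        ifelse(stats::runif(n) < config@prevalenceHypo, "hypo", "normo")
    else character(0)
    ch <- chol(config@correlation + diag(1e-8, p))
    Z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    colnames(Z) <- feats
    X <- config@featureMeans[labels, , drop = FALSE] +
        Z * rep(config@featureSds, each = n)
    vals <- X
    lg <- feats[schema$transform == "log"]
    vals[, lg] <- exp(X[, lg, drop = FALSE])
    for (f in names(config@sofaThresholds))
        vals[, f] <- findInterval(X[, f], config@sofaThresholds[[f]])
    for (f in names(config@binaryThresholds))
        vals[, f] <- as.numeric(X[, f] > config@binaryThresholds[f])
    if ("sofa_total" %in% feats)
        vals[, "sofa_total"] <-
            rowSums(vals[, .SOFA_COMPONENTS, drop = FALSE])
    ## outcomes and consistent clinical fields
    outcome <- character(n)
    icu <- integer(n); dday <- rep(NA_integer_, n)
    dispo <- character(n); od <- rep(NA, n)
    for (i in seq_len(n)) {
        pr <- config@outcomeProbs[labels[i], ]
        outcome[i] <- sample(.OUTCOMES, 1, prob = pr)
        if (outcome[i] == "early_death") {
            dday[i] <- sample(1:14, 1)
            icu[i] <- dday[i]
            dispo[i] <- "died"
        } else if (outcome[i] == "cci") {
            if (stats::runif(1) < 0.7) {
                icu[i] <- sample(15:28, 1)
                od[i] <- TRUE
                dispo[i] <- sample(c("skilled_nursing", "ltac", "rehab"), 1)
            } else {
                icu[i] <- sample(5:14, 1)
                od[i] <- FALSE
                dispo[i] <- sample(c("ltac", "other_hospital", "hospice"), 1)
            }
        } else {
            icu[i] <- sample(0:10, 1)
            od[i] <- FALSE
            dispo[i] <- sample(c("home", "rehab", "skilled_nursing"), 1)
        }
    }
    early <- outcome == "early_death"
    m28 <- early
    for (ph in c("hypo", "normo")) {
        idx <- which(labels == ph & !early)
        pEarly <- config@outcomeProbs[ph, "early_death"]
        q <- (config@mortality28Probs[ph] - pEarly) / (1 - pEarly)
        q <- min(max(q, 0), 1)
        m28[idx] <- stats::runif(length(idx)) < q
    }
    m1y <- m28 | (stats::runif(n) < ifelse(outcome == "cci", 0.2, 0.05))
    ## MCAR masking (adjudication fields and total SOFA stay observed)
    if (config@missingRate > 0 && n > 0) {
        maskable <- setdiff(feats, "sofa_total")
        mask <- matrix(stats::runif(n * length(maskable)) < config@missingRate,
                       n, length(maskable))
        vals[, maskable][mask] <- NA
    }
    ids <- sprintf("P%04d", seq_len(n))
    m <- t(vals)
    dimnames(m) <- list(feats, ids)
    pd <- data.frame(icu_days = icu,
                     organ_dysfunction_at_day14 = od,
                     death_day = dday,
                     disposition = dispo,
                     mortality_28d = m28,
                     mortality_1y = m1y,
                     outcome = outcome,
                     row.names = ids,
                     stringsAsFactors = FALSE)
    if (n == 0)
        pd <- data.frame(icu_days = integer(0),
                         organ_dysfunction_at_day14 = logical(0),
                         death_day = integer(0),
                         disposition = character(0),
                         mortality_28d = logical(0),
                         mortality_1y = logical(0),
                         outcome = character(0))
    cohort <- SepsisCohort(m, schema, pd, cohortId = cohortIdentifier)
    list(cohort = cohort, labels = stats::setNames(labels, ids))
}

#' Simulate a prediction cohort with one planted protective effect
#'
#' Draws candidate predictors as standard normal variables (mildly
#' correlated noise block) and a binary poor-outcome indicator whose log
#' odds depend only on standardized log ApoA-I with the given odds ratio
#' per SD. Used to verify that LASSO selection recovers a known
#' generative effect.
#'
#' @param n patients.
#' @param seed RNG seed.
#' @param orPerSD odds ratio of poor outcome per SD of log ApoA-I
#'   (default 0.2, protective).
#' @param nNoise number of inert candidate predictors.
#' @param baseRate marginal poor-outcome probability at the average
#'   ApoA-I level.
#' @return data.frame with \code{log_apoa1}, noise columns
#'   \code{noise01..}, and binary \code{poor_outcome}.
#' @export
simulateLassoCohort <- function(n = 400, seed = 1, orPerSD = 0.2,
                                nNoise = 12, baseRate = 0.35) {
    set.seed(as.integer(seed))
    z <- stats::rnorm(n)
    shared <- stats::rnorm(n)
    noise <- sapply(seq_len(nNoise), function(j)
        0.3 * shared + sqrt(1 - 0.09) * stats::rnorm(n))
    colnames(noise) <- sprintf("noise%02d", seq_len(nNoise))
    eta <- stats::qlogis(baseRate) + log(orPerSD) * z
    y <- as.integer(stats::runif(n) < stats::plogis(eta))
    data.frame(log_apoa1 = z, noise, poor_outcome = y)
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: n = %d, P(hypo) = %.3f, %d features, seed %d\n",
                object@n, object@prevalenceHypo, nrow(object@schema),
                object@seed))
    cat(sprintf("  missingRate = %.3f; outcome probs (hypo): %s\n",
                object@missingRate,
                paste(sprintf("%s=%.3f", colnames(object@outcomeProbs),
                              object@outcomeProbs["hypo", ]), collapse = ", ")))
})
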