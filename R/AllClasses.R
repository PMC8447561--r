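#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.FEATURE_CATEGORIES <- c("lipid", "endothelial", "inflammatory",
                         "sofa_component", "vital_sign", "clinical",
                         "severity_score")

.DISPOSITIONS <- c("home", "rehab", "skilled_nursing", "ltac",
                   "other_hospital", "hospice", "died")

.OUTCOMES <- c("rapid_recovery", "cci", "early_death")

.OUTCOME_COLUMNS <- c("icu_days", "organ_dysfunction_at_day14", "death_day",
                      "disposition", "mortality_28d", "mortality_1y",
                      "outcome")

#' SepsisCohort: a cohort of septic patients with biomarker features
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one assay,
#' \code{"features"}, a numeric feature-by-patient matrix (\code{NA} =
#' missing measurement). \code{rowData} carries the feature schema
#' (\code{category}, \code{units}, \code{transform}, \code{required});
#' \code{colData} carries the clinical outcome fields
#' (\code{icu_days}, \code{organ_dysfunction_at_day14}, \code{death_day},
#' \code{disposition}, \code{mortality_28d}, \code{mortality_1y},
#' \code{outcome}); \code{metadata(x)$cohort_id} tags the cohort.
#'
#' @seealso [SepsisCohort()] for construction, [readCohort()] /
#'   [writeCohort()] for CSV round-tripping.
#' @export
setClass("SepsisCohort", contains = "SummarizedExperiment")

setValidity("SepsisCohort", function(object) {
    msg <- character()
    if (!("features" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'features' is required")
    m <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(m))
        msg <- c(msg, "assay 'features' must be numeric")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature names must be present and unique")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("category", "units", "transform", "required")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, paste("rowData must contain:",
                            paste(need, collapse = ", ")))
    } else {
        if (!all(rd$category %in% .FEATURE_CATEGORIES))
            msg <- c(msg, "unknown feature category in rowData$category")
        if (!all(rd$transform %in% c("none", "log")))
            msg <- c(msg, "rowData$transform must be 'none' or 'log'")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(.OUTCOME_COLUMNS %in% colnames(cd))) {
        msg <- c(msg, paste("colData must contain:",
                            paste(.OUTCOME_COLUMNS, collapse = ", ")))
    } else {
        if (any(!is.na(cd$icu_days) & cd$icu_days < 0))
            msg <- c(msg, "icu_days must be non-negative")
        bad <- !is.na(cd$disposition) & !(cd$disposition %in% .DISPOSITIONS)
        if (any(bad))
            msg <- c(msg, "unknown disposition value")
        dd <- !is.na(cd$death_day)
        if (any(dd & (is.na(cd$disposition) | cd$disposition != "died")))
            msg <- c(msg, "death_day present requires disposition 'died'")
        if (any(dd & cd$death_day < 1))
            msg <- c(msg, "death_day must be a positive day index")
        bad <- !is.na(cd$outcome) & !(cd$outcome %in% .OUTCOMES)
        if (any(bad))
            msg <- c(msg, "unknown outcome label")
    }
    if (is.null(S4Vectors::metadata(object)$cohort_id))
        msg <- c(msg, "metadata(x)$cohort_id is required")
    if (length(msg)) msg else TRUE
})

#' ScalerParams: fitted per-feature centering/scaling for signature transfer
#'
#' Stores the per-feature mean, standard deviation (denominator n-1) and
#' median fitted on a derivation cohort, together with the outlier cap (in
#' SD units) used when projecting a new cohort through a signature.
#'
#' @slot features character, the features covered (duplicate-free).
#' @slot mean,sd,median named numeric vectors over \code{features}.
#' @slot cap positive numeric(1), cap in SD units (3 = the replication
#'   protocol's three-standard-deviation cap).
#' @slot cohortId character(1), cohort the parameters were fitted on.
#' @export
setClass("ScalerParams",
    representation(features = "character", mean = "numeric", sd = "numeric",
                   median = "numeric", cap = "numeric",
                   cohortId = "character"))

setValidity("ScalerParams", function(object) {
    msg <- character()
    f <- object@features
    if (length(f) == 0L) msg <- c(msg, "feature list must be non-empty")
    if (anyDuplicated(f)) msg <- c(msg, "feature list must be duplicate-free")
    for (s in c("mean", "sd", "median")) {
        v <- slot(object, s)
        if (!identical(names(v), f))
            msg <- c(msg, sprintf("'%s' must be named exactly by features", s))
    }
    if (any(object@sd < 0)) msg <- c(msg, "sd must be >= 0")
    if (length(object@cap) != 1L || is.na(object@cap) || object@cap <= 0)
        msg <- c(msg, "cap must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: generative specification for synthetic sepsis cohorts
#'
#' Fully specifies a two-phenotype (Hypolipoprotein vs. Normolipoprotein)
#' synthetic cohort: per-phenotype feature locations on the latent scale,
#' a shared latent correlation matrix, threshold maps for ordinal SOFA
#' components and binary clinical covariates, phenotype-conditional outcome
#' probabilities, 28-day mortality probabilities, MCAR missingness and the
#' RNG seed. See [defaultDerivationConfig()] for the calibrated defaults.
#'
#' @slot n integer(1), cohort size (>= 0).
#' @slot prevalenceHypo numeric(1) in (0,1).
#' @slot schema data.frame feature schema (name, category, units, transform,
#'   required).
#' @slot featureMeans 2 x p matrix (rows \code{hypo}, \code{normo}):
#'   per-phenotype location on the generation scale -- log scale for
#'   \code{transform == "log"} features, raw scale for \code{"none"},
#'   latent N(0,1) shift for thresholded (SOFA/binary) features.
#' @slot featureSds length-p vector of scales on the same generation scale.
#' @slot correlation p x p latent correlation matrix (symmetric, unit
#'   diagonal, positive semidefinite).
#' @slot sofaThresholds named list; per SOFA component, 4 increasing latent
#'   cutpoints mapping the latent to an ordinal 0-4 score.
#' @slot binaryThresholds named numeric; latent cutpoint per binary feature.
#' @slot outcomeProbs 2 x 3 matrix (rows \code{hypo}/\code{normo}, columns
#'   \code{rapid_recovery}/\code{cci}/\code{early_death}), rows sum to 1.
#' @slot mortality28Probs named numeric(2), per-phenotype P(28-day death).
#' @slot missingRate numeric(1) in [0,1): MCAR cell-level missingness.
#' @slot seed integer(1).
#' @export
setClass("SimulationConfig",
    representation(n = "integer", prevalenceHypo = "numeric",
                   schema = "data.frame", featureMeans = "matrix",
                   featureSds = "numeric", correlation = "matrix",
                   sofaThresholds = "list", binaryThresholds = "numeric",
                   outcomeProbs = "matrix", mortality28Probs = "numeric",
                   missingRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    p <- nrow(object@schema)
    feats <- object@schema$name
    if (anyDuplicated(feats)) msg <- c(msg, "schema feature names must be unique")
    if (object@n < 0L) msg <- c(msg, "n must be >= 0")
    if (object@prevalenceHypo <= 0 || object@prevalenceHypo >= 1)
        msg <- c(msg, "prevalenceHypo must lie in (0,1)")
    if (!identical(dim(object@featureMeans), c(2L, p)) ||
        !identical(rownames(object@featureMeans), c("hypo", "normo")) ||
        !identical(colnames(object@featureMeans), feats))
        msg <- c(msg, "featureMeans must be a 2 x p matrix (hypo/normo x schema)")
    if (!identical(names(object@featureSds), feats))
        msg <- c(msg, "featureSds must be named by schema features")
    else if (any(object@featureSds < 0))
        msg <- c(msg, "featureSds must be >= 0")
    R <- object@correlation
    if (!identical(dim(R), c(p, p)))
        msg <- c(msg, "correlation must be p x p")
    else {
        if (max(abs(R - t(R))) > 1e-8)
            msg <- c(msg, "correlation must be symmetric")
        if (max(abs(diag(R) - 1)) > 1e-8)
            msg <- c(msg, "correlation must have unit diagonal")
        ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8)
            msg <- c(msg, "correlation must be positive semidefinite")
    }
    po <- object@outcomeProbs
    if (!identical(rownames(po), c("hypo", "normo")) ||
        !identical(colnames(po), .OUTCOMES))
        msg <- c(msg, "outcomeProbs must be hypo/normo x rapid_recovery/cci/early_death")
    else {
        if (any(po < 0)) msg <- c(msg, "outcome probabilities must be >= 0")
        if (any(abs(rowSums(po) - 1) > 1e-9))
            msg <- c(msg, "outcomeProbs rows must sum to 1 (tolerance 1e-9)")
    }
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0,1)")
    for (nm in names(object@sofaThresholds)) {
        cu <- object@sofaThresholds[[nm]]
        if (length(cu) != 4L || is.unsorted(cu, strictly = TRUE))
            msg <- c(msg, sprintf("sofaThresholds[['%s']] must be 4 increasing cutpoints", nm))
    }
    if (length(msg)) msg else TRUE
})

#' LinkageTree: agglomerative merge sequence
#'
#' The full Ward merge history in the standard \code{hclust} convention:
#' \code{merge} is an (n-1) x 2 matrix in which negative entries are leaf
#' (patient) indices and positive entries reference earlier merges;
#' \code{height} holds the merge heights (non-decreasing under Ward);
#' \code{size} the size of each merged cluster; \code{order} a leaf order
#' for dendrogram export; \code{labels} the patient ids.
#'
#' @seealso [wardLinkage()], [cutClusters()], [asHclust()]
#' @export
setClass("LinkageTree",
    representation(merge = "matrix", height = "numeric", size = "integer",
                   order = "integer", labels = "character"))

setValidity("LinkageTree", function(object) {
    msg <- character()
    n <- length(object@labels)
    if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L ||
        length(object@size) != n - 1L)
        msg <- c(msg, "merge/height/size must have n-1 entries")
    if (n >= 2L && object@size[n - 1L] != n)
        msg <- c(msg, "final merge must contain all leaves")
    if (is.unsorted(object@height + 1e-8))
        msg <- c(msg, "merge heights must be non-decreasing (monotone dendrogram)")
    if (!identical(sort(object@order), seq_len(n)))
        msg <- c(msg, "order must be a permutation of the leaves")
    if (length(msg)) msg else TRUE
})

#' ClusterAssignment: per-patient cluster membership
#'
#' Cluster indices for a k-cut of a \linkS4class{LinkageTree}; indices are
#' assigned by order of first patient appearance. For k = 2 the clusters
#' may additionally carry the semantic labels \code{hypolipoprotein} /
#' \code{normolipoprotein} (see [labelClusters()]).
#'
#' @slot patientIds character, patient ids in cohort order.
#' @slot cluster integer, per-patient cluster index in 1..k.
#' @slot k integer(1).
#' @slot labels character(k), per-cluster semantic label (\code{NA} until
#'   labelled; only defined for k = 2).
#' @export
setClass("ClusterAssignment",
    representation(patientIds = "character", cluster = "integer",
                   k = "integer", labels = "character"))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    k <- object@k
    if (length(object@cluster) != length(object@patientIds))
        msg <- c(msg, "cluster and patientIds must have equal length")
    if (length(object@cluster) &&
        !identical(sort(unique(object@cluster)), seq_len(k)))
        msg <- c(msg, "exactly k non-empty clusters required")
    if (length(object@labels) != k)
        msg <- c(msg, "labels must have length k")
    if (k != 2L && any(!is.na(object@labels)))
        msg <- c(msg, "semantic labels are defined only for k = 2")
    if (length(msg)) msg else TRUE
})

#' ClusterSignature: portable cluster signature with transfer parameters
#'
#' The derivation artifact shipped to replication cohorts: the tested
#' feature list with per-feature cluster means, t statistics, two-sided
#' p-values, significance tiers (\code{not_significant}, \code{p<0.05},
#' \code{p<0.0001}) and directions (sign of normo - hypo mean), plus the
#' \linkS4class{ScalerParams} fitted on the derivation cohort and the
#' anchor feature used for semantic labelling.
#'
#' @slot stats data.frame with columns feature, meanHypo, meanNormo, t, p,
#'   tier, direction.
#' @slot scaler \linkS4class{ScalerParams} fitted on the derivation cohort.
#' @slot cohortId character(1) derivation cohort id.
#' @slot anchor character(1) anchor feature for labelling (default HDL-C).
#' @slot testVariant character(1), \code{"welch"} or \code{"student"}.
#' @export
setClass("ClusterSignature",
    representation(stats = "data.frame", scaler = "ScalerParams",
                   cohortId = "character", anchor = "character",
                   testVariant = "character"))

setValidity("ClusterSignature", function(object) {
    msg <- character()
    st <- object@stats
    need <- c("feature", "meanHypo", "meanNormo", "t", "p", "tier",
              "direction")
    if (!all(need %in% colnames(st)))
        return(paste("stats must contain:", paste(need, collapse = ", ")))
    if (nrow(st) < 2L) msg <- c(msg, "a signature needs at least 2 features")
    if (anyDuplicated(st$feature)) msg <- c(msg, "duplicate feature in signature")
    if (!all(st$tier %in% c("not_significant", "p<0.05", "p<0.0001")))
        msg <- c(msg, "unknown significance tier")
    strict <- st$tier == "p<0.0001" & !is.na(st$p)
    if (any(st$p[strict] >= 0.05))
        msg <- c(msg, "tier nesting violated: p<0.0001 features must satisfy p<0.05")
    if (!all(st$direction %in% c(-1, 0, 1)))
        msg <- c(msg, "direction must be in {-1, 0, +1}")
    if (!object@testVariant %in% c("welch", "student"))
        msg <- c(msg, "testVariant must be 'welch' or 'student'")
    if (!all(st$feature %in% object@scaler@features))
        msg <- c(msg, "scaler must cover all signature features")
    if (length(msg)) msg else TRUE
})

#' ProjectionResult: a replication cohort projected through a signature
#'
#' @slot assignment labelled \linkS4class{ClusterAssignment} on the kept
#'   patients.
#' @slot excluded data.frame(patient_id, reason) for patients failing the
#'   missingness eligibility rule.
#' @slot imputedPerFeature named integer, imputed-cell count per feature.
#' @slot ch numeric(1), Calinski-Harabasz score of the 2-cut.
#' @export
setClass("ProjectionResult",
    representation(assignment = "ClusterAssignment", excluded = "data.frame",
                   imputedPerFeature = "integer", ch = "numeric"))

#' LassoFit: LASSO-selected logistic model of poor sepsis outcome
#'
#' Result of [lassoSelect()]: the candidate list, cross-validated penalty
#' path, selected variable set at the minimum-deviance lambda, and the
#' unpenalized logistic refit on the selected set reported as odds ratios
#' with 95% Wald confidence intervals.
#'
#' @slot candidates,selected character vectors (selected is a subset).
#' @slot lambda numeric(1), chosen penalty.
#' @slot path data.frame(lambda, df, cvDeviance).
#' @slot refit data.frame(variable, estimate, or, ciLow, ciHigh, p).
#' @slot nFolds,seed,n,events integers; cross-validation and data summary.
#' @slot separation logical(1), TRUE when the refit showed quasi-separation
#'   (confidence intervals unstable).
#' @export
setClass("LassoFit",
    representation(candidates = "character", selected = "character",
                   lambda = "numeric", path = "data.frame",
                   refit = "data.frame", nFolds = "integer",
                   seed = "integer", n = "integer", events = "integer",
                   separation = "logical"))

setValidity("LassoFit", function(object) {
    msg <- character()
    if (!all(object@selected %in% object@candidates))
        msg <- c(msg, "selected set must be a subset of candidates")
    if (nrow(object@refit) && any(object@refit$or <= 0, na.rm = TRUE))
        msg <- c(msg, "odds ratios must be positive")
    ok <- !is.na(object@refit$ciLow) & !is.na(object@refit$ciHigh)
    if (nrow(object@refit) &&
        any(object@refit$or[ok] < object@refit$ciLow[ok] |
            object@refit$or[ok] > object@refit$ciHigh[ok]))
        msg <- c(msg, "confidence intervals must contain the odds ratio")
    if (length(msg)) msg else TRUE
})
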