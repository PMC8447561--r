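#' @include clustering.R preprocess.R
NULL

.tTest2 <- function(a, b, variant) {
    ## two-sided t-test robust to degenerate (constant) groups
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) return(c(t = 0, p = 1))
        return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
    }
    tt <- stats::t.test(a, b, var.equal = (variant == "student"))
    c(t = unname(tt$statistic), p = tt$p.value)
}

#' Derive the per-feature cluster signature
#'
#' For each feature, a two-sided t-test (Welch by default) of the
#' difference of means between the Hypolipoprotein and Normolipoprotein
#' clusters. All tested features are retained and tiered
#' (\code{not_significant}, \code{p<0.05}, \code{p<0.0001}); the
#' "selected" subset ([selectedFeatures()]) is every feature at
#' p < 0.05. The signature embeds the scaling parameters
#' ([fitScaler()]: means, SDs, medians, cap) fitted on the derivation
#' cohort so it can be shipped and projected onto other cohorts.
#'
#' @param x the derivation \linkS4class{SepsisCohort}, imputed on
#'   \code{features}.
#' @param assignment a labelled k = 2 \linkS4class{ClusterAssignment}
#'   (see [labelClusters()]).
#' @param features features to test (default: the 15-feature panel).
#' @param testVariant \code{"welch"} (default) or \code{"student"}.
#' @param cap outlier cap (SD units) stored with the scaler.
#' @param anchor anchor feature recorded for downstream labelling.
#' @return a \linkS4class{ClusterSignature}.
#' @export
deriveSignature <- function(x, assignment, features = signaturePanel(),
                            testVariant = c("welch", "student"), cap = 3,
                            anchor = "hdl_c") {
    testVariant <- match.arg(testVariant)
    if (assignment@k != 2L || all(is.na(assignment@labels)))
        stop("a labelled k = 2 assignment is required")
    lab <- clusterLabels(assignment)
    if (min(table(lab)) < 2)
        stop("each cluster must contain at least 2 patients for the t-tests")
    m <- featureMatrix(x)[features, assignment@patientIds, drop = FALSE]
    if (anyNA(m)) stop("features must be imputed before signature derivation")
    hypo <- lab == "hypolipoprotein"
    rows <- lapply(features, function(f) {
        a <- m[f, hypo]; b <- m[f, !hypo]
        ts <- .tTest2(a, b, testVariant)
        mh <- mean(a); mn <- mean(b)
        tier <- if (ts["p"] < 1e-4) "p<0.0001"
                else if (ts["p"] < 0.05) "p<0.05" else "not_significant"
        data.frame(feature = f, meanHypo = mh, meanNormo = mn,
                   t = ts["t"], p = ts["p"], tier = tier,
                   direction = sign(mn - mh), row.names = NULL)
    })
    st <- do.call(rbind, rows)
    new("ClusterSignature", stats = st,
        scaler = fitScaler(x, features, cap = cap),
        cohortId = cohortId(x), anchor = anchor, testVariant = testVariant)
}

#' Rank signature features by discriminative strength
#'
#' Features ordered by |t| descending (ties broken alphabetically): the
#' top of the list are the features contributing most to cluster
#' discrimination.
#'
#' @param signature a \linkS4class{ClusterSignature}.
#' @return character vector of feature names, strongest first.
#' @export
rankFeatures <- function(signature) {
    st <- signature@stats
    st$feature[order(-abs(st$t), st$feature)]
}

#' Project an independent cohort through a derivation signature
#'
#' The replication protocol: extract the signature features, drop
#' patients missing more than 20% of them, impute remaining missing
#' values by feature medians (derivation medians by default), z-normalize
#' with the derivation means and scaling factors, cap outliers at the
#' stored cap (three SDs by default), then re-cluster with Spearman
#' distance and Ward linkage, extract the first two clusters and label
#' them by the anchor feature. Patients are processed in sorted
#' patient-id order so the result is invariant to input row order.
#'
#' @param x the replication \linkS4class{SepsisCohort}.
#' @param signature a \linkS4class{ClusterSignature}.
#' @param imputeSource \code{"derivation"} (default: the medians stored
#'   in the signature) or \code{"replication"} (the cohort's own
#'   medians).
#' @param cap logical, apply the stored outlier cap (default TRUE).
#' @param maxMissingFraction eligibility bound (default 0.20).
#' @return a \linkS4class{ProjectionResult}.
#' @export
projectReplication <- function(x, signature,
                               imputeSource = c("derivation", "replication"),
                               cap = TRUE, maxMissingFraction = 0.20) {
    imputeSource <- match.arg(imputeSource)
    feats <- signatureFeatures(signature)
    absent <- setdiff(feats, rownames(x))
    if (length(absent))
        stop("signature feature(s) entirely absent from cohort schema: ",
             paste(absent, collapse = ", "))
    x <- x[, order(colnames(x))]
    elig <- eligibilityFilter(x, feats, maxMissingFraction)
    if (ncol(elig$kept) < 4)
        stop("fewer than 4 eligible patients; cannot cluster")
    med <- if (imputeSource == "derivation") signature@scaler@median else NULL
    imp <- imputeMedian(elig$kept, feats, medians = med)
    z <- applyScaler(imp$cohort, signature@scaler, cap = cap)
    tree <- wardLinkage(spearmanDistance(z))
    asg <- labelClusters(cutClusters(tree, 2), imp$cohort,
                         anchor = signature@anchor)
    new("ProjectionResult", assignment = asg, excluded = elig$excluded,
        imputedPerFeature = as.integer(imp$report$perFeature),
        ch = calinskiHarabasz(z, asg))
}

#' Cross-cohort signature concordance
#'
#' Re-runs the per-feature two-sided t-tests between the projected
#' replication clusters, flags significance at the Bonferroni threshold
#' 0.05/|F|, and records per-feature direction agreement with the
#' derivation signature (agreement requires equal, nonzero directions).
#'
#' @param signature the derivation \linkS4class{ClusterSignature}.
#' @param x the replication \linkS4class{SepsisCohort}.
#' @param projection the \linkS4class{ProjectionResult} from
#'   [projectReplication()].
#' @param imputeSource as in [projectReplication()]; use the same value.
#' @return list with \code{perFeature} (data.frame: feature,
#'   derivationDirection, replicationDirection, agreement, p,
#'   significant), \code{bonferroniThreshold} (0.05/|F|) and
#'   \code{concordantFraction}.
#' @export
signatureConcordance <- function(signature, x, projection,
                                 imputeSource = c("derivation",
                                                  "replication")) {
    imputeSource <- match.arg(imputeSource)
    feats <- signatureFeatures(signature)
    lab <- clusterLabels(projection@assignment)
    if (min(table(lab)) < 2)
        stop("each replication cluster must contain at least 2 patients")
    med <- if (imputeSource == "derivation") signature@scaler@median else NULL
    imp <- imputeMedian(x[, names(lab)], feats, medians = med)
    m <- featureMatrix(imp$cohort)[feats, names(lab), drop = FALSE]
    hypo <- lab == "hypolipoprotein"
    thr <- 0.05 / length(feats)
    rows <- lapply(feats, function(f) {
        ts <- .tTest2(m[f, hypo], m[f, !hypo], signature@testVariant)
        dRep <- sign(mean(m[f, !hypo]) - mean(m[f, hypo]))
        dDer <- signature@stats$direction[signature@stats$feature == f]
        data.frame(feature = f, derivationDirection = dDer,
                   replicationDirection = dRep,
                   agreement = (dDer == dRep) && dDer != 0,
                   p = ts["p"], significant = ts["p"] < thr,
                   row.names = NULL)
    })
    pf <- do.call(rbind, rows)
    list(perFeature = pf, bonferroniThreshold = thr,
         concordantFraction = mean(pf$agreement))
}

#' Serialize / deserialize a signature as versioned JSON
#'
#' The JSON carries the tested features with statistics and tiers, the
#' embedded scaler (means, SDs, medians, cap), the derivation cohort id,
#' anchor and test variant; the round trip is lossless.
#'
#' @param signature a \linkS4class{ClusterSignature}.
#' @param path JSON file path.
#' @return \code{writeSignature} returns \code{path} invisibly;
#'   \code{readSignature} returns the \linkS4class{ClusterSignature}.
#' @export
writeSignature <- function(signature, path) {
    sc <- signature@scaler
    obj <- list(format = "LipoPheno-signature", version = 1L,
                cohort_id = signature@cohortId,
                anchor = signature@anchor,
                test_variant = signature@testVariant,
                stats = signature@stats,
                scaler = list(features = sc@features,
                              mean = unname(sc@mean), sd = unname(sc@sd),
                              median = unname(sc@median), cap = sc@cap,
                              cohort_id = sc@cohortId))
    ## I(17) significant digits: lossless double round trip
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "LipoPheno-signature"))
        stop("not a signature file: ", path)
    sc <- obj$scaler
    scaler <- new("ScalerParams", features = sc$features,
                  mean = stats::setNames(sc$mean, sc$features),
                  sd = stats::setNames(sc$sd, sc$features),
                  median = stats::setNames(sc$median, sc$features),
                  cap = sc$cap, cohortId = sc$cohort_id)
    st <- as.data.frame(obj$stats)
    for (cl in c("meanHypo", "meanNormo", "t", "p", "direction"))
        st[[cl]] <- as.numeric(st[[cl]])  # integral values parse as int
    new("ClusterSignature", stats = st, scaler = scaler,
        cohortId = obj$cohort_id, anchor = obj$anchor,
        testVariant = obj$test_variant)
}
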