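#' @include cohort.R
NULL

#' Median imputation with fit and transfer modes
#'
#' Replaces missing feature cells by per-feature medians. In fit mode
#' (\code{medians = NULL}) the table's own observed medians are used; in
#' transfer mode the supplied medians (typically those stored with a
#' derivation signature) are used. Observed cells are never altered, so
#' the operation is idempotent.
#'
#' @param x a \linkS4class{SepsisCohort}.
#' @param features features to impute (default: all).
#' @param medians optional named numeric vector covering \code{features}.
#' @return list with \code{cohort} (imputed) and \code{report}, a list
#'   holding \code{perFeature} and \code{perPatient} imputed-cell counts
#'   and the logical \code{mask} of imputed cells.
#' @export
imputeMedian <- function(x, features = rownames(x), medians = NULL) {
    m <- featureMatrix(x)
    if (!all(features %in% rownames(m)))
        stop("feature(s) not in schema: ",
             paste(setdiff(features, rownames(m)), collapse = ", "))
    if (!is.null(medians) && !all(features %in% names(medians)))
        stop("supplied medians must cover all requested features")
    sub <- m[features, , drop = FALSE]
    mask <- is.na(sub)
    fill <- if (is.null(medians)) {
        v <- apply(sub, 1, stats::median, na.rm = TRUE)
        if (any(is.na(v)))
            stop("feature(s) with all values missing and no supplied median: ",
                 paste(features[is.na(v)], collapse = ", "))
        v
    } else medians[features]
    sub[mask] <- rep(fill, ncol(sub))[mask]
    m[features, ] <- sub
    SummarizedExperiment::assay(x, "features") <- m
    list(cohort = x,
         report = list(perFeature = rowSums(mask),
                       perPatient = colSums(mask),
                       mask = mask))
}

#' Missingness eligibility rule
#'
#' Excludes patients missing strictly more than
#' \code{floor(maxMissingFraction * |features|)} of the given features;
#' with the 15-feature signature and the default 20% this excludes
#' patients missing more than 3 features.
#'
#' @param x a \linkS4class{SepsisCohort}.
#' @param features the feature panel the rule is evaluated on.
#' @param maxMissingFraction tolerated missing fraction (default 0.20).
#' @return list with \code{kept} (a subset \linkS4class{SepsisCohort})
#'   and \code{excluded}, a data.frame(patient_id, n_missing, reason).
#' @export
eligibilityFilter <- function(x, features = rownames(x),
                              maxMissingFraction = 0.20) {
    m <- featureMatrix(x)[features, , drop = FALSE]
    nMiss <- colSums(is.na(m))
    lim <- floor(maxMissingFraction * length(features) + 1e-9)
    drop <- nMiss > lim
    excluded <- data.frame(patient_id = colnames(m)[drop],
                           n_missing = unname(nMiss[drop]),
                           reason = rep(sprintf("missing>%.0f%%",
                                                100 * maxMissingFraction),
                                        sum(drop)),
                           stringsAsFactors = FALSE)
    list(kept = x[, !drop], excluded = excluded)
}

#' Fit per-feature scaling parameters
#'
#' Sample mean, standard deviation (denominator n-1) and median per
#' feature, plus the outlier cap, packaged for transfer to other cohorts.
#' Features must be imputed first (no missing values). A constant feature
#' gets sd 0 and a warning.
#'
#' @param x a \linkS4class{SepsisCohort} (imputed on \code{features}).
#' @param features feature panel.
#' @param cap cap in SD units stored with the parameters (default 3).
#' @return a \linkS4class{ScalerParams}.
#' @export
fitScaler <- function(x, features = rownames(x), cap = 3) {
    m <- featureMatrix(x)[features, , drop = FALSE]
    if (anyNA(m))
        stop("features must be imputed before fitting the scaler")
    if (ncol(m) < 2)
        stop("at least 2 patients required to fit a scaler")
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    if (any(sd == 0))
        warning("constant feature(s): ",
                paste(features[sd == 0], collapse = ", "),
                " (sd = 0; z-scores will be 0)")
    new("ScalerParams", features = features,
        mean = stats::setNames(mu, features),
        sd = stats::setNames(sd, features),
        median = stats::setNames(apply(m, 1, stats::median), features),
        cap = cap, cohortId = cohortId(x))
}

#' Apply fitted scaling (z-normalization with optional capping)
#'
#' z = (x - mean)/sd per feature with the supplied parameters; features
#' with sd 0 map to z = 0. With \code{cap = TRUE}, z-scores are clamped
#' to +-\code{params@cap} standard deviations (the replication protocol's
#' outlier treatment).
#'
#' @param x a \linkS4class{SepsisCohort} (imputed on the scaler features).
#' @param params a \linkS4class{ScalerParams}.
#' @param cap logical, apply the outlier cap.
#' @return numeric z-matrix, features x patients.
#' @export
applyScaler <- function(x, params, cap = FALSE) {
    absent <- setdiff(params@features, rownames(x))
    if (length(absent))
        stop("feature(s) absent from cohort: ",
             paste(absent, collapse = ", "))
    m <- featureMatrix(x)[params@features, , drop = FALSE]
    if (anyNA(m))
        stop("features must be imputed before scaling")
    sd <- params@sd
    z <- (m - params@mean) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    if (cap) z <- pmin(pmax(z, -params@cap), params@cap)
    z
}
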