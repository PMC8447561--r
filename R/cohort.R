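#' @include AllClasses.R AllGenerics.R
NULL

#' Build a feature schema
#'
#' A feature schema is a data.frame with one row per measured variable:
#' \code{name}, \code{category} (one of lipid, endothelial, inflammatory,
#' sofa_component, vital_sign, clinical, severity_score), \code{units},
#' \code{transform} (\code{"none"} or \code{"log"}; log is only allowed
#' for strictly positive measurements) and \code{required}.
#'
#' @param name character feature names (unique).
#' @param category character, recycled; see above for the allowed set.
#' @param units free-text units (mg/dL, pg/mL, score points, ...).
#' @param transform \code{"none"} or \code{"log"}, recycled.
#' @param required logical, recycled.
#' @return a data.frame schema.
#' @examples
#' featureSchema(c("HDL-C", "ICAM-1"), c("lipid", "endothelial"),
#'               c("mg/dL", "ng/mL"), transform = "log")
#' @export
featureSchema <- function(name, category, units = "",
                          transform = "none", required = FALSE) {
    if (anyDuplicated(name))
        stop("feature names must be unique within a schema")
    sch <- data.frame(name = as.character(name),
                      category = rep_len(as.character(category), length(name)),
                      units = rep_len(as.character(units), length(name)),
                      transform = rep_len(as.character(transform), length(name)),
                      required = rep_len(as.logical(required), length(name)),
                      stringsAsFactors = FALSE)
    if (!all(sch$category %in% .FEATURE_CATEGORIES))
        stop("unknown feature category: ",
             paste(setdiff(sch$category, .FEATURE_CATEGORIES), collapse = ", "))
    if (!all(sch$transform %in% c("none", "log")))
        stop("transform must be 'none' or 'log'")
    sch
}

#' Construct a SepsisCohort
#'
#' @param features numeric feature-by-patient matrix with feature rownames
#'   and patient-id colnames; \code{NA} encodes a missing measurement.
#' @param schema feature schema from [featureSchema()]; its \code{name}
#'   column must match \code{rownames(features)}.
#' @param patientData data.frame (one row per patient) with the outcome
#'   fields \code{icu_days}, \code{organ_dysfunction_at_day14},
#'   \code{death_day}, \code{disposition}, \code{mortality_28d},
#'   \code{mortality_1y}, \code{outcome}; missing fields are added as NA.
#' @param cohortId character(1) cohort tag.
#' @return a \linkS4class{SepsisCohort}.
#' @export
SepsisCohort <- function(features, schema, patientData = NULL,
                         cohortId = "cohort") {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (is.null(rownames(features)))
        stop("features must have feature rownames")
    if (!identical(rownames(features), schema$name))
        stop("rownames(features) must equal schema$name (same order)")
    if (is.null(colnames(features)))
        colnames(features) <- sprintf("P%03d", seq_len(ncol(features)))
    np <- ncol(features)
    if (is.null(patientData))
        patientData <- data.frame(row.names = colnames(features))
    patientData <- as.data.frame(patientData)
    defaults <- list(icu_days = NA_integer_,
                     organ_dysfunction_at_day14 = NA,
                     death_day = NA_integer_,
                     disposition = NA_character_,
                     mortality_28d = NA,
                     mortality_1y = NA,
                     outcome = NA_character_)
    for (nm in names(defaults))
        if (!nm %in% colnames(patientData))
            patientData[[nm]] <- rep(defaults[[nm]], length.out = np)
    rd <- S4Vectors::DataFrame(schema[, c("category", "units", "transform",
                                          "required")],
                               row.names = schema$name)
    cd <- S4Vectors::DataFrame(patientData, row.names = colnames(features),
                               check.names = FALSE)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = features), rowData = rd, colData = cd)
    S4Vectors::metadata(se)$cohort_id <- cohortId
    new("SepsisCohort", se)
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "SepsisCohort", function(x)
    SummarizedExperiment::assay(x, "features"))

#' @rdname accessors
#' @export
setMethod("featureInfo", "SepsisCohort", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    data.frame(name = rownames(x), as.data.frame(rd),
               row.names = NULL, check.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("patientData", "SepsisCohort", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setMethod("cohortId", "SepsisCohort", function(x)
    S4Vectors::metadata(x)$cohort_id)

#' @rdname accessors
#' @export
setMethod("clusters", "ClusterAssignment", function(x)
    stats::setNames(x@cluster, x@patientIds))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) {
    if (all(is.na(x@labels)))
        stop("assignment carries no semantic labels; run labelClusters()")
    stats::setNames(x@labels[x@cluster], x@patientIds)
})

setMethod("show", "SepsisCohort", function(object) {
    cat(sprintf("SepsisCohort '%s': %d features x %d patients\n",
                cohortId(object), nrow(object), ncol(object)))
    tab <- table(SummarizedExperiment::rowData(object)$category)
    cat("  features by category: ",
        paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
    oc <- SummarizedExperiment::colData(object)$outcome
    if (any(!is.na(oc))) {
        ot <- table(factor(oc, levels = .OUTCOMES))
        cat("  adjudicated outcomes: ",
            paste(sprintf("%s=%d", names(ot), ot), collapse = ", "), "\n")
    }
    miss <- mean(is.na(featureMatrix(object)))
    cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
})

setMethod("show", "ClusterAssignment", function(object) {
    cat(sprintf("ClusterAssignment: %d patients, k = %d\n",
                length(object@patientIds), object@k))
    tab <- table(object@cluster)
    lab <- ifelse(is.na(object@labels), paste0("cluster", seq_len(object@k)),
                  object@labels)
    cat(paste(sprintf("  %s: n = %d", lab, tab), collapse = "\n"), "\n")
})

setMethod("show", "ScalerParams", function(object) {
    cat(sprintf("ScalerParams fitted on '%s': %d features, cap = %g SD\n",
                object@cohortId, length(object@features), object@cap))
})

setMethod("show", "LinkageTree", function(object) {
    cat(sprintf("LinkageTree: %d leaves, %d merges, heights [%.4g, %.4g]\n",
                length(object@labels), nrow(object@merge),
                min(object@height), max(object@height)))
})

setMethod("show", "ClusterSignature", function(object) {
    st <- object@stats
    cat(sprintf("ClusterSignature from '%s' (%s t-test, anchor %s)\n",
                object@cohortId, object@testVariant, object@anchor))
    cat(sprintf("  %d features tested; %d at p<0.05 (of which %d at p<0.0001)\n",
                nrow(st), sum(st$tier != "not_significant"),
                sum(st$tier == "p<0.0001")))
})

setMethod("show", "ProjectionResult", function(object) {
    cat("ProjectionResult\n")
    show(object@assignment)
    cat(sprintf("  excluded: %d patients; CH(2) = %.3f\n",
                nrow(object@excluded), object@ch))
})

setMethod("show", "LassoFit", function(object) {
    cat(sprintf("LassoFit: %d candidates, lambda = %.5g, selected %d\n",
                length(object@candidates), object@lambda,
                length(object@selected)))
    if (nrow(object@refit)) {
        cat("  refit odds ratios:\n")
        for (i in seq_len(nrow(object@refit)))
            cat(sprintf("    %s: OR %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
                        object@refit$variable[i], object@refit$or[i],
                        object@refit$ciLow[i], object@refit$ciHigh[i],
                        object@refit$p[i]))
    }
})

#' @rdname accessors
#' @export
setMethod("signatureStats", "ClusterSignature", function(x) x@stats)

#' @rdname accessors
#' @export
setMethod("signatureFeatures", "ClusterSignature", function(x)
    x@stats$feature)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "ClusterSignature", function(x)
    x@stats$feature[x@stats$tier != "not_significant"])

#' @rdname accessors
#' @export
setMethod("scalerParams", "ClusterSignature", function(x) x@scaler)
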