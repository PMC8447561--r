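#' @include AllClasses.R
NULL

#' Accessors for LipoPheno classes
#'
#' \code{featureMatrix} returns the feature-by-patient assay of a
#' \linkS4class{SepsisCohort}; \code{featureInfo} its feature schema
#' (rowData) as a data.frame; \code{patientData} its clinical colData;
#' \code{cohortId} the cohort tag. \code{clusters} and
#' \code{clusterLabels} return the numeric cluster indices and (for
#' labelled 2-cuts) the per-patient semantic labels of a
#' \linkS4class{ClusterAssignment}. \code{signatureStats},
#' \code{signatureFeatures}, \code{selectedFeatures} and
#' \code{scalerParams} expose the components of a
#' \linkS4class{ClusterSignature}.
#'
#' @param x an object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases featureMatrix featureInfo patientData cohortId clusters
#'   clusterLabels signatureStats signatureFeatures selectedFeatures
#'   scalerParams
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname accessors
#' @export
setGeneric("patientData", function(x) standardGeneric("patientData"))

#' @rdname accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("signatureStats", function(x) standardGeneric("signatureStats"))

#' @rdname accessors
#' @export
setGeneric("signatureFeatures", function(x) standardGeneric("signatureFeatures"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("scalerParams", function(x) standardGeneric("scalerParams"))

#' Convert a LinkageTree to a base hclust object
#'
#' @param x a \linkS4class{LinkageTree}.
#' @return an object of class \code{hclust} suitable for
#'   \code{plot}/\code{as.dendrogram}.
#' @export
setGeneric("asHclust", function(x) standardGeneric("asHclust"))
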