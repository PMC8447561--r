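#' @include signature.R outcome-stats.R simulate.R cohort-io.R
NULL

#' Run the full derivation pipeline on a cohort
#'
#' Orchestrates impute -> scale (optional cap) -> Spearman distance ->
#' Ward linkage -> elbow/CH diagnostics -> k-cut -> semantic labelling ->
#' t-test signature. Patients are processed in sorted patient-id order,
#' making the result invariant to input row order.
#'
#' @param x a \linkS4class{SepsisCohort}.
#' @param features clustering feature panel (default: all schema
#'   features).
#' @param signatureFeats features entering the signature (default: the
#'   clustering panel, which makes self-projection reproduce the
#'   derivation labels exactly).
#' @param k number of clusters extracted (default 2).
#' @param capDerivation logical, cap derivation z-scores (default FALSE;
#'   the cap is always stored for replication use).
#' @param cap outlier cap in SD units (default 3).
#' @param anchor anchor feature for labelling.
#' @param testVariant \code{"welch"} or \code{"student"}.
#' @param kRange range for the diagnostics curve.
#' @return list: \code{cohort} (imputed, sorted), \code{z} (z-matrix
#'   used for clustering), \code{tree} (\linkS4class{LinkageTree}),
#'   \code{assignment} (labelled), \code{signature}
#'   (\linkS4class{ClusterSignature}), \code{quality} ([elbowCurve()]
#'   table), \code{imputation} (report).
#' @export
derivePhenotypes <- function(x, features = rownames(x),
                             signatureFeats = features, k = 2,
                             capDerivation = FALSE, cap = 3,
                             anchor = "hdl_c",
                             testVariant = c("welch", "student"),
                             kRange = 1:10) {
    testVariant <- match.arg(testVariant)
    if (ncol(x) < 4) stop("need at least 4 patients to derive phenotypes")
    x <- x[, order(colnames(x))]
    imp <- imputeMedian(x, features)
    scaler <- fitScaler(imp$cohort, features, cap = cap)
    z <- applyScaler(imp$cohort, scaler, cap = capDerivation)
    tree <- wardLinkage(spearmanDistance(z))
    kRange <- kRange[kRange <= ncol(x)]
    quality <- elbowCurve(z, tree, kRange)
    asg <- labelClusters(cutClusters(tree, k), imp$cohort, anchor = anchor)
    sig <- deriveSignature(imp$cohort, asg, signatureFeats,
                           testVariant = testVariant, cap = cap,
                           anchor = anchor)
    list(cohort = imp$cohort, z = z, tree = tree, assignment = asg,
         signature = sig, quality = quality, imputation = imp$report)
}

.writeManifest <- function(outDir, stage, info) {
    man <- c(list(stage = stage,
                  package = as.character(utils::packageVersion("LipoPheno")),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             info)
    jsonlite::write_json(man, file.path(outDir, paste0(stage, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
}

.ensureDir <- function(d) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    d
}

#' Pipeline commands: simulate, derive, replicate, predict
#'
#' File-oriented front-ends over the package's functions, each writing
#' CSV/TSV/JSON outputs plus a run manifest into \code{outDir}. These
#' back the \code{inst/scripts/lipopheno.R} command-line wrapper.
#'
#' \code{runSimulate} writes \code{cohort.csv} (+ JSON schema sidecar),
#' \code{labels.csv} and a config echo. \code{runDerive} writes
#' \code{signature.json}, \code{assignments.csv}, \code{quality.tsv},
#' \code{linkage.tsv} (left, right, height, size), \code{leaf_order.txt},
#' \code{ordered_matrix.tsv} (features sorted by category x patients in
#' leaf order), \code{outcome_table.tsv} and \code{comparisons.tsv}.
#' \code{runReplicate} writes \code{projection.csv},
#' \code{excluded.csv}, \code{concordance.tsv} and
#' \code{outcome_table.tsv}. \code{runPredict} writes
#' \code{lasso_selected.tsv} (odds-ratio table), \code{lasso_path.tsv}
#' and \code{roc_auc.tsv} plus per-predictor ROC points.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if absent).
#' @param seed optional seed override.
#' @return invisibly, the main in-memory result of the stage.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config, outDir, seed = NULL) {
    .ensureDir(outDir)
    sim <- generateCohort(config, seed = seed)
    writeCohort(sim$cohort, file.path(outDir, "cohort.csv"))
    utils::write.csv(data.frame(patient_id = names(sim$labels),
                                phenotype = unname(sim$labels)),
                     file.path(outDir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(
        list(n = config@n, prevalence_hypo = config@prevalenceHypo,
             missing_rate = config@missingRate,
             seed = if (is.null(seed)) config@seed else seed,
             outcome_probs = as.data.frame(config@outcomeProbs),
             mortality28_probs = as.list(config@mortality28Probs)),
        file.path(outDir, "config_echo.json"), auto_unbox = TRUE,
        digits = NA)
    .writeManifest(outDir, "simulate",
                   list(n = config@n,
                        seed = if (is.null(seed)) config@seed else seed))
    invisible(sim)
}

#' @rdname pipeline
#' @param x a \linkS4class{SepsisCohort} (or path to a cohort CSV with
#'   schema sidecar).
#' @param ... passed to [derivePhenotypes()].
#' @export
runDerive <- function(x, outDir, features = NULL, ...) {
    .ensureDir(outDir)
    if (is.character(x)) x <- readCohort(x)
    if (is.null(features)) {
        features <- intersect(clusteringPanel(), rownames(x))
        if (length(features) < 2) features <- rownames(x)
    }
    res <- derivePhenotypes(x, features = features, ...)
    writeSignature(res$signature, file.path(outDir, "signature.json"))
    lab <- clusterLabels(res$assignment)
    utils::write.csv(data.frame(patient_id = names(lab),
                                cluster = unname(res$assignment@cluster),
                                label = unname(lab)),
                     file.path(outDir, "assignments.csv"),
                     row.names = FALSE)
    utils::write.table(res$quality, file.path(outDir, "quality.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tr <- res$tree
    utils::write.table(data.frame(left = tr@merge[, 1],
                                  right = tr@merge[, 2],
                                  height = tr@height, size = tr@size),
                       file.path(outDir, "linkage.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    writeLines(tr@labels[tr@order], file.path(outDir, "leaf_order.txt"))
    fi <- featureInfo(res$cohort)
    featOrd <- fi$name[order(fi$category, fi$name)]
    featOrd <- featOrd[featOrd %in% rownames(res$z)]
    om <- res$z[featOrd, tr@labels[tr@order], drop = FALSE]
    utils::write.table(data.frame(feature = rownames(om), om,
                                  check.names = FALSE),
                       file.path(outDir, "ordered_matrix.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pd <- patientData(res$cohort)
    if (!all(is.na(pd$outcome))) {
        ot <- clusterOutcomeTable(res$assignment,
                                  stats::setNames(pd$outcome, rownames(pd)),
                                  stats::setNames(pd$mortality_28d,
                                                  rownames(pd)))
        utils::write.table(ot, file.path(outDir, "outcome_table.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        cmp <- data.frame(t(featureMatrix(res$cohort)), check.names = FALSE)
        cmp$.cluster <- unname(lab)
        gc <- groupCompare(cmp, ".cluster",
                           signatureFeatures(res$signature),
                           familySize = length(
                               signatureFeatures(res$signature)))
        utils::write.table(gc, file.path(outDir, "comparisons.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    .writeManifest(outDir, "derive",
                   list(cohort = cohortId(x), n = ncol(x),
                        features = nrow(res$z),
                        imputed_cells = sum(res$imputation$perFeature)))
    invisible(res)
}

#' @rdname pipeline
#' @param signature a \linkS4class{ClusterSignature} or path to a
#'   signature JSON.
#' @param imputeSource,cap passed to [projectReplication()].
#' @export
runReplicate <- function(x, signature, outDir,
                         imputeSource = "derivation", cap = TRUE) {
    .ensureDir(outDir)
    if (is.character(x)) x <- readCohort(x)
    if (is.character(signature)) signature <- readSignature(signature)
    proj <- projectReplication(x, signature, imputeSource = imputeSource,
                               cap = cap)
    lab <- clusterLabels(proj@assignment)
    utils::write.csv(data.frame(patient_id = names(lab),
                                cluster = unname(proj@assignment@cluster),
                                label = unname(lab)),
                     file.path(outDir, "projection.csv"), row.names = FALSE)
    utils::write.csv(proj@excluded, file.path(outDir, "excluded.csv"),
                     row.names = FALSE)
    conc <- signatureConcordance(signature, x, proj,
                                 imputeSource = imputeSource)
    utils::write.table(conc$perFeature,
                       file.path(outDir, "concordance.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pd <- patientData(x)
    if (!all(is.na(pd$outcome))) {
        ot <- clusterOutcomeTable(proj@assignment,
                                  stats::setNames(pd$outcome, rownames(pd)),
                                  stats::setNames(pd$mortality_28d,
                                                  rownames(pd)))
        utils::write.table(ot, file.path(outDir, "outcome_table.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    .writeManifest(outDir, "replicate",
                   list(cohort = cohortId(x), kept = length(lab),
                        excluded = nrow(proj@excluded),
                        concordant_fraction = conc$concordantFraction))
    invisible(list(projection = proj, concordance = conc))
}

#' @rdname pipeline
#' @param assignment optional labelled \linkS4class{ClusterAssignment}
#'   for the AUC comparison (computed by [derivePhenotypes()] when
#'   absent).
#' @param candidates LASSO candidate features (default: a biomarker +
#'   clinical panel from the schema).
#' @param logTransform candidates to log-transform (default ApoA-I).
#' @param nFolds,cvSeed cross-validation settings.
#' @export
runPredict <- function(x, outDir, assignment = NULL, candidates = NULL,
                       logTransform = "apoa1", nFolds = 10, cvSeed = 1) {
    .ensureDir(outDir)
    if (is.character(x)) x <- readCohort(x)
    pd <- patientData(x)
    if (any(is.na(pd$outcome)))
        stop("all patients need adjudicated outcomes; run adjudicateCohort()")
    if (is.null(candidates))
        candidates <- intersect(
            c("age", "pon1_activity", "apoa1", "hdl_c", "ldl_c",
              "total_cholesterol", "triglycerides", "il6", "il8", "il10",
              "ip10", "mcp1", "tnfa", "sofa_total", "lactate", "mech_vent",
              "statin", "vasopressor", "apache2", "charlson"),
            rownames(x))
    df <- data.frame(t(featureMatrix(x)), check.names = FALSE)
    df$poor_outcome <- as.integer(pd$outcome %in% c("cci", "early_death"))
    fit <- lassoSelect(df, candidates, "poor_outcome",
                       logTransform = intersect(logTransform, candidates),
                       nFolds = nFolds, seed = cvSeed)
    utils::write.table(fit@refit, file.path(outDir, "lasso_selected.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fit@path, file.path(outDir, "lasso_path.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    aucs <- NULL
    if (is.null(assignment))
        assignment <- derivePhenotypes(x)$assignment
    oc <- stats::setNames(pd$outcome, rownames(pd))
    m <- featureMatrix(x)
    if (all(c("sofa_total", "apache2") %in% rownames(m))) {
        rocs <- compareSignatureAuc(assignment,
                                    m["sofa_total", ], m["apache2", ], oc)
        aucs <- data.frame(predictor = names(rocs),
                           auc = vapply(rocs, `[[`, numeric(1), "auc"),
                           n_pos = vapply(rocs, `[[`, numeric(1), "nPos"),
                           n_neg = vapply(rocs, `[[`, numeric(1), "nNeg"))
        utils::write.table(aucs, file.path(outDir, "roc_auc.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        for (nm in names(rocs))
            utils::write.table(rocs[[nm]]$points,
                               file.path(outDir,
                                         paste0("roc_points_", nm, ".tsv")),
                               sep = "\t", row.names = FALSE, quote = FALSE)
    }
    .writeManifest(outDir, "predict",
                   list(cohort = cohortId(x), n = fit@n,
                        events = fit@events, cv_seed = cvSeed,
                        selected = fit@selected))
    invisible(list(lasso = fit, auc = aucs))
}
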