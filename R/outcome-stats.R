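#' @include cohort.R
NULL

#' Univariate group comparisons with Bonferroni thresholding
#'
#' Continuous variables are compared by the Wilcoxon rank-sum test
#' (exact when both arms have at most 25 observations and no ties;
#' otherwise the normal approximation with tie and continuity
#' correction); categorical variables (factor/character/logical) by
#' Pearson's chi-square, falling back to Fisher's exact test when any
#' observed cell count is below 5 (set \code{fisherOn = "expected"} for
#' the expected-count convention). Missing values are dropped per
#' variable. Each result carries the Bonferroni family threshold
#' 0.05/m.
#'
#' @param data data.frame holding \code{variables} and \code{group}.
#' @param group name of a grouping column with >= 2 levels.
#' @param variables column names to compare.
#' @param familySize Bonferroni family size m (default: number of
#'   variables).
#' @param fisherOn \code{"observed"} (default) or \code{"expected"} cell
#'   counts triggering Fisher's exact test.
#' @return data.frame: variable, test, statistic, p, threshold,
#'   significant, and one summary column per group level (median
#'   (q1, q3) or counts).
#' @export
groupCompare <- function(data, group, variables,
                         familySize = length(variables),
                         fisherOn = c("observed", "expected")) {
    fisherOn <- match.arg(fisherOn)
    g <- factor(data[[group]])
    if (nlevels(g) < 2) stop("grouping variable needs >= 2 levels")
    thr <- 0.05 / familySize
    one <- function(v) {
        x <- data[[v]]
        keep <- !is.na(x) & !is.na(g)
        x <- x[keep]; gg <- droplevels(g[keep])
        if (length(unique(x)) < 2) {
            warning("variable '", v, "' is degenerate (single value); p = 1")
            return(data.frame(variable = v, test = "degenerate",
                              statistic = NA_real_, p = 1,
                              threshold = thr, significant = FALSE))
        }
        if (is.numeric(x)) {
            ns <- table(gg)
            exact <- all(ns <= 25) && !any(duplicated(x))
            wt <- suppressWarnings(
                stats::wilcox.test(x ~ gg, exact = exact, correct = TRUE))
            data.frame(variable = v, test = "wilcoxon_rank_sum",
                       statistic = unname(wt$statistic), p = wt$p.value,
                       threshold = thr, significant = wt$p.value < thr)
        } else {
            tab <- table(x, gg)
            small <- if (fisherOn == "observed") any(tab < 5)
                     else any(suppressWarnings(
                         stats::chisq.test(tab))$expected < 5)
            if (small) {
                ft <- stats::fisher.test(tab)
                data.frame(variable = v, test = "fisher_exact",
                           statistic = NA_real_, p = ft$p.value,
                           threshold = thr, significant = ft$p.value < thr)
            } else {
                ct <- stats::chisq.test(tab, correct = FALSE)
                data.frame(variable = v, test = "chi_square",
                           statistic = unname(ct$statistic), p = ct$p.value,
                           threshold = thr, significant = ct$p.value < thr)
            }
        }
    }
    res <- do.call(rbind, lapply(variables, one))
    ## per-group summaries
    for (lev in levels(g)) {
        res[[paste0("summary_", lev)]] <- vapply(variables, function(v) {
            x <- data[[v]][g == lev]
            if (is.numeric(x)) {
                q <- stats::quantile(x, c(.25, .5, .75), na.rm = TRUE)
                sprintf("%.3g (%.3g, %.3g)", q[2], q[1], q[3])
            } else {
                tb <- table(x)
                paste(sprintf("%s=%d", names(tb), tb), collapse = "; ")
            }
        }, character(1))
    }
    rownames(res) <- NULL
    res
}

#' Spearman correlation matrix between two feature panels
#'
#' Pairwise-complete Spearman rank correlations (average ranks for
#' ties) between the raw values of two feature sets, with p-values from
#' the t approximation and per-pair complete-observation counts. Pairs
#' with fewer than 3 complete observations get NA.
#'
#' @param x a \linkS4class{SepsisCohort}.
#' @param rowFeatures,colFeatures feature name vectors.
#' @return list with matrices \code{rho}, \code{p} and \code{n}
#'   (rowFeatures x colFeatures).
#' @export
spearmanMatrix <- function(x, rowFeatures, colFeatures) {
    m <- featureMatrix(x)
    miss <- setdiff(c(rowFeatures, colFeatures), rownames(m))
    if (length(miss))
        stop("feature(s) not in cohort: ", paste(miss, collapse = ", "))
    rho <- p <- nn <- matrix(NA_real_, length(rowFeatures),
                             length(colFeatures),
                             dimnames = list(rowFeatures, colFeatures))
    for (a in rowFeatures) for (b in colFeatures) {
        ok <- !is.na(m[a, ]) & !is.na(m[b, ])
        n <- sum(ok)
        nn[a, b] <- n
        if (n < 3) next
        r <- stats::cor(m[a, ok], m[b, ok], method = "spearman")
        rho[a, b] <- r
        if (abs(r) >= 1) { p[a, b] <- 0; next }
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p[a, b] <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    list(rho = rho, p = p, n = nn)
}

#' Cluster-by-outcome contingency table with percentages
#'
#' Counts and percentages of rapid recovery, chronic critical illness
#' and early death per cluster, plus 28-day mortality; percentages are
#' 100 * count / cluster size rounded to one decimal.
#'
#' @param assignment a \linkS4class{ClusterAssignment} (labelled or not).
#' @param outcomes named character vector of adjudicated outcomes
#'   covering every clustered patient.
#' @param mortality28d optional named logical vector, 28-day mortality.
#' @return data.frame: cluster, measure, count, denominator, pct.
#' @export
clusterOutcomeTable <- function(assignment, outcomes, mortality28d = NULL) {
    ids <- assignment@patientIds
    oc <- outcomes[ids]
    if (any(is.na(oc)))
        stop("clustered patient(s) without adjudicated outcome: ",
             paste(ids[is.na(oc)], collapse = ", "))
    if (!all(oc %in% .OUTCOMES))
        stop("unknown outcome label(s)")
    labs <- if (all(is.na(assignment@labels)))
        paste0("cluster", seq_len(assignment@k)) else assignment@labels
    rows <- list()
    for (g in seq_len(assignment@k)) {
        sel <- assignment@cluster == g
        n <- sum(sel)
        if (n == 0) stop("empty cluster ", g)
        for (o in .OUTCOMES) {
            cnt <- sum(oc[sel] == o)
            rows[[length(rows) + 1L]] <-
                data.frame(cluster = labs[g], measure = o, count = cnt,
                           denominator = n,
                           pct = round(100 * cnt / n, 1))
        }
        if (!is.null(mortality28d)) {
            m <- mortality28d[ids][sel]
            cnt <- sum(m, na.rm = TRUE)
            rows[[length(rows) + 1L]] <-
                data.frame(cluster = labs[g], measure = "mortality_28d",
                           count = cnt, denominator = n,
                           pct = round(100 * cnt / n, 1))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' LASSO variable selection with unpenalized refit
#'
#' L1-penalized logistic regression of a binary poor-outcome indicator
#' on a standardized candidate design; the penalty is chosen by k-fold
#' cross-validated binomial deviance (seeded, minimum-deviance rule).
#' Variables with nonzero coefficients at the chosen penalty form the
#' selected set; an unpenalized logistic refit on the selected set
#' yields odds ratios with 95% Wald confidence intervals and p-values
#' (per unit of the -- possibly log-transformed -- predictor).
#' Complete-case analysis on the candidates.
#'
#' @param data data.frame with candidate columns and the outcome column.
#' @param candidates candidate predictor names.
#' @param outcome name of the binary outcome column (1 = CCI or early
#'   death, 0 = rapid recovery).
#' @param logTransform candidate names to log-transform before modelling
#'   (values must be positive).
#' @param nFolds cross-validation folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param lambda optional fixed penalty overriding cross-validation.
#' @return a \linkS4class{LassoFit}.
#' @export
lassoSelect <- function(data, candidates, outcome = "poor_outcome",
                        logTransform = character(), nFolds = 10, seed = 1,
                        lambda = NULL) {
    df <- data[, c(candidates, outcome)]
    df <- df[stats::complete.cases(df), ]
    for (v in logTransform) {
        if (any(df[[v]] <= 0))
            stop("log transform requires positive values: ", v)
        df[[v]] <- log(df[[v]])
    }
    X <- as.matrix(df[, candidates, drop = FALSE])
    y <- as.integer(df[[outcome]])
    if (!all(y %in% 0:1)) stop("outcome must be binary 0/1")
    ev <- sum(y)
    if (min(ev, length(y) - ev) < 10)
        warning("fewer than 10 events; selection is unstable")
    set.seed(as.integer(seed))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = nFolds,
                            type.measure = "deviance", standardize = TRUE)
    lam <- if (is.null(lambda)) cv$lambda.min else lambda
    beta <- stats::coef(cv$glmnet.fit, s = lam, exact = TRUE, x = X, y = y,
                        family = "binomial", standardize = TRUE)
    beta <- as.numeric(beta)[-1]
    selected <- candidates[beta != 0]
    path <- data.frame(lambda = cv$lambda, df = cv$nzero,
                       cvDeviance = cv$cvm)
    refit <- data.frame(variable = character(0), estimate = numeric(0),
                        or = numeric(0), ciLow = numeric(0),
                        ciHigh = numeric(0), p = numeric(0))
    separation <- FALSE
    if (length(selected)) {
        fdf <- data.frame(df[, selected, drop = FALSE], .y = y,
                          check.names = FALSE)
        fit <- stats::glm(.y ~ ., data = fdf, family = stats::binomial())
        sm <- summary(fit)$coefficients
        sel <- rownames(sm) != "(Intercept)"
        est <- sm[sel, "Estimate"]; se <- sm[sel, "Std. Error"]
        separation <- any(abs(est) > 15 | se > 10)
        if (separation)
            warning("quasi-separation in the refit; confidence intervals ",
                    "are unstable")
        refit <- data.frame(variable = rownames(sm)[sel], estimate = est,
                            or = exp(est),
                            ciLow = exp(est - stats::qnorm(.975) * se),
                            ciHigh = exp(est + stats::qnorm(.975) * se),
                            p = sm[sel, "Pr(>|z|)"], row.names = NULL)
    }
    new("LassoFit", candidates = candidates, selected = selected,
        lambda = lam, path = path, refit = refit,
        nFolds = as.integer(nFolds), seed = as.integer(seed),
        n = length(y), events = as.integer(ev), separation = separation)
}

#' ROC curve and AUC by Mann-Whitney pair counting
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 0.5),
#' computed by the rank formula; the curve is a threshold sweep over the
#' unique score values, starting at (0,0) and ending at (1,1). Binary
#' predictors yield the 2-point ROC whose AUC equals
#' (sensitivity + specificity)/2.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param outcome binary 0/1 (or logical) outcome; both classes must be
#'   present.
#' @param predictor name recorded in the result.
#' @return list: predictor, auc, points (data.frame threshold, fpr,
#'   sensitivity), nPos, nNeg.
#' @export
rocAuc <- function(scores, outcome, predictor = "score") {
    y <- as.integer(outcome)
    if (anyNA(scores) || anyNA(y)) {
        keep <- !is.na(scores) & !is.na(y)
        scores <- scores[keep]; y <- y[keep]
    }
    nPos <- sum(y == 1); nNeg <- sum(y == 0)
    if (nPos == 0 || nNeg == 0)
        stop("both outcome classes must be present")
    r <- rank(scores)  # midranks handle ties as 0.5 concordance
    auc <- (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    pts <- t(vapply(thr, function(t) {
        pos <- scores >= t
        c(sum(pos & y == 1) / nPos, sum(pos & y == 0) / nNeg)
    }, numeric(2)))
    points <- data.frame(threshold = thr, fpr = pts[, 2],
                         sensitivity = pts[, 1])
    list(predictor = predictor, auc = auc, points = points,
         nPos = nPos, nNeg = nNeg)
}

#' Compare the cluster signature with SOFA and APACHE II by AUC
#'
#' ROC/AUC of (a) binary Hypolipoprotein cluster membership, (b) total
#' SOFA score and (c) APACHE II score for discriminating rapid recovery
#' from CCI-or-early-death, computed on the same patients.
#'
#' @param assignment a labelled \linkS4class{ClusterAssignment}.
#' @param sofa,apache named numeric score vectors covering the clustered
#'   patients.
#' @param outcomes named adjudicated outcome vector
#'   (\code{rapid_recovery}/\code{cci}/\code{early_death}).
#' @return list of three [rocAuc()] results named \code{cluster},
#'   \code{sofa}, \code{apache}.
#' @export
compareSignatureAuc <- function(assignment, sofa, apache, outcomes) {
    ids <- assignment@patientIds
    y <- as.integer(outcomes[ids] %in% c("cci", "early_death"))
    hypo <- as.integer(clusterLabels(assignment) == "hypolipoprotein")
    list(cluster = rocAuc(hypo, y, "cluster"),
         sofa = rocAuc(sofa[ids], y, "sofa"),
         apache = rocAuc(apache[ids], y, "apache"))
}
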