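#' @include cohort.R
NULL

#' Friedewald estimate of LDL cholesterol
#'
#' LDL-C (mg/dL) estimated from a fasting lipid panel as
#' \code{TC - HDL-C - TG/5}, the Friedewald relation. The estimate is
#' invalid at high triglyceride levels; by convention values at or above
#' 400 mg/dL are rejected (set \code{tgLimit = Inf} to disable the check).
#'
#' @param tc total cholesterol, mg/dL (non-negative).
#' @param hdl HDL cholesterol, mg/dL (non-negative).
#' @param tg triglycerides, mg/dL (non-negative, below \code{tgLimit}).
#' @param tgLimit triglyceride validity bound in mg/dL (default 400).
#' @return estimated LDL-C in mg/dL (vectorized).
#' @examples
#' friedewaldLDL(200, 50, 150)  # 120
#' friedewaldLDL(91, 19, 121)   # 47.8
#' @export
friedewaldLDL <- function(tc, hdl, tg, tgLimit = 400) {
    if (any(c(tc, hdl, tg) < 0, na.rm = TRUE))
        stop("lipid panel values must be non-negative")
    if (any(tg >= tgLimit, na.rm = TRUE))
        stop("Friedewald estimate invalid: triglycerides >= ", tgLimit,
             " mg/dL")
    tc - hdl - tg / 5
}

#' Adjudicate the primary sepsis outcome
#'
#' Assigns each patient exactly one of three primary outcome categories:
#' \describe{
#'   \item{early_death}{in-hospital death within 14 days of sepsis onset
#'     (\code{death_day <= 14}, 1-based days);}
#'   \item{cci}{chronic critical illness -- ICU stay beyond 14 days with
#'     continued organ dysfunction at day 14, or a shorter ICU stay with
#'     discharge to long-term acute care, another hospital, or hospice;}
#'   \item{rapid_recovery}{all remaining patients.}
#' }
#' A patient with \code{icu_days} beyond the threshold but an unknown
#' day-14 organ-dysfunction status is indeterminate and raises an error
#' rather than being silently classified.
#'
#' @param icu_days non-negative integer vector, total ICU days.
#' @param disposition character vector of hospital dispositions (one of
#'   home, rehab, skilled_nursing, ltac, other_hospital, hospice, died).
#' @param death_day in-hospital death day (1-based from sepsis onset) or
#'   NA for survivors.
#' @param organ_dysfunction_at_day14 logical; may be NA when irrelevant.
#' @param cciComparator \code{">"} (default: ICU stay strictly beyond 14
#'   days) or \code{">="}.
#' @return character vector of outcome labels.
#' @examples
#' adjudicateOutcome(10, "died", death_day = 5)            # early_death
#' adjudicateOutcome(20, "skilled_nursing",
#'                   organ_dysfunction_at_day14 = TRUE)    # cci
#' adjudicateOutcome(3, "home")                            # rapid_recovery
#' @export
adjudicateOutcome <- function(icu_days, disposition, death_day = NA,
                              organ_dysfunction_at_day14 = NA,
                              cciComparator = c(">", ">=")) {
    cciComparator <- match.arg(cciComparator)
    n <- max(length(icu_days), length(disposition))
    icu_days <- rep_len(icu_days, n)
    disposition <- rep_len(as.character(disposition), n)
    death_day <- rep_len(death_day, n)
    od <- rep_len(organ_dysfunction_at_day14, n)
    if (any(is.na(icu_days)) || any(is.na(disposition)))
        stop("icu_days and disposition are required for adjudication")
    if (any(icu_days < 0))
        stop("icu_days must be non-negative")
    dd <- !is.na(death_day)
    if (any(dd & disposition != "died"))
        stop("death_day present requires disposition 'died'")
    long_icu <- if (cciComparator == ">") icu_days > 14 else icu_days >= 14
    early <- dd & death_day <= 14
    indet <- !early & long_icu & is.na(od)
    if (any(indet))
        stop("indeterminate: ICU stay beyond threshold but day-14 organ ",
             "dysfunction unknown for patient(s) ",
             paste(which(indet), collapse = ", "))
    cci <- !early & ((long_icu & od %in% TRUE) |
                     (!long_icu & disposition %in%
                          c("ltac", "other_hospital", "hospice")))
    out <- rep("rapid_recovery", n)
    out[cci] <- "cci"
    out[early] <- "early_death"
    out
}

#' Adjudicate outcomes for every patient of a cohort
#'
#' Applies [adjudicateOutcome()] to the cohort's clinical fields and
#' stores the labels in \code{patientData(x)$outcome}.
#'
#' @param x a \linkS4class{SepsisCohort}.
#' @param cciComparator passed to [adjudicateOutcome()].
#' @return the cohort with the \code{outcome} column filled.
#' @export
adjudicateCohort <- function(x, cciComparator = c(">", ">=")) {
    cd <- SummarizedExperiment::colData(x)
    out <- adjudicateOutcome(cd$icu_days, cd$disposition, cd$death_day,
                             cd$organ_dysfunction_at_day14,
                             cciComparator = match.arg(cciComparator))
    SummarizedExperiment::colData(x)$outcome <- out
    validObject(x)
    x
}
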