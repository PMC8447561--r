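#' @include cohort.R
NULL

.schemaPath <- function(path) sub("\\.csv$", "", path) |>
    paste0(".schema.json")

#' Write / read a cohort as CSV plus JSON schema sidecar
#'
#' The cohort CSV has one row per patient: \code{patient_id} first, the
#' feature columns in schema order, then the outcome fields
#' (\code{icu_days}, \code{organ_dysfunction_at_day14}, \code{death_day},
#' \code{disposition}, \code{mortality_28d}, \code{mortality_1y},
#' \code{outcome}). Missing cells are written empty; on read both the
#' empty string and \code{"NA"} denote missing. The feature schema is
#' written alongside as \code{<path>.schema.json} (dropping a trailing
#' \code{.csv}). The round trip \code{readCohort(writeCohort(x))} is
#' lossless on values, missingness and ordering.
#'
#' @param x a \linkS4class{SepsisCohort}.
#' @param path CSV file path.
#' @param schemaPath optional explicit sidecar path.
#' @return \code{writeCohort} returns \code{path} invisibly;
#'   \code{readCohort} returns a \linkS4class{SepsisCohort}.
#' @export
writeCohort <- function(x, path, schemaPath = .schemaPath(path)) {
    m <- featureMatrix(x)
    cd <- patientData(x)
    fmt <- function(v) {
        if (is.numeric(v)) ifelse(is.na(v), "", vapply(v, function(z)
            format(z, digits = 15, scientific = FALSE, trim = TRUE),
            character(1)))
        else ifelse(is.na(v), "", as.character(v))
    }
    df <- data.frame(patient_id = colnames(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (f in rownames(m)) df[[f]] <- fmt(m[f, ])
    for (oc in .OUTCOME_COLUMNS) df[[oc]] <- fmt(cd[[oc]])
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    sch <- featureInfo(x)
    jsonlite::write_json(list(cohort_id = cohortId(x), schema = sch),
                         schemaPath, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCohort
#' @param schema a schema data.frame ([featureSchema()]); when NULL it is
#'   read from the JSON sidecar.
#' @param cohortIdentifier cohort tag; when NULL taken from the sidecar
#'   (or the file name).
#' @export
readCohort <- function(path, schema = NULL, schemaPath = .schemaPath(path),
                       cohortIdentifier = NULL) {
    if (is.null(schema)) {
        if (!file.exists(schemaPath))
            stop("no schema given and no sidecar found at ", schemaPath)
        side <- jsonlite::read_json(schemaPath, simplifyVector = TRUE)
        schema <- as.data.frame(side$schema)
        if (is.null(cohortIdentifier)) cohortIdentifier <- side$cohort_id
    }
    if (is.null(cohortIdentifier))
        cohortIdentifier <- sub("\\.csv$", "", basename(path))
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE)
    if (colnames(raw)[1] != "patient_id")
        stop("first column must be 'patient_id'")
    known <- c("patient_id", schema$name, .OUTCOME_COLUMNS)
    unknown <- setdiff(colnames(raw), known)
    if (length(unknown))
        stop("column(s) not in schema: ", paste(unknown, collapse = ", "))
    absent <- setdiff(schema$name, colnames(raw))
    if (length(absent))
        stop("schema feature(s) missing from file: ",
             paste(absent, collapse = ", "))
    asNum <- function(v, col) {
        blank <- v == "" | v == "NA"
        out <- suppressWarnings(as.numeric(v))
        bad <- which(!blank & is.na(out))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' in row %d, column '%s'",
                         v[bad[1]], bad[1], col))
        out[blank] <- NA_real_
        out
    }
    asLog <- function(v) ifelse(v == "" | v == "NA", NA,
                                toupper(v) %in% c("TRUE", "T", "1"))
    m <- vapply(schema$name, function(f) asNum(raw[[f]], f),
                numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw),
                dimnames = list(NULL, schema$name))
    m <- t(m)
    colnames(m) <- raw$patient_id
    getc <- function(col, conv) {
        if (!col %in% colnames(raw)) return(NULL)
        conv(raw[[col]])
    }
    pd <- data.frame(row.names = raw$patient_id)
    pd$icu_days <- getc("icu_days", function(v) as.integer(asNum(v, "icu_days")))
    pd$organ_dysfunction_at_day14 <- getc("organ_dysfunction_at_day14", asLog)
    pd$death_day <- getc("death_day",
                         function(v) as.integer(asNum(v, "death_day")))
    pd$disposition <- getc("disposition",
                           function(v) ifelse(v == "" | v == "NA",
                                              NA_character_, v))
    pd$mortality_28d <- getc("mortality_28d", asLog)
    pd$mortality_1y <- getc("mortality_1y", asLog)
    pd$outcome <- getc("outcome", function(v) ifelse(v == "" | v == "NA",
                                                     NA_character_, v))
    SepsisCohort(m, schema, pd, cohortId = cohortIdentifier)
}
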