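## Canonical questionnaire-derived metadata schema.  Free-form disease and
## medication answers are assumed to have been reduced upstream to the
## boolean any-other-disease / any-medication flags.

.metaFlags <- c("atopic_dermatitis", "other_disease", "medication",
                "hospitalization_surgery", "helicobacter_treatment",
                "insomnia_consultation", "smoking_history",
                "colorectal_surgery_history")
.metaFlagsNA <- c("menstruating_at_collection", "pregnant_or_breastfeeding")

.metaLevels <- list(
    sex = c("female", "male"),
    defecation_frequency = c("3_or_more_per_day", "1_2_per_day",
                             "4_6_per_week", "1_3_per_week",
                             "less_than_1_per_week"),
    alcohol_frequency = c("none", "light_5_or_fewer_days",
                          "heavy_or_frequent"),
    menstrual_status = c("regular", "irregular", "menopause",
                         "not_applicable"))

#' Metadata columns and categorical levels
#'
#' The closed category sets used by the group criteria (defecation and
#' alcohol categories mirror the questionnaire phrasing, e.g. "1-2 times
#' a day", "4-6 times a week").
#'
#' @return named list: \code{columns} (required column names),
#'   \code{levels} (allowed levels per categorical column)
#' @export
metadataFields <- function() {
    list(columns = .requiredMetaColumns(), levels = .metaLevels)
}

.requiredMetaColumns <- function() {
    unique(c("sample_id", "sex", "age", "bmi", "cesd", .metaFlags,
             .metaFlagsNA, setdiff(names(.metaLevels), "sex")))
}

.validateMetadata <- function(df) {
    need <- .requiredMetaColumns()
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("metadata missing required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id in metadata")
    for (col in names(.metaLevels)) {
        vals <- df[[col]]
        ok <- is.na(vals) | vals %in% .metaLevels[[col]]
        if (!all(ok))
            stop("unknown level in '", col, "': ",
                 paste(unique(vals[!ok]), collapse = ", "))
        if (col == "sex" && anyNA(vals)) stop("sex must not be missing")
    }
    for (col in .metaFlags) {
        v <- df[[col]]
        if (anyNA(v) || !all(v %in% c(0L, 1L)))
            stop("flag '", col, "' must be 0/1 with no missing values")
    }
    for (col in .metaFlagsNA) {
        v <- df[[col]]
        if (!all(is.na(v) | v %in% c(0L, 1L)))
            stop("flag '", col, "' must be 0/1 or missing")
    }
    if (!all(is.na(df$bmi) | (df$bmi > 5 & df$bmi < 80)))
        stop("implausible BMI value")
    if (!all(is.na(df$cesd) | (df$cesd >= 0 & abs(df$cesd - round(df$cesd)) < 1e-8)))
        stop("CES-D must be a non-negative integer")
    df
}

#' Read per-sample questionnaire metadata
#'
#' Comma-separated text with a header naming all required columns
#' (see \code{\link{metadataFields}}).  Empty numeric fields (BMI, CES-D)
#' are stored as missing, not zero; unknown categorical levels are
#' errors.
#'
#' @param path file path
#' @return validated data.frame, one row per sample
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) stop("metadata file not found: ", path)
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
    for (col in intersect(c(.metaFlags, .metaFlagsNA, "age", "cesd"), names(df)))
        df[[col]] <- as.integer(df[[col]])
    if ("bmi" %in% names(df)) df$bmi <- as.numeric(df$bmi)
    if ("sample_id" %in% names(df)) df$sample_id <- as.character(df$sample_id)
    .validateMetadata(df)
}

#' Write per-sample questionnaire metadata
#'
#' @param meta metadata data.frame
#' @param path destination file
#' @export
writeSampleMetadata <- function(meta, path) {
    write.csv(meta, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}
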