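## Analysis-group assignment from questionnaire metadata.
##
## Each sample of the requested sex is assigned the first group, in the
## order NC, AS, AM, OD, whose full criteria set it satisfies; anything
## else (including all samples of the other sex) is "excluded".  A
## missing value in a field a criterion needs counts as "criterion not
## satisfied" for the health-requiring NC conditions, and as "does not
## contribute an other-disease marker" inside the other-disease
## definition, so that a lone missing BMI cannot promote a sample.

.criterionColumns <- list(
    NC1 = c("atopic_dermatitis", "other_disease"),
    NC2 = "medication", NC3 = "bmi", NC4 = "cesd",
    NC5 = "hospitalization_surgery", NC6 = "helicobacter_treatment",
    NC7 = "insomnia_consultation", NC8 = "defecation_frequency",
    NC9 = "alcohol_frequency", NC10 = "smoking_history",
    NC11 = c("menstrual_status", "age"), NC12 = "menstruating_at_collection",
    NC13 = "pregnant_or_breastfeeding",
    AS1 = "atopic_dermatitis",
    AS2 = c("other_disease", "bmi", "cesd", "colorectal_surgery_history"),
    AS3 = "medication", AS4 = "pregnant_or_breastfeeding",
    AM1 = "atopic_dermatitis",
    AM2 = c("other_disease", "bmi", "cesd", "colorectal_surgery_history"),
    AM3 = "medication", AM4 = "pregnant_or_breastfeeding",
    OD1 = "atopic_dermatitis",
    OD2 = c("other_disease", "bmi", "cesd", "colorectal_surgery_history"),
    OD3 = "medication", OD4 = "pregnant_or_breastfeeding")

.naFalse <- function(x) !is.na(x) & x

#' Assign samples to the NC/AS/AM/OD analysis groups
#'
#' Evaluates, for every sample of the chosen sex, the thirteen
#' normal-control conditions (NC1-NC13; NC11-NC13 female-only), then the
#' four conditions of each patient group: atopic dermatitis without
#' other disease (AS), with other disease (AM), and other disease without
#' atopic dermatitis (OD).  The first fully satisfied group wins; BMI
#' outside [18.5, 25), CES-D >= 16, and prior colorectal cancer/polyp
#' surgery count as "other disease" for the patient groups.  All groups
#' require that no prescription or over-the-counter drugs are taken, so a
#' medicated sample is excluded.  Samples of the other sex are excluded.
#'
#' @param meta metadata data.frame (see \code{\link{readSampleMetadata}})
#' @param sex "female" or "male"; female-only criteria are skipped for
#'   males
#' @return data.frame with columns \code{sample}, \code{label}
#'   (NC/AS/AM/OD/excluded) and \code{failed} (semicolon-separated ids of
#'   failed criteria; empty for assigned samples)
#' @export
assignGroups <- function(meta, sex = c("female", "male")) {
    sex <- match.arg(sex)
    meta <- as.data.frame(meta)
    crits <- names(.criterionColumns)
    if (sex == "male")
        crits <- setdiff(crits, c("NC11", "NC12", "NC13", "AS4", "AM4", "OD4"))
    for (cr in crits) {
        miss <- setdiff(.criterionColumns[[cr]], names(meta))
        if (length(miss))
            stop("criterion ", cr, " needs missing metadata column(s): ",
                 paste(miss, collapse = ", "))
    }
    if (!all(c("sample_id", "sex") %in% names(meta)))
        stop("metadata needs sample_id and sex columns")

    n <- nrow(meta)
    sexOK <- meta$sex == sex
    otherDisease <- .naFalse(meta$other_disease == 1) |
        .naFalse(meta$bmi < 18.5) | .naFalse(meta$bmi >= 25) |
        .naFalse(meta$cesd >= 16) |
        .naFalse(meta$colorectal_surgery_history == 1)

    ok <- list(
        NC1 = .naFalse(meta$atopic_dermatitis == 0) &
              .naFalse(meta$other_disease == 0),
        NC2 = .naFalse(meta$medication == 0),
        NC3 = .naFalse(meta$bmi >= 18.5 & meta$bmi < 25),
        NC4 = .naFalse(meta$cesd < 16),
        NC5 = .naFalse(meta$hospitalization_surgery == 0),
        NC6 = .naFalse(meta$helicobacter_treatment == 0),
        NC7 = .naFalse(meta$insomnia_consultation == 0),
        NC8 = .naFalse(meta$defecation_frequency %in%
                       c("1_2_per_day", "4_6_per_week")),
        NC9 = .naFalse(meta$alcohol_frequency %in%
                       c("none", "light_5_or_fewer_days")),
        NC10 = .naFalse(meta$smoking_history == 0),
        NC11 = .naFalse(meta$menstrual_status == "regular") |
               (.naFalse(meta$menstrual_status == "menopause") &
                .naFalse(meta$age >= 40)),
        NC12 = .naFalse(meta$menstruating_at_collection == 0),
        NC13 = .naFalse(meta$pregnant_or_breastfeeding == 0),
        AS1 = .naFalse(meta$atopic_dermatitis == 1),
        AS2 = !otherDisease,
        AS3 = .naFalse(meta$medication == 0),
        AS4 = .naFalse(meta$pregnant_or_breastfeeding == 0),
        AM1 = .naFalse(meta$atopic_dermatitis == 1),
        AM2 = otherDisease,
        AM3 = .naFalse(meta$medication == 0),
        AM4 = .naFalse(meta$pregnant_or_breastfeeding == 0),
        OD1 = .naFalse(meta$atopic_dermatitis == 0),
        OD2 = otherDisease,
        OD3 = .naFalse(meta$medication == 0),
        OD4 = .naFalse(meta$pregnant_or_breastfeeding == 0))
    ok <- ok[crits]

    groupsOf <- list(NC = grep("^NC", crits, value = TRUE),
                     AS = grep("^AS", crits, value = TRUE),
                     AM = grep("^AM", crits, value = TRUE),
                     OD = grep("^OD", crits, value = TRUE))
    label <- rep("excluded", n)
    failed <- character(n)
    critMat <- do.call(cbind, ok)     # n x criteria
    for (i in seq_len(n)) {
        if (!sexOK[i]) { failed[i] <- "SEX"; next }
        fails <- crits[!critMat[i, ]]
        assigned <- FALSE
        for (g in names(groupsOf)) {
            if (!any(groupsOf[[g]] %in% fails)) {
                label[i] <- g
                assigned <- TRUE
                break
            }
        }
        if (!assigned) failed[i] <- paste(fails, collapse = ";")
    }
    data.frame(sample = as.character(meta$sample_id), label = label,
               failed = failed, stringsAsFactors = FALSE)
}

#' Write a group assignment as two-column CSV
#'
#' @param ga result of \code{\link{assignGroups}}
#' @param path destination file
#' @export
writeGroupAssignment <- function(ga, path) {
    write.csv(ga[, c("sample", "label")], path, row.names = FALSE,
              quote = FALSE)
    invisible(path)
}
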