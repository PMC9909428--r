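#' Default pipeline configuration
#'
#' All randomness flows from the single root \code{seed}: the CLR /
#' marker-selection stage uses it directly and the split and balancing
#' stages use fixed offsets from it, so a run is reproducible
#' end-to-end.
#'
#' @param seed root seed (default 1234, also the default of the CLR
#'   stage)
#' @param clr list(nInstances, prior)
#' @param selection list(reps, k)
#' @param sem list(alpha, rmseaMax)
#' @param risk list(frac, smoteK, overPct, underPct, features)
#' @return nested configuration list
#' @export
pipelineConfig <- function(seed = 1234L,
                           clr = list(nInstances = 128L, prior = 0.5),
                           selection = list(reps = 500L, k = 20L),
                           sem = list(alpha = 0.05, rmseaMax = 0.08),
                           risk = list(frac = 0.8, smoteK = 5L,
                                       overPct = 200, underPct = 200,
                                       features = list("lv1", "lv2",
                                                       c("lv1", "lv2")))) {
    list(seed = as.integer(seed), clr = clr, selection = selection,
         sem = sem, risk = risk)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "': ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full latent-biomarker pipeline
#'
#' Orchestrates group assignment, marker stability selection between the
#' healthy controls (NC) and the disease-only group (AS), the DWLS SEM
#' on the merged NC + AS data with backward modification, measurement
#' model extraction and Bartlett scoring of all four groups, and the
#' stratified-split / SMOTE / logistic-regression / ROC risk stage for
#' each configured feature set.
#'
#' When the SEM cannot be constructed (no admissible model), the report
#' records that and the scoring and risk stages are skipped.
#'
#' @param counts a \linkS4class{MicrobiomeCounts} or path to a count
#'   table
#' @param metadata per-sample metadata data.frame or path (defaults to
#'   the colData of \code{counts})
#' @param sex which sex stratum to analyze
#' @param config from \code{\link{pipelineConfig}}
#' @param markers optional \linkS4class{StableMarkers} or named effect
#'   vector; when supplied the selection stage is skipped
#' @param outdir optional directory: every intermediate artifact is
#'   written as plain text (counts are left untouched)
#' @return report list with per-stage outputs: groups, markers, spec,
#'   fit, measurement model, scores, group comparisons, risk results per
#'   feature set, and flags
#' @export
runPipeline <- function(counts, metadata = NULL, sex = "female",
                        config = pipelineConfig(), markers = NULL,
                        outdir = NULL) {
    if (is.character(counts)) {
        if (!file.exists(counts))
            stop("pipeline stage 'input': counts file not found: ", counts)
        counts <- readCountTable(counts)
    }
    if (is.character(metadata)) metadata <- readSampleMetadata(metadata)
    if (is.null(metadata)) {
        metadata <- as.data.frame(SummarizedExperiment::colData(counts))
        if (!nrow(metadata) || !"sample_id" %in% names(metadata))
            stop("pipeline stage 'input': no metadata available")
    }
    report <- list(config = config,
                   reducedReplication = config$selection$reps < 50L)

    ga <- .stage("groups", assignGroups(metadata, sex))
    report$groups <- ga
    grp <- setNames(ga$label, ga$sample)
    cm <- counts(counts)
    ncas <- ga$sample[ga$label %in% c("NC", "AS")]
    if (length(ncas) < 8L)
        stop("pipeline stage 'groups': too few NC/AS samples (",
             length(ncas), ")")

    if (is.null(markers)) {
        markers <- .stage("selection", stableMarkerSelection(
            cm[, ncas, drop = FALSE],
            factor(grp[ncas], levels = c("NC", "AS")),
            reps = config$selection$reps, k = config$selection$k,
            baseSeed = config$seed,
            nInstances = config$clr$nInstances, prior = config$clr$prior))
    }
    report$markers <- markers
    spec <- .stage("model spec", buildModelSpec(markers))
    report$spec <- spec

    ensNCAS <- .stage("clr", clrEnsemble(
        cm[, ncas, drop = FALSE], nInstances = config$clr$nInstances,
        prior = config$clr$prior, seed = config$seed))
    clrNCAS <- clrPointEstimate(ensNCAS)
    yNCAS <- as.integer(grp[ncas] == "AS")

    fit0 <- .stage("sem fit", fitSem(spec, clrNCAS, yNCAS))
    report$startFit <- fit0
    fit <- tryCatch(
        modifyModel(fit0, clrNCAS, yNCAS, alpha = config$sem$alpha,
                    rmseaMax = config$sem$rmseaMax),
        error = function(e) e)
    if (inherits(fit, "error")) {
        report$semConstructed <- FALSE
        report$semError <- conditionMessage(fit)
        if (!is.null(outdir)) .writePipelineOutputs(report, outdir)
        return(report)
    }
    report$semConstructed <- TRUE
    report$fit <- fit
    report$measurement <- extractMeasurementModel(fit)

    scored <- ga$sample[ga$label %in% c("NC", "AS", "AM", "OD")]
    ensAll <- .stage("scoring clr", clrEnsemble(
        cm[, scored, drop = FALSE], nInstances = config$clr$nInstances,
        prior = config$clr$prior, seed = config$seed))
    clrAll <- clrPointEstimate(ensAll)
    scores <- .stage("scoring", bartlettScores(
        report$measurement, clrAll, groups = grp[scored]))
    report$scores <- scores
    report$comparisons <- .stage("comparison", compareGroups(scores))

    label <- setNames(as.integer(grp[scored] %in% c("AS", "AM")),
                      scored)
    split <- .stage("split", stratifiedSplit(scores,
        frac = config$risk$frac, seed = config$seed + 1L))
    report$split <- split
    tr <- scores[match(split$train, scores$sample), ]
    te <- scores[match(split$test, scores$sample), ]
    risk <- list()
    for (fs in config$risk$features) {
        key <- paste(fs, collapse = "+")
        bal <- .stage("smote", smoteBalance(
            tr[, fs, drop = FALSE], label[tr$sample],
            k = config$risk$smoteK, overPct = config$risk$overPct,
            underPct = config$risk$underPct, seed = config$seed + 2L))
        rm <- .stage("logistic", fitRiskModel(bal$x, bal$y, features = fs))
        prob <- predictRisk(rm, te[, fs, drop = FALSE])
        roc <- .stage("roc", rocAuc(prob, label[te$sample]))
        risk[[key]] <- list(features = fs, coef = rm$coef, roc = roc,
                            prob = setNames(prob, te$sample))
    }
    report$risk <- risk
    if (!is.null(outdir)) .writePipelineOutputs(report, outdir)
    report
}

.writePipelineOutputs <- function(report, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeGroupAssignment(report$groups, file.path(outdir, "groups.csv"))
    if (!is.null(report$markers))
        writeStableMarkers(report$markers, file.path(outdir, "markers.csv"))
    if (isTRUE(report$semConstructed)) {
        writeParameterTable(report$fit, file.path(outdir, "parameters.csv"))
        fi <- report$fit@fit
        write.csv(data.frame(index = names(fi),
                             value = unlist(fi)),
                  file.path(outdir, "fit_indices.csv"), row.names = FALSE)
        writeMeasurementModel(report$measurement,
                              file.path(outdir, "measurement_model.txt"))
        writeScoreTable(report$scores, file.path(outdir, "scores.csv"))
        write.csv(report$comparisons, file.path(outdir, "comparisons.csv"),
                  row.names = FALSE)
        auc <- do.call(rbind, lapply(names(report$risk), function(k) {
            r <- report$risk[[k]]
            data.frame(features = k, auc = r$roc$auc,
                       ci_lower = r$roc$ci["lower"],
                       ci_upper = r$roc$ci["upper"])
        }))
        write.csv(auc, file.path(outdir, "auc.csv"), row.names = FALSE)
        for (k in names(report$risk))
            write.csv(report$risk[[k]]$roc$curve,
                      file.path(outdir, paste0("roc_", gsub("\\+", "_", k),
                                               ".csv")),
                      row.names = FALSE)
    } else if (!is.null(report$semError)) {
        writeLines(report$semError, file.path(outdir, "sem_error.txt"))
    }
    invisible(outdir)
}
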