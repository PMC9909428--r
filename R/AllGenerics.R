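#' @importFrom BiocGenerics counts
NULL

#' Extract the count matrix
#'
#' @param object a \linkS4class{MicrobiomeCounts}
#' @return genus x sample integer matrix
#' @export
setMethod("counts", "MicrobiomeCounts", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

#' Number of Monte-Carlo instances in a CLR ensemble
#' @param object a \linkS4class{ClrEnsemble}
#' @export
setGeneric("nInstances", function(object) standardGeneric("nInstances"))

#' @rdname nInstances
#' @export
setMethod("nInstances", "ClrEnsemble", function(object) dim(object@values)[3L])

#' Genus labels
#' @param object an object with genera
#' @export
setGeneric("genera", function(object) standardGeneric("genera"))

#' @rdname genera
#' @export
setMethod("genera", "MicrobiomeCounts", function(object) rownames(object))

#' @rdname genera
#' @export
setMethod("genera", "ClrEnsemble", function(object) dimnames(object@values)[[2L]])

#' @rdname genera
#' @export
setMethod("genera", "StableMarkers", function(object) object@genera)

#' Standardized parameter table of a fitted SEM
#'
#' One row per parameter of the standardized solution (factor loadings,
#' outcome paths, residual variances, latent variances and covariance)
#' with columns lhs, op, rhs, est, se, z, p, ci.lower, ci.upper.
#'
#' @param object a \linkS4class{FittedSem}
#' @export
setGeneric("parameterTable", function(object) standardGeneric("parameterTable"))

#' @rdname parameterTable
#' @export
setMethod("parameterTable", "FittedSem", function(object) object@estimates)

#' Fit indices of a fitted SEM
#'
#' @param object a \linkS4class{FittedSem}
#' @return list with chi2, df, gfi, agfi, rmsea
#' @export
setGeneric("fitIndices", function(object) standardGeneric("fitIndices"))

#' @rdname fitIndices
#' @export
setMethod("fitIndices", "FittedSem", function(object) object@fit)

#' Convergence flag of a fitted SEM
#' @param object a \linkS4class{FittedSem}
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname isConverged
#' @export
setMethod("isConverged", "FittedSem", function(object) object@converged)

#' Serialize a model in the lavaan-style text grammar
#'
#' \code{SemSpec} serializes with free parameters
#' (\code{lv1 =~ g1 + g2}); \code{MeasurementModel} with fixed
#' coefficients (\code{lv1 =~ 0.54*g1 + ...}).
#'
#' @param object a \linkS4class{SemSpec} or \linkS4class{MeasurementModel}
#' @return character vector of model lines
#' @export
setGeneric("semSyntax", function(object) standardGeneric("semSyntax"))

#' Bartlett factor scores
#'
#' @param object a \linkS4class{MeasurementModel} (or
#'   \linkS4class{FittedSem}, which additionally uses the outcome column)
#' @param clr sample x genus matrix of CLR values (point estimates)
#' @param ... further arguments (\code{groups}, \code{outcome})
#' @return data.frame with columns sample, lv1, lv2 and (if given) group
#' @export
setGeneric("bartlettScores",
    function(object, clr, ...) standardGeneric("bartlettScores"))

setMethod("show", "ClrEnsemble", function(object) {
    d <- dim(object@values)
    cat("ClrEnsemble:", d[1L], "samples x", d[2L], "genera x", d[3L],
        "instances\n  mode:", object@mode, " prior:", object@prior,
        " seed:", object@seed, "\n")
})

setMethod("show", "StableMarkers", function(object) {
    cat("StableMarkers: ", length(object@genera), " genera stable across ",
        object@reps, " repetitions (top-", object@k, ")\n", sep = "")
    if (length(object@genera))
        print(round(object@meanEffect, 3))
})

setMethod("show", "SemSpec", function(object) {
    cat("SemSpec\n")
    cat("  lv1 =~", paste(object@lv1, collapse = " + "), "\n")
    cat("  lv2 =~", paste(object@lv2, collapse = " + "), "\n")
    cat(" ", object@outcome, "~ lv1 + lv2\n  lv1 ~~ lv2\n")
    if (object@underIdentified)
        cat("  [flagged under-identified: a latent has < 2 indicators]\n")
})

setMethod("show", "FittedSem", function(object) {
    cat("FittedSem (DWLS, standardized), N =", object@N, "\n")
    cat("  converged:", object@converged,
        if (length(object@heywood))
            paste0(" heywood: ", paste(object@heywood, collapse = ", "))
        else "", "\n")
    f <- object@fit
    cat(sprintf("  chi2 = %.3f (df = %d), GFI = %.3f, AGFI = %s, RMSEA = %.3f\n",
                f$chi2, f$df, f$gfi,
                ifelse(is.na(f$agfi), "NA", sprintf("%.3f", f$agfi)),
                f$rmsea))
    est <- object@estimates
    print(est[est$op %in% c("=~", "~"), ], row.names = FALSE, digits = 3)
})

setMethod("show", "MeasurementModel", function(object) {
    cat("MeasurementModel (fixed parameters)\n")
    for (ln in semSyntax(object)) cat(" ", ln, "\n")
})
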