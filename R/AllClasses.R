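#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor dnorm qnorm pnorm median rnorm rgamma rmultinom
#'   rbinom runif sd nlminb optim glm binomial predict as.formula setNames
#'   dist quantile
#' @importFrom utils combn read.delim write.table read.csv write.csv
NULL

#' Genus-level microbiome count table
#'
#' \code{MicrobiomeCounts} holds a genus x sample matrix of non-negative
#' integer read counts in the \code{"counts"} assay of a
#' \linkS4class{SummarizedExperiment}, with per-sample questionnaire
#' metadata (if any) in \code{colData}.  Rows are genera, columns are
#' samples.
#'
#' Validity requires: a \code{"counts"} assay of non-negative integral
#' values, at least 2 genera and 2 samples, and unique, non-empty row and
#' column names.
#'
#' @seealso \code{\link{readCountTable}}, \code{\link{simulateCommunity}}
#' @export
setClass("MicrobiomeCounts", contains = "SummarizedExperiment")

setValidity("MicrobiomeCounts", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (nrow(m) < 2L || ncol(m) < 2L)
        return("need at least 2 genera and 2 samples")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("genus labels must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        return("sample ids must be present and unique")
    if (anyNA(m) || any(m < 0))
        return("counts must be non-negative and non-missing")
    if (any(abs(m - round(m)) > 1e-8))
        return("counts must be integers")
    TRUE
})

#' Monte-Carlo Dirichlet CLR ensemble
#'
#' A sample x genus x instance array of centered log-ratio values (log2
#' units).  Each instance is the CLR of one composition drawn from
#' Dirichlet(counts + prior) for each sample; the deterministic
#' "expected" mode stores a single instance computed from the expected
#' proportions.  For every sample and instance the CLR values sum to zero
#' across genera.
#'
#' @slot values numeric array, sample x genus x instance
#' @slot prior numeric, pseudo-count added to every cell
#' @slot mode character, "montecarlo" or "expected"
#' @slot seed integer seed used for the Dirichlet draws
#' @export
setClass("ClrEnsemble",
    representation(values = "array", prior = "numeric", mode = "character",
                   seed = "integer"))

setValidity("ClrEnsemble", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be a 3-d array")
    dn <- dimnames(v)
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
        return("sample and genus dimnames are required")
    ## zero-sum per sample per instance (loose here; tests assert 1e-9)
    z <- apply(v, c(1L, 3L), sum)
    if (max(abs(z)) > 1e-6) return("CLR values must sum to zero per sample")
    TRUE
})

#' Stable marker genera
#'
#' The genera appearing in the top-k list (by absolute effect size) of
#' every one of \code{reps} independently re-randomized effect-size
#' computations, with their mean effect over the repetitions.
#'
#' @slot genera character, the surviving genera (decreasing |mean effect|)
#' @slot meanEffect named numeric, mean effect per surviving genus
#' @slot reps integer, number of repetitions
#' @slot k integer, list length per repetition
#' @export
setClass("StableMarkers",
    representation(genera = "character", meanEffect = "numeric",
                   reps = "integer", k = "integer"))

setValidity("StableMarkers", function(object) {
    if (length(object@genera) != length(object@meanEffect))
        return("genera and meanEffect lengths differ")
    if (length(object@genera) > object@k)
        return("more markers than k")
    TRUE
})

#' Two-latent-variable SEM specification
#'
#' Indicators split between two latent variables (lv1, expected to push
#' the outcome up; lv2, expected to push it down), a binary outcome
#' regressed on both latents, and a free lv1-lv2 covariance.
#'
#' @slot lv1 character, indicator genera of lv1
#' @slot lv2 character, indicator genera of lv2
#' @slot outcome character scalar, name of the binary outcome variable
#' @slot underIdentified logical, TRUE when a latent has < 2 indicators
#'   (such a spec is valid but flagged: a free fit is not identified)
#' @export
setClass("SemSpec",
    representation(lv1 = "character", lv2 = "character",
                   outcome = "character", underIdentified = "logical"))

setValidity("SemSpec", function(object) {
    if (length(object@lv1) < 1L || length(object@lv2) < 1L)
        return("each latent variable needs at least one indicator")
    if (length(intersect(object@lv1, object@lv2)) > 0L)
        return(paste("indicator assigned to both latent variables:",
                     paste(intersect(object@lv1, object@lv2), collapse = ", ")))
    if (anyDuplicated(c(object@lv1, object@lv2)))
        return("duplicated indicator")
    if (length(object@outcome) != 1L)
        return("exactly one outcome variable")
    TRUE
})

#' Fitted structural equation model
#'
#' Result of the diagonally weighted least-squares fit of a
#' \linkS4class{SemSpec} to CLR data and a binary outcome.  All estimates
#' are standardized (latent variances 1, observed variables standardized),
#' so each indicator satisfies loading^2 + residual variance = 1.
#'
#' @slot spec the fitted \linkS4class{SemSpec}
#' @slot estimates data.frame with columns lhs, op, rhs, est, se, z, p,
#'   ci.lower, ci.upper (the standardized solution)
#' @slot fit list with chi2, df, gfi, agfi, rmsea
#' @slot N integer, number of samples
#' @slot converged logical
#' @slot heywood character, variables with a negative estimated variance
#'   component (empty when the solution is admissible)
#' @slot standardization list with per-indicator center/scale used for
#'   standardizing observed variables (frozen for later scoring)
#' @slot sampleCorr the sample correlation matrix that was fitted
#'   (Pearson among indicators, polyserial against the outcome)
#' @slot discrepancy numeric, DWLS discrepancy at the optimum
#' @slot deletionLog character, indicators removed during model
#'   modification (empty for a direct fit)
#' @export
setClass("FittedSem",
    representation(spec = "SemSpec", estimates = "data.frame", fit = "list",
                   N = "integer", converged = "logical", heywood = "character",
                   standardization = "list", sampleCorr = "matrix",
                   discrepancy = "numeric", deletionLog = "character"))

#' Frozen measurement model
#'
#' The measurement-equation part of a fitted SEM with all parameters fixed
#' at their standardized estimates: loadings, residual variances, and the
#' latent covariance.  The outcome variable and its paths are dropped, so
#' any sample can be scored without knowing its disease status.  The
#' standardization moments of the fitting population are carried along and
#' reused for new samples.
#'
#' @slot loadings numeric matrix, indicators x latents, zero off-block
#' @slot theta named numeric, residual variance per indicator (> 0)
#' @slot latentCov numeric in (-1, 1), covariance of the two unit-variance
#'   latents
#' @slot center,scale named numeric, per-indicator standardization moments
#' @export
setClass("MeasurementModel",
    representation(loadings = "matrix", theta = "numeric",
                   latentCov = "numeric", center = "numeric",
                   scale = "numeric"))

setValidity("MeasurementModel", function(object) {
    L <- object@loadings
    if (ncol(L) != 2L) return("two latent variables expected")
    if (is.null(rownames(L))) return("loadings need indicator rownames")
    if (any(rowSums(L != 0) != 1L))
        return("each indicator must load on exactly one latent")
    if (!identical(names(object@theta), rownames(L)))
        return("theta names must match loading rownames")
    if (any(object@theta <= 0))
        return("residual variances must be positive")
    if (abs(object@latentCov) >= 1)
        return("latent covariance must lie in (-1, 1)")
    if (!identical(names(object@center), rownames(L)) ||
        !identical(names(object@scale), rownames(L)))
        return("center/scale names must match indicators")
    if (any(object@scale <= 0)) return("scales must be positive")
    TRUE
})
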