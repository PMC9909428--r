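## Backward model modification for the two-latent-variable SEM.
##
## Phase 1 removes indicators while any negative variance component
## (Heywood case) is present, most negative first.  Phase 2 removes
## indicators whose standardized loading is not significant, largest
## p-value first.  Among all admissible models visited, the one with the
## largest total absolute outcome path coefficient subject to an RMSEA
## ceiling is returned.

.dropIndicator <- function(spec, genus) {
    semSpec(setdiff(spec@lv1, genus), setdiff(spec@lv2, genus),
            spec@outcome)
}

.loadingPvals <- function(f) {
    est <- f@estimates
    ld <- est[est$op == "=~", ]
    setNames(ld$p, ld$rhs)
}

.pathPvals <- function(f) {
    est <- f@estimates
    setNames(est$p[est$op == "~"], est$rhs[est$op == "~"])
}

.indicatorResiduals <- function(f) {
    est <- f@estimates
    rs <- est[est$op == "~~" & est$lhs == est$rhs &
              !(est$lhs %in% c("lv1", "lv2", f@spec@outcome)), ]
    setNames(rs$est, rs$lhs)
}

.isAdmissible <- function(f, alpha, rmseaMax, pathAlpha) {
    if (!f@converged) return(FALSE)
    if (length(f@heywood)) return(FALSE)
    if (length(f@spec@lv1) < 2L || length(f@spec@lv2) < 2L) return(FALSE)
    lp <- .loadingPvals(f)
    if (any(is.na(lp)) || any(lp >= alpha)) return(FALSE)
    if (is.na(f@fit$rmsea) || f@fit$rmsea >= rmseaMax) return(FALSE)
    pp <- .pathPvals(f)
    ## the outcome must be connected to at least one latent; when every
    ## path p-value is large the model does not explain the outcome
    if (all(is.na(pp)) || min(pp, na.rm = TRUE) >= pathAlpha) return(FALSE)
    TRUE
}

#' Backward modification of a fitted SEM
#'
#' Starting from \code{f}, indicators are deleted one at a time and the
#' model refitted: first while any negative variance component exists
#' (the indicator with the most negative residual variance goes first),
#' then while any standardized loading has p >= \code{alpha} (largest p
#' first).  Every fit along the way is recorded; among the admissible
#' ones (converged, no Heywood case, at least two indicators per latent,
#' all loadings significant at \code{alpha}, RMSEA below
#' \code{rmseaMax}, and at least one outcome path with p <
#' \code{pathAlpha}) the fit maximizing the total absolute standardized
#' outcome path coefficient is returned, with the deletions logged in
#' \code{deletionLog}.
#'
#' If no visited model is admissible — in particular when the outcome is
#' unrelated to every indicator, so that all outcome-path p-values stay
#' large — the model cannot be constructed and an error is raised.
#'
#' @param f starting \linkS4class{FittedSem}
#' @param clr,outcome the data used for refitting (as in
#'   \code{\link{fitSem}})
#' @param alpha significance level for loadings (default 0.05)
#' @param rmseaMax RMSEA admissibility ceiling (default 0.08, the
#'   conventional adequate-fit bound)
#' @param pathAlpha outcome-connection threshold (default 0.1): a model
#'   whose outcome paths all have p at or above this is inadmissible
#' @return the selected \linkS4class{FittedSem}
#' @export
modifyModel <- function(f, clr, outcome, alpha = 0.05, rmseaMax = 0.08,
                        pathAlpha = 0.1) {
    stopifnot(is(f, "FittedSem"))
    visited <- list(f)
    log <- character(0)
    cur <- f

    refitDropping <- function(genus, why) {
        if (!length(setdiff(cur@spec@lv1, genus)) ||
            !length(setdiff(cur@spec@lv2, genus)))
            return(NULL)                 # cannot empty a latent entirely
        spec2 <- .dropIndicator(cur@spec, genus)
        f2 <- fitSem(spec2, clr, outcome)
        log <<- c(log, paste0(genus, " (", why, ")"))
        visited[[length(visited) + 1L]] <<- f2
        f2
    }

    ## phase 1: Heywood cases.  An indicator with a negative residual is
    ## deleted directly (most negative first); a negative outcome
    ## residual (paths exhausting the outcome variance, typical of weak
    ## noise-laden latents) is attacked by deleting the indicator with
    ## the weakest loading.
    repeat {
        if (!length(cur@heywood)) break
        res <- .indicatorResiduals(cur)
        neg <- res[res < 0]
        if (length(neg)) {
            worst <- names(neg)[which.min(neg)]
            why <- "negative variance"
        } else {
            ## outcome residual negative or latent covariance collapsed:
            ## attack the weakest measurement
            lp <- .loadingPvals(cur)
            worst <- names(lp)[which.max(ifelse(is.na(lp), 1, lp))]
            why <- paste0("inadmissible component (",
                          paste(cur@heywood, collapse = "/"),
                          "); weakest loading")
        }
        nxt <- refitDropping(worst, why)
        if (is.null(nxt)) break
        cur <- nxt
    }
    ## phase 2: non-significant loadings
    repeat {
        lp <- .loadingPvals(cur)
        bad <- lp[is.na(lp) | lp >= alpha]
        if (!length(bad)) break
        worst <- names(bad)[which.max(ifelse(is.na(bad), 1, bad))]
        nxt <- refitDropping(worst, sprintf("loading p = %.3g", lp[worst]))
        if (is.null(nxt)) break
        cur <- nxt
    }

    adm <- Filter(function(x) .isAdmissible(x, alpha, rmseaMax, pathAlpha),
                  visited)
    if (!length(adm))
        stop("model could not be constructed: no admissible model ",
             "(all candidates failed convergence, admissibility, fit or ",
             "outcome-path significance)")
    score <- vapply(adm, function(x) sum(abs(.fittedPaths(x))), numeric(1))
    best <- adm[[which.max(score)]]
    best@deletionLog <- log
    best
}
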