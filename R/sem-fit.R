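#' Build a two-latent-variable SEM specification from marker effects
#'
#' Genera with a positive effect (higher CLR abundance in the affected
#' group) become indicators of lv1, the latent assumed to push the
#' outcome up; genera with a negative effect (higher in controls) become
#' indicators of lv2, the latent assumed to push it down.  The binary
#' outcome is regressed on both latents and the lv1-lv2 covariance is
#' left free.
#'
#' @param markers a \linkS4class{StableMarkers} or a named numeric vector
#'   of (mean) effects
#' @param outcome name of the binary outcome variable (default
#'   "atopic_dermatitis")
#' @return a \linkS4class{SemSpec}; flagged under-identified when a
#'   latent ends up with fewer than 2 indicators
#' @export
buildModelSpec <- function(markers, outcome = "atopic_dermatitis") {
    eff <- if (is(markers, "StableMarkers")) markers@meanEffect else markers
    if (is.null(names(eff)) || !is.numeric(eff))
        stop("markers must be a named numeric vector or StableMarkers")
    lv1 <- names(eff)[eff > 0]
    lv2 <- names(eff)[eff < 0]
    if (!length(lv1) || !length(lv2))
        stop("need at least one positive-effect and one negative-effect genus")
    semSpec(lv1, lv2, outcome)
}

#' Construct a SEM specification directly
#'
#' @param lv1,lv2 character vectors of indicator genera (disjoint)
#' @param outcome binary outcome variable name
#' @return a \linkS4class{SemSpec}
#' @export
semSpec <- function(lv1, lv2, outcome = "atopic_dermatitis") {
    new("SemSpec", lv1 = as.character(lv1), lv2 = as.character(lv2),
        outcome = outcome,
        underIdentified = length(lv1) < 2L || length(lv2) < 2L)
}

## two-step polyserial correlation between a continuous x and binary y:
## threshold from the sample prevalence, then the point-biserial
## correlation rescaled by sqrt(p q) / phi(tau).
.polyserial <- function(x, y) {
    p <- mean(y)
    tau <- qnorm(1 - p)
    r <- cor(x, y)
    rho <- r * sqrt(p * (1 - p)) / dnorm(tau)
    max(-0.999, min(0.999, rho))
}

## asymptotic variance of a correlation estimate; the polyserial variant
## inflates the Pearson formula by p q / phi(tau)^2 (exact at rho = 0).
.corrAvar <- function(rho, N, p = NULL) {
    base <- (1 - rho^2)^2 / N
    if (is.null(p)) return(base)
    tau <- qnorm(1 - p)
    base * p * (1 - p) / dnorm(tau)^2
}

## internal model structure: variables are c(indicators, outcome); lvOf
## maps each indicator to 1 or 2; pairs is the 2 x npair index matrix of
## the fitted (lower-triangle) correlations.
.semStructure <- function(spec) {
    ind <- c(spec@lv1, spec@lv2)
    lvOf <- c(rep(1L, length(spec@lv1)), rep(2L, length(spec@lv2)))
    vars <- c(ind, spec@outcome)
    q <- length(vars)
    pairs <- combn(q, 2L)
    list(ind = ind, lvOf = lvOf, vars = vars, q = q, pairs = pairs,
         nInd = length(ind), outIdx = q)
}

## implied correlations for parameter vector theta = (a_1..a_p, b1, b2, c)
.impliedCorr <- function(theta, st) {
    p <- st$nInd
    a <- theta[seq_len(p)]
    b <- theta[p + 1:2]
    cc <- theta[p + 3L]
    lv <- st$lvOf
    sig <- numeric(ncol(st$pairs))
    for (j in seq_len(ncol(st$pairs))) {
        i1 <- st$pairs[1L, j]; i2 <- st$pairs[2L, j]
        if (i2 <= p) {                       # indicator - indicator
            sig[j] <- if (lv[i1] == lv[i2]) a[i1] * a[i2]
                      else a[i1] * a[i2] * cc
        } else {                             # indicator - outcome
            k <- lv[i1]; o <- 3L - k
            sig[j] <- a[i1] * (b[k] + cc * b[o])
        }
    }
    sig
}

## numeric Jacobian of the implied correlations (central differences)
.impliedJacobian <- function(theta, st, h = 1e-6) {
    f0 <- .impliedCorr(theta, st)
    J <- matrix(0, length(f0), length(theta))
    for (j in seq_along(theta)) {
        tp <- tm <- theta
        tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
        J[, j] <- (.impliedCorr(tp, st) - .impliedCorr(tm, st)) / (2 * h)
    }
    J
}

.estRow <- function(lhs, op, rhs, est, se) {
    z <- if (is.na(se) || se == 0) NA_real_ else est / se
    p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
    data.frame(lhs = lhs, op = op, rhs = rhs, est = est, se = se, z = z,
               p = p,
               ci.lower = if (is.na(se)) est else est - 1.959964 * se,
               ci.upper = if (is.na(se)) est else est + 1.959964 * se,
               stringsAsFactors = FALSE)
}

#' Fit a two-latent-variable SEM by diagonally weighted least squares
#'
#' The observed indicators are standardized (mean 0, variance 1); the
#' moment structure fitted is the vector of Pearson correlations among
#' indicators plus the polyserial correlation (threshold/probit link)
#' between each indicator and the binary outcome.  Parameters (factor
#' loadings, the two outcome paths, and the latent correlation) minimize
#' the discrepancy weighted by the inverse asymptotic variance of each
#' correlation (a diagonal weight matrix).  Residual variances follow
#' from the standardized identity \code{v = 1 - a^2}, so every indicator
#' satisfies \code{a^2 + v = 1} exactly; a loading greater than 1 in
#' magnitude therefore signals a Heywood case (negative residual
#' variance), as does an implied negative outcome residual.
#'
#' Standard errors are delta-method DWLS errors,
#' \code{(J' W J)^{-1}} with J the Jacobian of the implied correlations.
#' Non-convergence is flagged but estimates are still returned.
#'
#' @param spec a \linkS4class{SemSpec}
#' @param clr sample x genus matrix of CLR values (point estimates)
#' @param outcome binary 0/1 vector aligned with the rows of \code{clr}
#' @param standardization optional list(center, scale) of per-indicator
#'   moments to reuse (by default computed from \code{clr})
#' @return a \linkS4class{FittedSem}
#' @export
fitSem <- function(spec, clr, outcome, standardization = NULL) {
    stopifnot(is(spec, "SemSpec"))
    st <- .semStructure(spec)
    missing <- setdiff(st$ind, colnames(clr))
    if (length(missing))
        stop("indicator(s) absent from data: ", paste(missing, collapse = ", "))
    if (length(outcome) != nrow(clr))
        stop("outcome must have one value per sample")
    y <- as.numeric(outcome)
    if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
    if (length(unique(y)) < 2L) stop("outcome must have both levels")
    N <- nrow(clr)
    X <- clr[, st$ind, drop = FALSE]
    if (is.null(standardization)) {
        ctr <- colMeans(X)
        scl <- apply(X, 2L, sd)
    } else {
        ctr <- standardization$center[st$ind]
        scl <- standardization$scale[st$ind]
    }
    if (any(scl <= 0)) stop("constant indicator: ",
                            paste(st$ind[scl <= 0], collapse = ", "))
    Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

    ## sample moment vector: Pearson among indicators, polyserial vs y
    p <- st$nInd
    R <- cor(Z)
    prev <- mean(y)
    s <- numeric(ncol(st$pairs))
    avar <- numeric(ncol(st$pairs))
    for (j in seq_len(ncol(st$pairs))) {
        i1 <- st$pairs[1L, j]; i2 <- st$pairs[2L, j]
        if (i2 <= p) {
            s[j] <- R[i1, i2]
            avar[j] <- .corrAvar(s[j], N)
        } else {
            s[j] <- .polyserial(Z[, i1], y)
            avar[j] <- .corrAvar(s[j], N, p = prev)
        }
    }
    if (any(avar < 1e-12))
        stop("singular weight matrix (a correlation is at +-1); ",
             "consider removing an indicator")
    w <- 1 / (avar * N)                     # unit-scale weights
    obj <- function(th) sum(w * (s - .impliedCorr(th, st))^2)
    start <- c(rep(0.5, p), 0.2, -0.2, 0)
    lower <- c(rep(-1.5, p), -3, -3, -0.995)
    upper <- c(rep(1.5, p), 3, 3, 0.995)
    opt <- nlminb(start, obj, lower = lower, upper = upper,
                  control = list(iter.max = 500L, eval.max = 1000L))
    th <- opt$par
    converged <- opt$convergence == 0L

    a <- th[seq_len(p)]
    b <- th[p + 1:2]
    cc <- th[p + 3L]
    v <- 1 - a^2
    vy <- 1 - (b[1L]^2 + b[2L]^2 + 2 * b[1L] * b[2L] * cc)

    ## delta-method standard errors
    J <- .impliedJacobian(th, st)
    W <- 1 / avar
    H <- crossprod(J, J * W)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(th),
                                                       length(th)))
    seTh <- sqrt(pmax(diag(V), 0))
    ## derived: se(v) = 2|a| se(a); se(vy) by delta over (b1, b2, c)
    seV <- 2 * abs(a) * seTh[seq_len(p)]
    gvy <- c(-2 * b[1L] - 2 * b[2L] * cc, -2 * b[2L] - 2 * b[1L] * cc,
             -2 * b[1L] * b[2L])
    idx <- p + 1:3
    seVy <- if (anyNA(V)) NA_real_ else
        sqrt(max(0, drop(t(gvy) %*% V[idx, idx] %*% gvy)))

    lvName <- c(rep("lv1", length(spec@lv1)), rep("lv2", length(spec@lv2)))
    est <- do.call(rbind, c(
        lapply(seq_len(p), function(i)
            .estRow(lvName[i], "=~", st$ind[i], a[i], seTh[i])),
        list(.estRow(spec@outcome, "~", "lv1", b[1L], seTh[p + 1L]),
             .estRow(spec@outcome, "~", "lv2", b[2L], seTh[p + 2L])),
        lapply(seq_len(p), function(i)
            .estRow(st$ind[i], "~~", st$ind[i], v[i], seV[i])),
        list(.estRow(spec@outcome, "~~", spec@outcome, vy, seVy),
             .estRow("lv1", "~~", "lv1", 1, NA_real_),
             .estRow("lv2", "~~", "lv2", 1, NA_real_),
             .estRow("lv1", "~~", "lv2", cc, seTh[p + 3L]))))

    heywood <- character(0)
    if (any(v < 0)) heywood <- st$ind[v < 0]
    if (vy < 0) heywood <- c(heywood, spec@outcome)
    ## a latent correlation at (or essentially at) +-1 collapses the two
    ## factors: the latent covariance matrix is no longer positive
    ## definite in any meaningful sense and the outcome paths become
    ## collinear.  Treated as an inadmissible variance component.
    if (abs(cc) >= 0.95) heywood <- c(heywood, "latent-covariance")

    Smat <- diag(st$q)
    Smat[t(st$pairs)] <- s
    Smat[t(st$pairs)[, 2:1]] <- s
    dimnames(Smat) <- list(st$vars, st$vars)

    fit <- .fitIndicesFromDiscrepancy(opt$objective, s,
                                      .impliedCorr(th, st), w, st$q,
                                      length(th), N)
    new("FittedSem", spec = spec, estimates = est, fit = fit,
        N = as.integer(N), converged = converged, heywood = heywood,
        standardization = list(center = setNames(ctr, st$ind),
                               scale = setNames(scl, st$ind)),
        sampleCorr = Smat, discrepancy = opt$objective,
        deletionLog = character(0))
}

## GFI / AGFI / RMSEA from the DWLS discrepancy.  chi2 is the unscaled
## discrepancy times (N - 1); GFI compares the weighted residual sum of
## squares to the weighted total for the fitted moments (diagonal
## elements are reproduced exactly and enter the total with unit weight).
.fitIndicesFromDiscrepancy <- function(F0, s, sig, w, q, npar, N) {
    df <- length(s) - npar
    chi2 <- (N - 1) * F0
    rmsea <- if (df <= 0) 0 else sqrt(max(chi2 - df, 0) / (df * (N - 1)))
    num <- sum(w * (s - sig)^2)
    den <- sum(w * s^2) + q
    gfi <- 1 - num / den
    agfi <- if (df <= 0) NA_real_ else 1 - (q * (q + 1) / (2 * df)) * (1 - gfi)
    list(chi2 = chi2, df = as.integer(df), gfi = gfi, agfi = agfi,
         rmsea = rmsea)
}

#' Recompute fit indices for a fitted SEM
#'
#' \code{chi2} is the DWLS discrepancy at the optimum times (N - 1);
#' \code{RMSEA = sqrt(max(chi2 - df, 0) / (df (N - 1)))} (0 when df = 0);
#' \code{GFI} is one minus the ratio of the weighted residual to the
#' weighted total sum of squares of the sample correlation matrix, with
#' the estimator's diagonal weights; \code{AGFI = 1 - (q(q+1)/(2 df))
#' (1 - GFI)} (missing when df = 0).
#'
#' @param f a \linkS4class{FittedSem}
#' @return list with chi2, df, gfi, agfi, rmsea
#' @export
computeFitIndices <- function(f) {
    stopifnot(is(f, "FittedSem"))
    f@fit
}

#' Export the standardized parameter table as CSV
#'
#' Columns lhs, op, rhs, est, se, z, p, ci.lower, ci.upper.
#'
#' @param f a \linkS4class{FittedSem}
#' @param path destination file
#' @export
writeParameterTable <- function(f, path) {
    write.csv(parameterTable(f), path, row.names = FALSE)
    invisible(path)
}

## convenience extractors used across the package
.fittedLoadings <- function(f) {
    est <- f@estimates
    ld <- est[est$op == "=~", ]
    setNames(ld$est, ld$rhs)
}

.fittedPaths <- function(f) {
    est <- f@estimates
    pa <- est[est$op == "~", ]
    setNames(pa$est, pa$rhs)
}

.fittedLatentCov <- function(f) {
    est <- f@estimates
    est$est[est$op == "~~" & est$lhs == "lv1" & est$rhs == "lv2"]
}
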