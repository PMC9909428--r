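#' Extract the frozen measurement model from a fitted SEM
#'
#' Keeps the measurement-equation part only — factor loadings, residual
#' variances and the latent covariance, all fixed at their standardized
#' estimates — and drops the outcome variable and its paths, so new
#' samples can be scored without knowing their disease status.  The
#' standardization moments of the fitting population are carried along.
#'
#' @param f a converged \linkS4class{FittedSem}
#' @return a \linkS4class{MeasurementModel}
#' @export
extractMeasurementModel <- function(f) {
    stopifnot(is(f, "FittedSem"))
    if (!f@converged) stop("fit did not converge")
    a <- .fittedLoadings(f)
    th <- .indicatorResiduals(f)
    ind <- c(f@spec@lv1, f@spec@lv2)
    L <- matrix(0, length(ind), 2L,
                dimnames = list(ind, c("lv1", "lv2")))
    L[f@spec@lv1, "lv1"] <- a[f@spec@lv1]
    L[f@spec@lv2, "lv2"] <- a[f@spec@lv2]
    new("MeasurementModel", loadings = L, theta = th[ind],
        latentCov = .fittedLatentCov(f),
        center = f@standardization$center[ind],
        scale = f@standardization$scale[ind])
}

#' Construct a measurement model from explicit parameters
#'
#' @param lv1,lv2 named numeric vectors of loadings per latent
#' @param theta named numeric residual variances (defaults to
#'   \code{1 - loading^2})
#' @param latentCov latent covariance in (-1, 1)
#' @param center,scale standardization moments (default 0/1)
#' @return a \linkS4class{MeasurementModel}
#' @export
measurementModel <- function(lv1, lv2, theta = NULL, latentCov = 0,
                             center = NULL, scale = NULL) {
    ind <- c(names(lv1), names(lv2))
    L <- matrix(0, length(ind), 2L, dimnames = list(ind, c("lv1", "lv2")))
    L[names(lv1), "lv1"] <- lv1
    L[names(lv2), "lv2"] <- lv2
    if (is.null(theta)) theta <- setNames(1 - rowSums(L)^2, ind)
    if (is.null(center)) center <- setNames(numeric(length(ind)), ind)
    if (is.null(scale)) scale <- setNames(rep(1, length(ind)), ind)
    new("MeasurementModel", loadings = L, theta = theta[ind],
        latentCov = latentCov, center = center[ind], scale = scale[ind])
}

.bartlett <- function(L, theta, Z) {
    ## scores = (L' Th^-1 L)^-1 L' Th^-1 x  per sample (rows of Z)
    Ti <- 1 / theta
    M <- crossprod(L, L * Ti)
    B <- solve(M, t(L * Ti))              # 2 x p
    Z %*% t(B)
}

#' @describeIn bartlettScores score samples with a frozen measurement
#'   model; indicators are standardized with the stored (training)
#'   moments
#' @param groups optional group labels (named by sample or aligned)
#' @export
setMethod("bartlettScores", "MeasurementModel",
    function(object, clr, groups = NULL, ...) {
        ind <- rownames(object@loadings)
        missing <- setdiff(ind, colnames(clr))
        if (length(missing))
            stop("missing genus column(s): ", paste(missing, collapse = ", "))
        if (any(object@theta <= 0)) stop("non-positive residual variance")
        Z <- sweep(sweep(clr[, ind, drop = FALSE], 2L, object@center),
                   2L, object@scale, "/")
        sc <- .bartlett(object@loadings, object@theta, Z)
        if (is.null(rownames(clr)))
            rownames(clr) <- sprintf("sample_%d", seq_len(nrow(clr)))
        res <- data.frame(sample = rownames(clr), lv1 = sc[, 1L],
                          lv2 = sc[, 2L], stringsAsFactors = FALSE)
        if (!is.null(groups)) {
            res$group <- if (!is.null(names(groups)))
                as.character(groups[res$sample]) else as.character(groups)
        }
        if (any(!is.finite(sc))) stop("non-finite factor score")
        rownames(res) <- NULL
        res
    })

#' @describeIn bartlettScores score with the full fitted SEM: the
#'   standardized binary outcome enters as an extra indicator with the
#'   outcome paths as loadings and the outcome residual variance
#' @param outcome binary 0/1 vector aligned with \code{clr} rows
#' @export
setMethod("bartlettScores", "FittedSem",
    function(object, clr, outcome, groups = NULL, ...) {
        m <- extractMeasurementModel(object)
        y <- as.numeric(outcome)
        ys <- (y - mean(y)) / sd(y)
        b <- .fittedPaths(object)
        vy <- object@estimates$est[object@estimates$op == "~~" &
            object@estimates$lhs == object@spec@outcome]
        if (vy <= 0) stop("non-positive outcome residual variance")
        L <- rbind(m@loadings, outcome = c(b["lv1"], b["lv2"]))
        theta <- c(m@theta, outcome = vy)
        Z <- sweep(sweep(clr[, rownames(m@loadings), drop = FALSE], 2L,
                         m@center), 2L, m@scale, "/")
        sc <- .bartlett(L, theta, cbind(Z, outcome = ys))
        res <- data.frame(sample = rownames(clr), lv1 = sc[, 1L],
                          lv2 = sc[, 2L], stringsAsFactors = FALSE)
        if (!is.null(groups)) res$group <- as.character(groups)
        rownames(res) <- NULL
        res
    })

#' Mann-Whitney U test (rank-sum)
#'
#' Exact enumeration of all group-label assignments when n1 + n2 <= 10
#' (valid with ties); otherwise the normal approximation with tie and
#' continuity corrections.  U counts the (x, y) pairs with x > y, ties
#' one half.
#'
#' @param x,y numeric vectors for the two groups
#' @return list with U, p (two-sided), n1, n2, method
#' @export
wilcoxonRankSum <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    if (!n1 || !n2) stop("both groups must be non-empty")
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    if (n1 + n2 <= 10L) {
        idx <- combn(n1 + n2, n1)
        Us <- apply(idx, 2L, function(ii)
            sum(r[ii]) - n1 * (n1 + 1) / 2)
        p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
        method <- "exact enumeration"
    } else {
        n <- n1 + n2
        ties <- table(pooled)
        sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        d <- U - mu
        z <- if (d == 0) 0 else (d - sign(d) * 0.5) / sqrt(sig2)
        p <- min(1, 2 * pnorm(-abs(z)))
        method <- "normal approximation"
    }
    list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}

#' Compare latent-variable scores between groups
#'
#' Two-sided Mann-Whitney rank-sum tests for each requested group pair
#' and latent variable.
#'
#' @param scores data.frame with columns lv1, lv2 and group (from
#'   \code{\link{bartlettScores}})
#' @param pairs list of length-2 character vectors of group labels
#' @param variables which score columns to compare
#' @return data.frame: group1, group2, variable, U, p, n1, n2, method
#' @export
compareGroups <- function(scores, pairs = list(c("NC", "AS"), c("NC", "AM"),
                                               c("NC", "OD")),
                          variables = c("lv1", "lv2")) {
    if (!"group" %in% names(scores)) stop("scores need a group column")
    out <- list()
    for (pr in pairs) {
        g1 <- scores[scores$group == pr[1L], , drop = FALSE]
        g2 <- scores[scores$group == pr[2L], , drop = FALSE]
        if (!nrow(g1) || !nrow(g2))
            stop("empty group in pair ", pr[1L], " vs ", pr[2L])
        for (v in variables) {
            w <- wilcoxonRankSum(g1[[v]], g2[[v]])
            out[[length(out) + 1L]] <- data.frame(
                group1 = pr[1L], group2 = pr[2L], variable = v,
                U = w$U, p = w$p, n1 = w$n1, n2 = w$n2, method = w$method,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Export a score table as CSV (sample, lv1, lv2, group)
#'
#' @param scores data.frame from \code{\link{bartlettScores}}
#' @param path destination file
#' @export
writeScoreTable <- function(scores, path) {
    write.csv(scores, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
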