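#' Standardized compositional effect sizes between two groups
#'
#' For every Monte-Carlo instance of the CLR ensemble, samples are
#' randomly paired across the two groups (the larger group size sets the
#' number of pairings; the smaller group is sampled with replacement) and
#' within each group.  Per genus, the effect is the median over all
#' instances and pairings of the between-group CLR difference divided by
#' the larger of the two within-group absolute differences.  A positive
#' effect means higher CLR abundance in the \emph{second} level of
#' \code{groups}.
#'
#' On an expected-proportion (deterministic) ensemble the random
#' pairings are replaced by exhaustive ones, so the result is free of
#' Monte-Carlo noise: effect = median between-group difference over all
#' cross pairs divided by the larger within-group median absolute
#' difference.
#'
#' Internally the computation always runs with the group levels in
#' alphabetical order and the sign is flipped afterwards if the caller
#' asked for the opposite orientation, so swapping the level order
#' negates the effects exactly.
#'
#' @param ens a \linkS4class{ClrEnsemble}
#' @param groups factor (or character) of length nSamples with exactly
#'   two levels; the level \emph{order} sets the sign convention
#' @param seed integer seed for the random pairings
#' @return data.frame (one row per genus): \code{genus}, \code{effect},
#'   \code{diff_btw} (median between-group difference) and
#'   \code{diff_win} (median within-group dispersion)
#' @export
effectSizes <- function(ens, groups, seed = 1234L) {
    stopifnot(is(ens, "ClrEnsemble"))
    v <- ens@values
    S <- dim(v)[1L]
    if (length(groups) != S) stop("groups must have one label per sample")
    groups <- if (is.factor(groups)) droplevels(groups) else factor(groups, levels = unique(groups))
    lv <- levels(groups)
    if (length(lv) != 2L) stop("exactly two group levels required")
    flip <- is.unsorted(lv)              # canonical order is alphabetical
    lvs <- sort(lv)
    i1 <- which(groups == lvs[1L]); i2 <- which(groups == lvs[2L])
    n1 <- length(i1); n2 <- length(i2)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 samples (got ", n1, " and ", n2, ")")
    G <- dim(v)[2L]; I <- dim(v)[3L]
    if (ens@mode == "expected") {
        ## deterministic backend: exhaustive pairings instead of random
        ## ones — between-group differences over all cross pairs,
        ## within-group dispersions over all within pairs, effect =
        ## median between difference / larger within median
        x1 <- t(v[i1, , 1L, drop = FALSE][, , 1L])   # G x n1
        x2 <- t(v[i2, , 1L, drop = FALSE][, , 1L])
        eff <- btwMed <- winMax <- numeric(G)
        for (g in seq_len(G)) {
            btw <- outer(x2[g, ], x1[g, ], "-")
            w1 <- abs(outer(x1[g, ], x1[g, ], "-"))
            w2 <- abs(outer(x2[g, ], x2[g, ], "-"))
            btwMed[g] <- median(btw)
            winMax[g] <- max(median(w1[upper.tri(w1)]),
                             median(w2[upper.tri(w2)]), 1e-12)
            eff[g] <- btwMed[g] / winMax[g]
        }
        res <- data.frame(genus = dimnames(v)[[2L]],
                          effect = if (flip) -eff else eff,
                          diff_btw = (if (flip) -1 else 1) * btwMed,
                          diff_win = winMax, stringsAsFactors = FALSE)
        return(res)
    }
    np <- max(n1, n2)
    draw <- function(n) if (n == np) sample.int(n) else
        sample.int(n, np, replace = TRUE)
    set.seed(seed)
    rat <- matrix(NA_real_, G, np * I)
    btw <- win <- matrix(NA_real_, G, np * I)
    for (k in seq_len(I)) {
        x1 <- t(v[i1, , k, drop = FALSE][, , 1L])   # G x n1
        x2 <- t(v[i2, , k, drop = FALSE][, , 1L])
        a1 <- draw(n1); b1 <- draw(n1)
        a2 <- draw(n2); b2 <- draw(n2)
        d <- x2[, a2, drop = FALSE] - x1[, a1, drop = FALSE]
        w <- pmax(abs(x1[, a1, drop = FALSE] - x1[, b1, drop = FALSE]),
                  abs(x2[, a2, drop = FALSE] - x2[, b2, drop = FALSE]),
                  1e-12)
        cols <- ((k - 1L) * np + 1L):(k * np)
        btw[, cols] <- d
        win[, cols] <- w
        rat[, cols] <- d / w
    }
    eff <- apply(rat, 1L, median)
    res <- data.frame(genus = dimnames(v)[[2L]],
                      effect = if (flip) -eff else eff,
                      diff_btw = (if (flip) -1 else 1) * apply(btw, 1L, median),
                      diff_win = apply(win, 1L, median),
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Top-k genera by absolute effect size
#'
#' Descending \code{|effect|}; ties broken by lexicographic genus label.
#'
#' @param et effect table from \code{\link{effectSizes}}
#' @param k number of genera to return
#' @return character vector of k genus labels
#' @export
topKByAbsEffect <- function(et, k) {
    if (k <= 0) stop("k must be positive")
    if (k > nrow(et)) stop("k exceeds the number of genera")
    ord <- order(-abs(et$effect), et$genus)
    et$genus[ord][seq_len(k)]
}

## intersection of top-k lists; kept separate so the set semantics are
## unit-testable without re-running the stochastic backend
.intersectLists <- function(lists) Reduce(intersect, lists)

#' Stability selection of marker genera
#'
#' Recomputes the CLR ensemble and the effect sizes \code{reps} times
#' with fresh random numbers (seeds \code{baseSeed + 1 ...
#' baseSeed + reps}, re-randomizing both the Dirichlet instances and the
#' pairings) and keeps the genera present in the top-k list of
#' \emph{every} repetition.  This removes genera whose large apparent
#' effect is an artifact of one particular Monte-Carlo draw.
#'
#' @param x a \linkS4class{MicrobiomeCounts} or count matrix (only the
#'   samples with a group label are used)
#' @param groups two-level factor aligned with the samples of \code{x};
#'   positive effects mean higher abundance in the second level
#' @param reps number of repetitions (default 500)
#' @param k list length per repetition (default 20)
#' @param baseSeed integer; repetition r uses seed baseSeed + r
#' @param nInstances,prior,mode passed to \code{\link{clrEnsemble}}
#' @return a \linkS4class{StableMarkers}; an empty intersection is a
#'   valid result and is returned as an empty marker set with a warning
#' @export
stableMarkerSelection <- function(x, groups, reps = 500L, k = 20L,
                                  baseSeed = 1234L, nInstances = 128L,
                                  prior = 0.5, mode = "montecarlo") {
    reps <- as.integer(reps)
    if (reps < 1L) stop("reps must be >= 1")
    m <- if (is(x, "MicrobiomeCounts")) counts(x) else as.matrix(x)
    keep <- !is.na(groups)
    m <- m[, keep, drop = FALSE]
    groups <- groups[keep]
    lists <- vector("list", reps)
    effSum <- NULL
    for (r in seq_len(reps)) {
        ens <- clrEnsemble(m, nInstances = nInstances, prior = prior,
                           seed = baseSeed + r, mode = mode)
        et <- effectSizes(ens, groups, seed = baseSeed + r)
        if (is.null(effSum)) effSum <- setNames(numeric(nrow(et)), et$genus)
        effSum[et$genus] <- effSum[et$genus] + et$effect
        lists[[r]] <- topKByAbsEffect(et, k)
    }
    stable <- .intersectLists(lists)
    if (!length(stable))
        warning("no genus was in the top-", k, " of all ", reps,
                " repetitions; empty marker set")
    meanEff <- effSum[stable] / reps
    ord <- order(-abs(meanEff), names(meanEff))
    new("StableMarkers", genera = as.character(names(meanEff)[ord]),
        meanEffect = meanEff[ord], reps = reps, k = as.integer(k))
}

#' Export stable markers as CSV (genus, mean effect, sign)
#'
#' @param markers a \linkS4class{StableMarkers}
#' @param path destination file
#' @export
writeStableMarkers <- function(markers, path) {
    df <- data.frame(genus = markers@genera,
                     mean_effect = unname(markers@meanEffect),
                     sign = ifelse(markers@meanEffect >= 0, "+", "-"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
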