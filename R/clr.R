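#' Monte-Carlo Dirichlet CLR transform of a count table
#'
#' For each sample, \code{nInstances} composition vectors are drawn from
#' Dirichlet(counts + prior) and each is centered-log-ratio transformed
#' in log2 units, centering over all genera:
#' \code{clr(p)_j = log2 p_j - mean_j(log2 p_j)}.  This propagates the
#' count (sequencing-depth) uncertainty of low-abundance genera through
#' every downstream statistic.  The deterministic \code{"expected"} mode
#' replaces the Dirichlet draws by the expected proportions
#' \code{(counts + prior) / sum} and yields a single instance; it is
#' exactly scale-invariant and useful for tests.
#'
#' @param x a \linkS4class{MicrobiomeCounts} or genus x sample count
#'   matrix
#' @param nInstances number of Monte-Carlo instances (default 128)
#' @param prior pseudo-count added to every cell (default 0.5; must be
#'   positive in Monte-Carlo mode, may be 0 in expected mode when all
#'   counts are positive)
#' @param seed integer seed (default 1234); the ensemble is bit-identical
#'   for a fixed seed
#' @param mode "montecarlo" (default) or "expected"
#' @return a \linkS4class{ClrEnsemble} (sample x genus x instance)
#' @examples
#' m <- matrix(c(2, 8, 5, 5), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' clrEnsemble(m, nInstances = 4, seed = 1)
#' @export
clrEnsemble <- function(x, nInstances = 128L, prior = 0.5, seed = 1234L,
                        mode = c("montecarlo", "expected")) {
    mode <- match.arg(mode)
    m <- if (is(x, "MicrobiomeCounts")) counts(x) else as.matrix(x)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("counts need genus rownames and sample colnames")
    nInstances <- as.integer(nInstances)
    if (nInstances < 1L) stop("nInstances must be >= 1")
    if (mode == "montecarlo" && prior <= 0)
        stop("prior must be > 0 in Monte-Carlo mode")
    if (prior < 0) stop("prior must be >= 0")
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("sample with all-zero counts: ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    G <- nrow(m); S <- ncol(m)
    a <- m + prior
    if (mode == "expected") {
        if (any(a <= 0))
            stop("expected mode needs positive counts + prior")
        nInstances <- 1L
        lp <- log2(a) - rep(log2(colSums(a)), each = G)
        clr <- lp - rep(colMeans(lp), each = G)
        vals <- array(t(clr), dim = c(S, G, 1L))
    } else {
        set.seed(seed)
        ## gamma draws shape = counts + prior, normalized per (sample,
        ## instance) give Dirichlet compositions; log2 then center.
        ## Draws are made in canonical (sorted) genus order so the
        ## ensemble is invariant to the row order of the input table.
        ord <- order(rownames(m))
        g <- array(rgamma(G * S * nInstances,
                          shape = as.vector(a[ord, , drop = FALSE])),
                   dim = c(G, S, nInstances))
        g <- g[order(ord), , , drop = FALSE]
        lg <- log2(g)
        ## clr(p) = log2 g - mean(log2 g): normalizing constant cancels
        ctr <- colMeans(lg)                       # S x I
        clr <- lg - rep(ctr, each = G)
        vals <- aperm(clr, c(2L, 1L, 3L))
    }
    dimnames(vals) <- list(colnames(m), rownames(m), NULL)
    new("ClrEnsemble", values = vals, prior = prior, mode = mode,
        seed = as.integer(seed))
}

#' Collapse a CLR ensemble to a point-estimate matrix
#'
#' Element-wise median across Monte-Carlo instances, with each sample row
#' re-centered to sum zero (the median is taken per genus, so the
#' zero-sum constraint must be restored).
#'
#' @param ens a \linkS4class{ClrEnsemble}
#' @return sample x genus matrix of CLR values
#' @export
clrPointEstimate <- function(ens) {
    stopifnot(is(ens, "ClrEnsemble"))
    v <- ens@values
    d <- dim(v)
    if (d[3L] == 1L) {
        m <- v[, , 1L, drop = TRUE]
        if (is.null(dim(m))) m <- matrix(m, d[1L], d[2L])
    } else {
        flat <- matrix(v, d[1L] * d[2L], d[3L])
        med <- apply(flat, 1L, median)
        m <- matrix(med, d[1L], d[2L])
    }
    m <- m - rowMeans(m)
    dimnames(m) <- dimnames(v)[1:2]
    m
}

#' Export a CLR point-estimate matrix as tab-separated text
#'
#' @param m sample x genus matrix from \code{\link{clrPointEstimate}}
#' @param path destination file
#' @export
writeClrMatrix <- function(m, path) {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
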