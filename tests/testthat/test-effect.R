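# Effect sizes, top-k ranking and stability selection.

makeTwoGroupCounts <- function(n1 = 20, n2 = 20, G = 12, shift = 0,
                               shiftGenus = "g01", seed = 1) {
    set.seed(seed)
    z <- matrix(rnorm((n1 + n2) * G), n1 + n2, G)
    colnames(z) <- sprintf("g%02d", seq_len(G))
    z[(n1 + 1):(n1 + n2), shiftGenus] <- z[(n1 + 1):(n1 + n2), shiftGenus] +
        shift
    cnt <- apply(z, 1, function(zi) {
        p <- 2^(zi - max(zi)); rmultinom(1, 20000, p / sum(p))
    })
    rownames(cnt) <- colnames(z)
    colnames(cnt) <- sprintf("s%03d", seq_len(n1 + n2))
    list(counts = cnt,
         groups = factor(rep(c("A", "B"), c(n1, n2)), levels = c("A", "B")))
}

test_that("swapping the group order negates effects exactly", {
    d <- makeTwoGroupCounts(shift = 2)
    ens <- clrEnsemble(d$counts, nInstances = 16, seed = 4)
    eAB <- effectSizes(ens, d$groups, seed = 9)
    eBA <- effectSizes(ens, factor(d$groups, levels = c("B", "A")), seed = 9)
    expect_equal(eAB$effect, -eBA$effect, tolerance = 1e-12)
})

test_that("a strongly shifted genus has the largest effect, above 1", {
    d <- makeTwoGroupCounts(n1 = 25, n2 = 25, shift = 5, seed = 2)
    ens <- clrEnsemble(d$counts, nInstances = 32, seed = 6)
    et <- effectSizes(ens, d$groups, seed = 6)
    top <- et$genus[which.max(abs(et$effect))]
    expect_identical(top, "g01")
    expect_gt(et$effect[et$genus == "g01"], 1)   # higher in second group
})

test_that("identical distributions give small effects", {
    d <- makeTwoGroupCounts(n1 = 50, n2 = 50, G = 20, shift = 0, seed = 3)
    ens <- clrEnsemble(d$counts, nInstances = 32, seed = 8)
    et <- effectSizes(ens, d$groups, seed = 8)
    expect_lt(max(abs(et$effect)), 0.5)
    expect_lt(median(abs(et$effect)), 0.2)
})

test_that("groups below 2 samples are rejected", {
    d <- makeTwoGroupCounts(n1 = 1, n2 = 5, G = 5)
    ens <- clrEnsemble(d$counts, nInstances = 4, seed = 1)
    expect_error(effectSizes(ens, d$groups), "at least 2")
})

test_that("top-k ranks by absolute effect with lexicographic ties", {
    et <- data.frame(genus = c("a", "b", "c"),
                     effect = c(0.5, -0.9, 0.1))
    expect_identical(topKByAbsEffect(et, 2), c("b", "a"))
    expect_setequal(topKByAbsEffect(et, 3), et$genus)
    tie <- data.frame(genus = c("zeta", "alpha"), effect = c(0.4, -0.4))
    expect_identical(topKByAbsEffect(tie, 1), "alpha")
    expect_error(topKByAbsEffect(et, 0), "positive")
    expect_error(topKByAbsEffect(et, 4), "exceeds")
})

test_that("intersection semantics: one absence drops a genus", {
    lists <- c(replicate(499, c("a", "b", "c"), simplify = FALSE),
               list(c("a", "c", "d")))
    expect_setequal(microSEM:::.intersectLists(lists), c("a", "c"))
})

test_that("deterministic backend makes the stable set the single top-k", {
    d <- makeTwoGroupCounts(n1 = 15, n2 = 15, shift = 3, seed = 4)
    mk <- stableMarkerSelection(d$counts, d$groups, reps = 5, k = 4,
                                baseSeed = 10, nInstances = 1,
                                mode = "expected")
    ens <- clrEnsemble(d$counts, mode = "expected")
    et <- effectSizes(ens, d$groups, seed = 11)
    expect_setequal(genera(mk), topKByAbsEffect(et, 4))
})

test_that("selection recovers strongly shifted genera and is monotone in reps", {
    set.seed(12)
    n <- 25; G <- 30
    z <- matrix(rnorm(2 * n * G), 2 * n, G)
    colnames(z) <- sprintf("g%02d", seq_len(G))
    for (g in c("g01", "g02", "g03"))
        z[(n + 1):(2 * n), g] <- z[(n + 1):(2 * n), g] + 4
    cnt <- apply(z, 1, function(zi) {
        p <- 2^(zi - max(zi)); rmultinom(1, 20000, p / sum(p))
    })
    rownames(cnt) <- colnames(z); colnames(cnt) <- sprintf("s%03d", 1:(2 * n))
    grp <- factor(rep(c("A", "B"), each = n))
    mk10 <- stableMarkerSelection(cnt, grp, reps = 10, k = 5, baseSeed = 50,
                                  nInstances = 16)
    expect_true(all(c("g01", "g02", "g03") %in% genera(mk10)))
    expect_lte(length(genera(mk10)), 5L)
    ## intersection over more repetitions is nested in fewer
    mk5 <- stableMarkerSelection(cnt, grp, reps = 5, k = 5, baseSeed = 50,
                                 nInstances = 16)
    expect_true(all(genera(mk10) %in% genera(mk5)))
})

test_that("selection result is invariant to genus row order", {
    d <- makeTwoGroupCounts(n1 = 12, n2 = 12, G = 8, shift = 3, seed = 6)
    perm <- sample(nrow(d$counts))
    mk1 <- stableMarkerSelection(d$counts, d$groups, reps = 3, k = 3,
                                 baseSeed = 20, nInstances = 8)
    mk2 <- stableMarkerSelection(d$counts[perm, ], d$groups, reps = 3, k = 3,
                                 baseSeed = 20, nInstances = 8)
    expect_setequal(genera(mk1), genera(mk2))
})
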