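# Measurement-model extraction, Bartlett scoring, group comparison.

test_that("extraction freezes the fitted parameters exactly", {
    d <- drawLatentData(1500, seed = 21)
    f <- fitSem(d$spec, d$X, d$y)
    m <- extractMeasurementModel(f)
    a <- microSEM:::.fittedLoadings(f)
    expect_equal(m@loadings[d$spec@lv1, "lv1"], a[d$spec@lv1])
    expect_equal(m@loadings[d$spec@lv2, "lv2"], a[d$spec@lv2])
    expect_equal(m@theta, microSEM:::.indicatorResiduals(f)[names(m@theta)])
    expect_equal(m@latentCov, microSEM:::.fittedLatentCov(f))
    ## no outcome variable present
    expect_false("atopic_dermatitis" %in% rownames(m@loadings))
})

test_that("the measurement model round-trips through its text grammar", {
    d <- drawLatentData(800, seed = 23)
    m <- extractMeasurementModel(fitSem(d$spec, d$X, d$y))
    path <- withr::local_tempfile(fileext = ".txt")
    writeMeasurementModel(m, path)
    m2 <- readMeasurementModel(path)
    expect_equal(m2@loadings, m@loadings, tolerance = 1e-9)
    expect_equal(m2@theta, m@theta, tolerance = 1e-9)
    expect_equal(m2@latentCov, m@latentCov, tolerance = 1e-9)
    expect_equal(m2@center, m@center, tolerance = 1e-9)
    ## scoring with the round-tripped model is identical
    s1 <- bartlettScores(m, d$X)
    s2 <- bartlettScores(m2, d$X)
    expect_equal(s1$lv1, s2$lv1, tolerance = 1e-8)
})

test_that("x = Lambda * 1 is a fixed point of the Bartlett estimator", {
    m <- measurementModel(lv1 = c(x1 = 0.6, x2 = 0.8),
                          lv2 = c(x3 = 0.5, x4 = 0.5),
                          theta = c(x1 = 0.64, x2 = 0.36, x3 = 0.75,
                                    x4 = 0.75))
    X <- rbind(a = c(x1 = 0.6, x2 = 0.8, x3 = 0, x4 = 0),
               zero = c(x1 = 0, x2 = 0, x3 = 0, x4 = 0))
    sc <- bartlettScores(m, X)
    expect_equal(sc$lv1[1], 1, tolerance = 1e-12)
    expect_equal(sc$lv2[1], 0, tolerance = 1e-12)
    expect_equal(unlist(sc[2, c("lv1", "lv2")]), c(lv1 = 0, lv2 = 0),
                 tolerance = 1e-12)
})

test_that("Bartlett scores equal the direct GLS solve", {
    set.seed(31)
    L <- matrix(0, 5, 2, dimnames = list(paste0("x", 1:5), c("lv1", "lv2")))
    L[1:3, 1] <- runif(3, 0.3, 0.8)
    L[4:5, 2] <- runif(2, 0.3, 0.8)
    theta <- setNames(runif(5, 0.2, 0.9), rownames(L))
    m <- measurementModel(lv1 = L[1:3, 1], lv2 = L[4:5, 2], theta = theta)
    X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, rownames(L)))
    sc <- bartlettScores(m, X)
    ## independent oracle: per-sample generalized least squares
    for (i in c(1, 17, 40)) {
        oracle <- solve(t(L) %*% diag(1 / theta) %*% L,
                        t(L) %*% diag(1 / theta) %*% X[i, ])
        expect_equal(unlist(sc[i, c("lv1", "lv2")]),
                     c(lv1 = oracle[1], lv2 = oracle[2]), tolerance = 1e-12)
    }
})

test_that("Bartlett scores are conditionally unbiased", {
    n <- 2000
    d <- drawLatentData(n, seed = 33)
    m <- measurementModel(
        lv1 = c(p1 = 0.54, p2 = 0.53, p3 = 0.44),
        lv2 = c(q1 = 0.58, q2 = 0.42, q3 = 0.20),
        latentCov = 0.07)
    sc <- bartlettScores(m, d$X)
    slope1 <- coef(lm(sc$lv1 ~ d$f1))[2]
    slope2 <- coef(lm(sc$lv2 ~ d$f2))[2]
    expect_equal(unname(slope1), 1, tolerance = 0.05)
    expect_equal(unname(slope2), 1, tolerance = 0.08)
})

test_that("extracted-model scores track full-model scores", {
    d <- drawLatentData(1500, seed = 35)
    f <- fitSem(d$spec, d$X, d$y)
    m <- extractMeasurementModel(f)
    s1 <- bartlettScores(m, d$X)
    s2 <- bartlettScores(f, d$X, outcome = d$y)
    expect_gt(cor(s1$lv1, s2$lv1, method = "spearman"), 0.9)
    expect_gt(cor(s1$lv2, s2$lv2, method = "spearman"), 0.9)
})

test_that("missing indicator columns are reported by name", {
    m <- measurementModel(lv1 = c(x1 = 0.6, x2 = 0.7),
                          lv2 = c(x3 = 0.5, x4 = 0.5))
    X <- matrix(0, 2, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
    expect_error(bartlettScores(m, X), "x4")
})

test_that("exact rank-sum enumeration matches hand calculation", {
    w <- wilcoxonRankSum(c(1, 2), c(3, 4))
    expect_equal(w$U, 0)
    expect_equal(w$p, 2 / 6, tolerance = 1e-12)
    expect_identical(w$method, "exact enumeration")
    ## identical groups: p = 1
    expect_equal(wilcoxonRankSum(c(5, 6), c(5, 6))$p, 1)
    ## swap symmetry: U' = n1 n2 - U, same p
    a <- c(1.2, 3.4, 2.2); b <- c(0.5, 4.1)
    w1 <- wilcoxonRankSum(a, b); w2 <- wilcoxonRankSum(b, a)
    expect_equal(w1$U + w2$U, length(a) * length(b))
    expect_equal(w1$p, w2$p)
})

test_that("exact p matches wilcox.test when there are no ties", {
    set.seed(41)
    for (i in 1:5) {
        x <- rnorm(4); y <- rnorm(5) + 0.5
        ours <- wilcoxonRankSum(x, y)
        ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
        expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
        expect_equal(ours$U, unname(ref$statistic))
    }
})

test_that("normal approximation matches wilcox.test with ties", {
    set.seed(43)
    x <- round(rnorm(20), 1); y <- round(rnorm(25) + 0.3, 1)
    ours <- wilcoxonRankSum(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("group comparisons run over pairs and reject empty groups", {
    set.seed(45)
    sc <- data.frame(sample = sprintf("s%02d", 1:40),
                     lv1 = rnorm(40), lv2 = rnorm(40),
                     group = rep(c("NC", "AS", "AM", "OD"), each = 10))
    res <- compareGroups(sc)
    expect_identical(nrow(res), 6L)
    expect_true(all(res$p > 0 & res$p <= 1))
    expect_true(all(res$U >= 0 & res$U <= res$n1 * res$n2))
    expect_error(compareGroups(sc, pairs = list(c("NC", "XX"))), "empty")
})
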