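# DWLS SEM: specification, fitting, indices, and backward modification.

test_that("marker signs map to the correct latent variables", {
    eff <- c(Alistipes = 0.5, Butyricimonas = 0.45, Coprobacter = 0.4,
             Fusicatenibacter = -0.5, Agathobacter = -0.4,
             Streptococcus = -0.2)
    spec <- buildModelSpec(eff)
    expect_setequal(spec@lv1, c("Alistipes", "Butyricimonas", "Coprobacter"))
    expect_setequal(spec@lv2, c("Fusicatenibacter", "Agathobacter",
                                "Streptococcus"))
    expect_false(spec@underIdentified)
    expect_error(buildModelSpec(c(a = 0.5, b = 0.3)), "negative-effect")
    expect_true(semSpec("a", c("b", "c"))@underIdentified)
    expect_error(semSpec(c("a", "b"), c("b", "c")), "both latent")
})

test_that("near-noiseless indicators drive standardized loadings to 1", {
    set.seed(2)
    n <- 800
    f1 <- rnorm(n); f2 <- rnorm(n)
    X <- cbind(p1 = f1 + rnorm(n, sd = 0.02), p2 = f1 + rnorm(n, sd = 0.02),
               q1 = f2 + rnorm(n, sd = 0.02), q2 = f2 + rnorm(n, sd = 0.02))
    rownames(X) <- sprintf("s%03d", 1:n)
    y <- as.integer(0.5 * f1 - 0.5 * f2 + rnorm(n, sd = 0.5) > 1)
    f <- fitSem(semSpec(c("p1", "p2"), c("q1", "q2")), X, y)
    ld <- microSEM:::.fittedLoadings(f)
    expect_true(all(abs(ld) > 0.97))
    b <- microSEM:::.fittedPaths(f)
    expect_gt(b["lv1"], 0)
    expect_lt(b["lv2"], 0)
})

test_that("every fit satisfies the standardized identity a^2 + v = 1", {
    d <- drawLatentData(400, seed = 7)
    f <- fitSem(d$spec, d$X, d$y)
    a <- microSEM:::.fittedLoadings(f)
    v <- microSEM:::.indicatorResiduals(f)
    expect_equal(unname(a[names(v)]^2 + v), rep(1, length(v)),
                 tolerance = 1e-6)
    ## outcome residual identity
    pt <- parameterTable(f)
    b <- microSEM:::.fittedPaths(f)
    cc <- microSEM:::.fittedLatentCov(f)
    vy <- pt$est[pt$op == "~~" & pt$lhs == "atopic_dermatitis"]
    expect_equal(vy, 1 - (b[["lv1"]]^2 + b[["lv2"]]^2 +
                          2 * b[["lv1"]] * b[["lv2"]] * cc),
                 tolerance = 1e-9)
})

test_that("parameters are recovered on synthetic draws (n = 5000)", {
    truth <- c(0.54, 0.53, 0.44, 0.58, 0.42, 0.20, 0.32, -0.41)
    errs <- sapply(1:8, function(s) {
        d <- drawLatentData(5000, seed = 100 + s)
        f <- fitSem(d$spec, d$X, d$y)
        est <- c(microSEM:::.fittedLoadings(f), microSEM:::.fittedPaths(f))
        mean(abs(est - truth))
    })
    expect_lt(mean(errs), 0.05)
})

test_that("flipping the outcome flips paths and keeps loadings", {
    d <- drawLatentData(600, seed = 9)
    f1 <- fitSem(d$spec, d$X, d$y)
    f2 <- fitSem(d$spec, d$X, 1L - d$y)
    expect_equal(abs(microSEM:::.fittedLoadings(f1)),
                 abs(microSEM:::.fittedLoadings(f2)), tolerance = 1e-3)
    expect_equal(microSEM:::.fittedPaths(f1),
                 -microSEM:::.fittedPaths(f2), tolerance = 1e-3)
})

test_that("missing variables and degenerate outcomes are rejected", {
    d <- drawLatentData(100, seed = 3)
    expect_error(fitSem(semSpec(c("p1", "zz"), c("q1", "q2")), d$X, d$y),
                 "zz")
    expect_error(fitSem(d$spec, d$X, rep(0L, 100)), "both levels")
})

test_that("RMSEA follows its formula and degenerates correctly", {
    f <- microSEM:::.fitIndicesFromDiscrepancy(
        F0 = 100 / 400, s = rep(0.3, 30), sig = rep(0.3, 30),
        w = rep(1, 30), q = 8, npar = 5, N = 401)
    expect_equal(f$chi2, 100)
    expect_equal(f$df, 25L)
    expect_equal(f$rmsea, sqrt(75 / (25 * 400)), tolerance = 1e-12)
    ## chi2 <= df gives RMSEA 0; saturated model gives GFI 1
    f2 <- microSEM:::.fitIndicesFromDiscrepancy(
        F0 = 10 / 400, s = rep(0.3, 30), sig = rep(0.3, 30),
        w = rep(1, 30), q = 8, npar = 5, N = 401)
    expect_equal(f2$rmsea, 0)
    expect_equal(f2$gfi, 1)
    f3 <- microSEM:::.fitIndicesFromDiscrepancy(
        F0 = 0, s = rep(0.3, 10), sig = rep(0.3, 10), w = rep(1, 10),
        q = 5, npar = 10, N = 200)
    expect_equal(f3$rmsea, 0)
    expect_true(is.na(f3$agfi))
})

test_that("well-specified fits at n >= 1000 have RMSEA below 0.08", {
    rmseas <- sapply(1:5, function(s) {
        d <- drawLatentData(1000, seed = 200 + s)
        fitIndices(fitSem(d$spec, d$X, d$y))$rmsea
    })
    expect_true(all(rmseas < 0.08))
})

test_that("an admissible start fit is returned unchanged by modification", {
    d <- drawLatentData(2000, seed = 11)
    f <- fitSem(d$spec, d$X, d$y)
    m <- modifyModel(f, d$X, d$y)
    expect_identical(m@spec@lv1, f@spec@lv1)
    expect_identical(m@spec@lv2, f@spec@lv2)
    expect_length(m@deletionLog, 0L)
})

test_that("a pure-noise indicator is deleted during modification", {
    d <- drawLatentData(2000, seed = 13)
    X <- cbind(d$X, noise = rnorm(nrow(d$X)))
    spec <- semSpec(c("p1", "p2", "p3"), c("q1", "q2", "q3", "noise"))
    f <- fitSem(spec, X, d$y)
    m <- modifyModel(f, X, d$y)
    expect_false("noise" %in% c(m@spec@lv1, m@spec@lv2))
    expect_true(any(grepl("noise", m@deletionLog)))
    expect_setequal(m@spec@lv1, c("p1", "p2", "p3"))
})

test_that("an outcome unrelated to all indicators cannot be modeled", {
    ## outcome built from a residual orthogonal to every indicator, so
    ## all outcome-path p-values stay large in every candidate model
    d <- drawLatentData(400, seed = 317)
    set.seed(417)
    z <- residuals(lm(rnorm(400) ~ d$X))
    yIndep <- as.integer(z > quantile(z, 0.85))
    f <- fitSem(d$spec, d$X, yIndep)
    expect_error(modifyModel(f, d$X, yIndep), "could not be constructed")
})

test_that("the model text grammar matches the spec structure", {
    spec <- semSpec(c("Alistipes", "Butyricimonas", "Coprobacter"),
                    c("Fusicatenibacter", "Agathobacter", "Streptococcus"))
    txt <- semSyntax(spec)
    expect_identical(txt[1],
        "lv1 =~ Alistipes + Butyricimonas + Coprobacter")
    expect_identical(txt[3], "atopic_dermatitis ~ lv1 + lv2")
    expect_identical(txt[4], "lv1 ~~ lv2")
})
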