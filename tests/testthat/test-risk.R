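# Stratified splitting, SMOTE, logistic risk model, ROC/AUC.

test_that("stratified split sizes follow banker's rounding per stratum", {
    sizes <- c(NC = 321, AS = 45, AM = 75, OD = 1669)
    sc <- data.frame(sample = sprintf("s%05d", seq_len(sum(sizes))),
                     group = rep(names(sizes), sizes))
    sp <- stratifiedSplit(sc, frac = 0.8, seed = 3)
    expect_identical(sp$strata[c("NC", "AS", "AM", "OD")],
                     c(NC = 257, AS = 36, AM = 60, OD = 1335))
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), sc$sample)
})

test_that("frac = 1 empties the verification set; seeds reproduce", {
    sc <- data.frame(sample = sprintf("s%03d", 1:50),
                     group = rep(c("NC", "AS"), c(30, 20)))
    expect_length(stratifiedSplit(sc, frac = 1, seed = 1)$test, 0L)
    s1 <- stratifiedSplit(sc, frac = 0.8, seed = 9)
    s2 <- stratifiedSplit(sc, frac = 0.8, seed = 9)
    expect_identical(s1$train, s2$train)
    expect_false(identical(s1$train,
                           stratifiedSplit(sc, frac = 0.8, seed = 10)$train))
})

test_that("tiny strata go wholly to training with a warning", {
    sc <- data.frame(sample = c("a", "b", "c", "d"),
                     group = c("NC", "NC", "NC", "AS"))
    expect_warning(sp <- stratifiedSplit(sc, frac = 0.5, seed = 1),
                   "fewer than 2")
    expect_true("d" %in% sp$train)
})

test_that("synthetic SMOTE points lie on segments between minority points", {
    x <- data.frame(lv1 = c(0, 1, 10, 11, 12, 13, 14, 15),
                    lv2 = c(0, 1, 10, 11, 12, 13, 14, 15))
    y <- c(1, 1, 0, 0, 0, 0, 0, 0)
    bal <- smoteBalance(x, y, k = 1, overPct = 300, underPct = 100, seed = 2)
    syn <- bal$x[bal$origin == "synthetic", ]
    ## with k = 1 and two minority points every synthetic point is a
    ## convex combination of (0,0) and (1,1)
    expect_true(all(syn$lv1 >= 0 & syn$lv1 <= 1))
    expect_equal(syn$lv1, syn$lv2, tolerance = 1e-12)
    ## originals preserved
    expect_identical(sum(bal$origin == "minority"), 2L)
})

test_that("over/under percentages set the class counts", {
    set.seed(4)
    x <- data.frame(lv1 = rnorm(60), lv2 = rnorm(60))
    y <- rep(c(1, 0), c(10, 50))
    bal <- smoteBalance(x, y, k = 5, overPct = 200, underPct = 200, seed = 5)
    expect_identical(sum(bal$origin == "synthetic"), 20L)   # 200% of 10
    expect_identical(sum(bal$origin == "majority"), 40L)    # 200% of 20
    expect_identical(sum(bal$y == "1"), 30L)
})

test_that("SMOTE refuses a minority class smaller than k + 1", {
    x <- data.frame(lv1 = rnorm(20))
    y <- rep(c(1, 0), c(3, 17))
    expect_error(smoteBalance(x, y, k = 5), "at least 6")
})

test_that("null features give chance-level training AUC", {
    set.seed(6)
    x <- data.frame(lv1 = rnorm(500), lv2 = rnorm(500))
    y <- rbinom(500, 1, 0.3)
    fit <- fitRiskModel(x, y, features = c("lv1", "lv2"))
    expect_lt(max(abs(fit$coef[-1])), 0.5)
    auc <- rocAuc(predictRisk(fit, x), y)$auc
    expect_equal(auc, 0.5, tolerance = 0.1)
})

test_that("a separable feature is learned with AUC 1", {
    set.seed(7)
    x <- data.frame(lv2 = rnorm(200))
    y <- as.integer(x$lv2 < 0)
    w <- capture_warnings(fit <- fitRiskModel(x, y, features = "lv2"))
    expect_true(any(grepl("fitted probabilities|converge", w)))
    expect_lt(fit$coef["lv2"], 0)
    expect_equal(suppressWarnings(rocAuc(predictRisk(fit, x), y))$auc, 1)
})

test_that("two-point logistic fit matches the closed form", {
    x <- data.frame(lv2 = c(-1, 1))
    y <- c(0, 1)
    suppressWarnings(fit <- fitRiskModel(x, y, features = "lv2"))
    p <- predictRisk(fit, data.frame(lv2 = 0.3))
    b <- fit$coef
    expect_equal(p, 1 / (1 + exp(-(b[[1]] + b[[2]] * 0.3))), tolerance = 1e-9)
})

test_that("AUC equals the concordant-pair fraction", {
    r <- suppressWarnings(rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)))
    expect_equal(r$auc, 1)
    ## pos (0.8, 0.4), neg (0.6, 0.2): 3 of 4 pairs concordant
    r2 <- rocAuc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
    expect_equal(r2$auc, 0.75)
    ## all tied scores: 0.5
    r3 <- rocAuc(rep(0.4, 10), rep(c(0, 1), 5))
    expect_equal(r3$auc, 0.5)
    expect_true(r3$ci["lower"] <= r3$auc && r3$auc <= r3$ci["upper"])
    expect_error(rocAuc(runif(5), rep(1, 5)), "single class")
})

test_that("AUC against an independent pair-counting oracle", {
    set.seed(8)
    prob <- round(runif(60), 2)            # ties likely
    y <- rbinom(60, 1, 0.4)
    pairAuc <- mean(outer(prob[y == 1], prob[y == 0],
                          function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(rocAuc(prob, y)$auc, pairAuc, tolerance = 1e-12)
    ## invariant under strictly monotone transforms
    expect_equal(rocAuc(qlogis(pmin(pmax(prob, 0.01), 0.99)), y)$auc,
                 rocAuc(pmin(pmax(prob, 0.01), 0.99), y)$auc)
})

test_that("the ROC curve is monotone nondecreasing", {
    set.seed(9)
    r <- rocAuc(runif(80), rbinom(80, 1, 0.3))
    expect_true(all(diff(r$curve$tpr) >= -1e-12))
    expect_true(all(diff(r$curve$fpr) >= -1e-12))
})
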