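#' Stratified training/verification split
#'
#' Within each group stratum, \code{round(frac * n)} samples (banker's
#' rounding) are drawn into the training set; the rest form the
#' verification set.  Reproducible for a fixed seed.
#'
#' @param scores data.frame with columns \code{sample} and \code{group}
#' @param frac training fraction (default 0.8)
#' @param seed integer seed
#' @param by column to stratify on (default "group"; stratifying on the
#'   disease label instead is possible by passing that column name)
#' @return list with \code{train}, \code{test} (sample id vectors) and
#'   \code{strata} (per-stratum training counts)
#' @export
stratifiedSplit <- function(scores, frac = 0.8, seed = 1L, by = "group") {
    if (!by %in% names(scores)) stop("no '", by, "' column to stratify on")
    if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
    set.seed(seed)
    train <- character(0)
    strata <- c()
    for (g in unique(scores[[by]])) {
        ids <- scores$sample[scores[[by]] == g]
        n <- length(ids)
        if (n < 2L) {
            warning("stratum '", g, "' has fewer than 2 samples; ",
                    "assigning all to training")
            nTr <- n
        } else nTr <- round(frac * n)
        train <- c(train, sample(ids)[seq_len(nTr)])
        strata[g] <- nTr
    }
    list(train = train, test = setdiff(scores$sample, train),
         strata = strata)
}

#' SMOTE class balancing
#'
#' Each synthetic minority sample is \code{x + u (neighbor - x)} with
#' \code{u ~ Uniform(0, 1)} and the neighbor drawn among the k nearest
#' minority points (Euclidean distance in feature space).
#' \code{overPct} synthetic points per 100 original minority points are
#' added (e.g. 200 adds two per original); the majority class is then
#' sampled (with replacement) to \code{underPct} per 100 synthetic
#' points.  All original minority points are preserved.
#'
#' @param x data.frame / matrix of numeric features
#' @param y binary labels (the rarer level is the minority class)
#' @param k number of nearest neighbours (default 5)
#' @param overPct over-sampling percentage (default 200)
#' @param underPct under-sampling percentage (default 200)
#' @param seed integer seed
#' @return list with \code{x} (features), \code{y} (labels) and
#'   \code{origin} ("minority", "synthetic" or "majority")
#' @export
smoteBalance <- function(x, y, k = 5L, overPct = 200, underPct = 200,
                         seed = 1L) {
    x <- as.data.frame(x)
    if (k < 1L) stop("k must be >= 1")
    if (overPct <= 0 || underPct <= 0) stop("percentages must be positive")
    tab <- sort(table(y))
    if (length(tab) != 2L) stop("y must have exactly two classes")
    minLab <- names(tab)[1L]; majLab <- names(tab)[2L]
    minIdx <- which(y == minLab); majIdx <- which(y == majLab)
    nMin <- length(minIdx)
    if (nMin < k + 1L)
        stop("minority class has ", nMin, " samples; SMOTE with k = ", k,
             " needs at least ", k + 1L)
    set.seed(seed)
    Xmin <- as.matrix(x[minIdx, , drop = FALSE])
    D <- as.matrix(dist(Xmin))
    diag(D) <- Inf
    nn <- matrix(apply(D, 1L, function(d) order(d)[seq_len(k)]),
                 nrow = nMin, ncol = k, byrow = TRUE)
    perPoint <- round(overPct / 100)
    syn <- vector("list", nMin)
    for (i in seq_len(nMin)) {
        nb <- nn[i, sample.int(k, perPoint, replace = TRUE)]
        u <- runif(perPoint)
        syn[[i]] <- Xmin[rep(i, perPoint), , drop = FALSE] +
            u * (Xmin[nb, , drop = FALSE] - Xmin[rep(i, perPoint), , drop = FALSE])
    }
    synth <- do.call(rbind, syn)
    nMaj <- round(underPct / 100 * nrow(synth))
    majSel <- majIdx[sample.int(length(majIdx), nMaj, replace = TRUE)]
    feats <- rbind(as.matrix(x[minIdx, , drop = FALSE]), synth,
                   as.matrix(x[majSel, , drop = FALSE]))
    rownames(feats) <- NULL
    list(x = as.data.frame(feats),
         y = c(rep(minLab, nMin + nrow(synth)), rep(majLab, nMaj)),
         origin = c(rep("minority", nMin), rep("synthetic", nrow(synth)),
                    rep("majority", nMaj)))
}

#' Fit the logistic disease-risk model
#'
#' Maximum-likelihood logistic regression of the binary label on the
#' selected latent-variable features.  Separable data are handled by
#' glm's iteration cap (a warning is raised); constant features raise a
#' warning.
#'
#' @param x data.frame of features (training, typically SMOTE-balanced)
#' @param y binary 0/1 labels (or the two-level labels of
#'   \code{\link{smoteBalance}})
#' @param features which columns of \code{x} to use
#' @return list with \code{model} (glm), \code{coef} (named coefficients
#'   incl. intercept) and \code{features}
#' @export
fitRiskModel <- function(x, y, features = colnames(x)) {
    x <- as.data.frame(x)[, features, drop = FALSE]
    yy <- if (is.numeric(y)) y else as.integer(factor(y)) - 1L
    if (length(unique(yy)) < 2L) stop("labels contain a single class")
    const <- vapply(x, function(v) sd(v) == 0, logical(1))
    if (any(const))
        warning("constant feature(s): ",
                paste(features[const], collapse = ", "))
    d <- cbind(x, .y = yy)
    fml <- as.formula(paste(".y ~", paste(features, collapse = " + ")))
    model <- glm(fml, family = binomial(), data = d)
    list(model = model, coef = stats::coef(model), features = features)
}

#' Predict disease-risk probabilities
#'
#' @param fit result of \code{\link{fitRiskModel}}
#' @param newdata data.frame containing the model's features
#' @return numeric vector of probabilities
#' @export
predictRisk <- function(fit, newdata) {
    as.numeric(predict(fit$model, newdata = as.data.frame(newdata),
                       type = "response"))
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the probability that a random positive outscores a random
#' negative (ties count one half); the 95\% CI is DeLong's.
#'
#' @param prob numeric risk scores
#' @param labels binary 0/1 outcome
#' @return list with \code{auc}, \code{ci} (lower, upper) and
#'   \code{curve} (data.frame fpr, tpr, monotone nondecreasing)
#' @export
rocAuc <- function(prob, labels) {
    labels <- as.numeric(labels)
    if (length(unique(labels)) < 2L)
        stop("labels contain a single class; ROC undefined")
    r <- pROC::roc(response = labels, predictor = prob, quiet = TRUE,
                   levels = c(0, 1), direction = "<")
    ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
    curve <- data.frame(fpr = rev(1 - r$specificities),
                        tpr = rev(r$sensitivities))
    list(auc = as.numeric(pROC::auc(r)), ci = c(lower = ci[1L],
         upper = ci[3L]), curve = curve)
}
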