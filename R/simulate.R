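#' Configuration for the synthetic cohort generator
#'
#' The generative model inverts the analysis model: two unit-variance
#' latent factors (F1, F2) with correlation \code{latentCor}; each marker
#' genus carries a CLR-scale signal \code{a * F + e}, \code{e ~ N(0, 1 -
#' a^2)}; background genera are independent standard normals; the
#' per-sample CLR vector is mapped to a composition by softmax (base 2)
#' and read counts are multinomial at fixed depth (Dirichlet-multinomial
#' when \code{overdispersion > 0}).  The disease liability is \code{b1 F1
#' + b2 F2 + eps} with \code{eps ~ N(0, 1 - b1^2 - b2^2 - 2 b1 b2 c)};
#' the label is 1 when the liability exceeds the threshold implied by
#' \code{prevalence}.
#'
#' @param nSamples named integer vector c(NC, AS, AM, OD) of group sizes
#'   (or a single total when \code{fixedGroups = FALSE})
#' @param markers list with named numeric loading vectors \code{lv1} and
#'   \code{lv2} (loadings in (-1, 1))
#' @param nBackground number of background genera (default 94)
#' @param latentCor latent correlation c, |c| < 1
#' @param paths c(lv1 = b1, lv2 = b2) outcome path coefficients
#' @param prevalence target disease prevalence; defaults to
#'   (AS + AM) / total
#' @param depth read depth per sample (default 20000)
#' @param overdispersion Dirichlet-multinomial overdispersion (default 0
#'   = multinomial)
#' @param seed integer seed
#' @param fixedGroups when TRUE (default) group sizes are met exactly by
#'   conditioning the liability draws on the group's disease label; when
#'   FALSE labels are drawn unconditionally from the threshold model
#' @return validated configuration list (class "SimConfig")
#' @export
simConfig <- function(nSamples = c(NC = 100L, AS = 20L, AM = 20L, OD = 100L),
                      markers = list(
                          lv1 = c(marker_a = 0.6, marker_b = 0.5,
                                  marker_c = 0.5),
                          lv2 = c(marker_d = 0.6, marker_e = 0.5,
                                  marker_f = 0.4)),
                      nBackground = 94L, latentCor = 0.1,
                      paths = c(lv1 = 0.3, lv2 = -0.4), prevalence = NULL,
                      depth = 20000L, overdispersion = 0, seed = 1234L,
                      fixedGroups = TRUE) {
    if (fixedGroups) {
        stopifnot(all(c("NC", "AS", "AM", "OD") %in% names(nSamples)))
        if (any(nSamples < 0)) stop("group sizes must be >= 0")
    }
    a <- unlist(markers)
    if (any(abs(a) >= 1)) stop("loadings must lie in (-1, 1)")
    if (abs(latentCor) >= 1) stop("|latentCor| must be < 1")
    if (depth < 1000) stop("depth must be >= 1000")
    if (overdispersion < 0) stop("overdispersion must be >= 0")
    b1 <- paths[["lv1"]]; b2 <- paths[["lv2"]]
    resid <- 1 - (b1^2 + b2^2 + 2 * b1 * b2 * latentCor)
    if (resid <= 0) stop("outcome variance exhausted: b1^2 + b2^2 + ",
                         "2 b1 b2 c >= 1")
    if (is.null(prevalence)) {
        prevalence <- if (fixedGroups)
            (nSamples[["AS"]] + nSamples[["AM"]]) / sum(nSamples) else 0.1
        if (prevalence <= 0) prevalence <- 0.1   # degenerate all-control runs
    }
    structure(list(nSamples = nSamples, markers = markers,
                   nBackground = as.integer(nBackground),
                   latentCor = latentCor, paths = paths,
                   prevalence = prevalence,
                   threshold = qnorm(1 - prevalence),
                   depth = as.integer(depth),
                   overdispersion = overdispersion,
                   seed = as.integer(seed), fixedGroups = fixedGroups),
              class = "SimConfig")
}

#' Reference female-cohort scenario
#'
#' A ready-to-run configuration whose generating parameters equal the
#' reference standardized solution shipped with the package (see
#' \code{\link{femaleSolution}}): loadings (0.54, 0.53, 0.44) on lv1 for
#' Alistipes, Butyricimonas and Coprobacter, (0.58, 0.42, 0.20) on lv2
#' for Fusicatenibacter, Agathobacter and Streptococcus, latent
#' correlation 0.07 and outcome paths (0.32, -0.41), with group sizes
#' (321, 45, 75, 1669) scaled by \code{nScale}.
#'
#' @param nScale group-size scaling factor (default 1)
#' @param seed integer seed
#' @return a \code{\link{simConfig}} object
#' @export
femaleScenario <- function(nScale = 1, seed = 1234L) {
    if (nScale <= 0) stop("nScale must be positive")
    sol <- femaleSolution()
    simConfig(nSamples = round(nScale * c(NC = 321L, AS = 45L, AM = 75L,
                                          OD = 1669L)),
              markers = list(lv1 = sol$loadings$lv1, lv2 = sol$loadings$lv2),
              nBackground = 94L, latentCor = sol$latentCor,
              paths = sol$paths, depth = 20000L, seed = seed)
}

#' Reference standardized solution for the female cohort
#'
#' The printed standardized solution used as the generating parameter
#' set of \code{\link{femaleScenario}} and as the fixed scoring model in
#' reference analyses: loadings, their printed residual variances, the
#' latent correlation, outcome paths, and the outcome residual variance.
#'
#' @return named list: loadings (list lv1, lv2), residuals (named),
#'   latentCor, paths, outcomeResidual, groupSizes
#' @export
femaleSolution <- function() {
    list(loadings = list(
             lv1 = c(Alistipes = 0.54, Butyricimonas = 0.53,
                     Coprobacter = 0.44),
             lv2 = c(Fusicatenibacter = 0.58, Agathobacter = 0.42,
                     Streptococcus = 0.20)),
         residuals = c(Alistipes = 0.70, Butyricimonas = 0.72,
                       Coprobacter = 0.80, Fusicatenibacter = 0.67,
                       Agathobacter = 0.83, Streptococcus = 0.96),
         latentCor = 0.07,
         paths = c(lv1 = 0.32, lv2 = -0.41),
         outcomeResidual = 0.75,
         groupSizes = c(NC = 321L, AS = 45L, AM = 75L, OD = 1669L))
}

## metadata row templates per group; AM/OD samples get one randomly
## chosen other-disease marker (flag, BMI, CES-D or colorectal surgery)
.simMetadata <- function(group, sex) {
    n <- length(group)
    df <- data.frame(
        sample_id = sprintf("S%05d", seq_len(n)),
        sex = rep(sex, n),
        age = sample(20:70, n, replace = TRUE),
        bmi = round(runif(n, 19, 24.5), 1),
        cesd = sample(0:14, n, replace = TRUE),
        atopic_dermatitis = as.integer(group %in% c("AS", "AM")),
        other_disease = 0L, medication = 0L,
        hospitalization_surgery = 0L, helicobacter_treatment = 0L,
        insomnia_consultation = 0L,
        defecation_frequency = rep("1_2_per_day", n),
        alcohol_frequency = rep("none", n),
        smoking_history = 0L,
        menstrual_status = rep(if (sex == "female") "regular"
                               else "not_applicable", n),
        menstruating_at_collection = if (sex == "female") 0L else NA_integer_,
        pregnant_or_breastfeeding = if (sex == "female") 0L else NA_integer_,
        colorectal_surgery_history = 0L,
        stringsAsFactors = FALSE)
    sick <- which(group %in% c("AM", "OD"))
    if (length(sick)) {
        how <- sample(c("flag", "bmi_low", "bmi_high", "cesd", "colorectal"),
                      length(sick), replace = TRUE)
        df$other_disease[sick[how == "flag"]] <- 1L
        df$bmi[sick[how == "bmi_low"]] <- round(runif(sum(how == "bmi_low"),
                                                      16, 18.4), 1)
        df$bmi[sick[how == "bmi_high"]] <- round(runif(sum(how == "bmi_high"),
                                                       25.1, 32), 1)
        df$cesd[sick[how == "cesd"]] <- sample(16:40, sum(how == "cesd"),
                                               replace = TRUE)
        crc <- sick[how == "colorectal"]
        df$colorectal_surgery_history[crc] <- 1L
        df$hospitalization_surgery[crc] <- 1L   # surgery implies the NC5 flag
    }
    df
}

#' Generate a synthetic cohort with known latent structure
#'
#' See \code{\link{simConfig}} for the generative model.  The returned
#' metadata satisfies the group criteria exactly, so
#' \code{\link{assignGroups}} reproduces the configured group sizes.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param sex cohort sex for the metadata (default "female")
#' @return list with \code{counts} (a \linkS4class{MicrobiomeCounts}
#'   carrying the metadata in colData), \code{metadata} (data.frame),
#'   \code{truth} (per-sample F1, F2, liability, label, group) and
#'   \code{config}
#' @export
simulateCommunity <- function(cfg, sex = "female") {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    b1 <- cfg$paths[["lv1"]]; b2 <- cfg$paths[["lv2"]]
    cc <- cfg$latentCor
    residSd <- sqrt(1 - (b1^2 + b2^2 + 2 * b1 * b2 * cc))
    tau <- cfg$threshold

    drawLatent <- function(n) {
        f1 <- rnorm(n)
        f2 <- cc * f1 + sqrt(1 - cc^2) * rnorm(n)
        L <- b1 * f1 + b2 * f2 + residSd * rnorm(n)
        cbind(F1 = f1, F2 = f2, L = L)
    }

    if (cfg$fixedGroups) {
        group <- rep(c("NC", "AS", "AM", "OD"),
                     times = cfg$nSamples[c("NC", "AS", "AM", "OD")])
        wantPos <- group %in% c("AS", "AM")
        n <- length(group)
        F <- matrix(NA_real_, n, 3L,
                    dimnames = list(NULL, c("F1", "F2", "L")))
        filled <- rep(FALSE, n)
        while (!all(filled)) {
            cand <- drawLatent(2L * sum(!filled) + 32L)
            pos <- cand[cand[, "L"] > tau, , drop = FALSE]
            neg <- cand[cand[, "L"] <= tau, , drop = FALSE]
            needP <- which(!filled & wantPos)
            needN <- which(!filled & !wantPos)
            kP <- min(length(needP), nrow(pos))
            kN <- min(length(needN), nrow(neg))
            if (kP) { F[needP[seq_len(kP)], ] <- pos[seq_len(kP), ]
                      filled[needP[seq_len(kP)]] <- TRUE }
            if (kN) { F[needN[seq_len(kN)], ] <- neg[seq_len(kN), ]
                      filled[needN[seq_len(kN)]] <- TRUE }
        }
        label <- as.integer(wantPos)
    } else {
        n <- sum(cfg$nSamples)
        F <- drawLatent(n)
        label <- as.integer(F[, "L"] > tau)
        group <- ifelse(label == 1L, "AS", "NC")
    }

    a1 <- cfg$markers$lv1; a2 <- cfg$markers$lv2
    mk <- c(names(a1), names(a2))
    bg <- sprintf("background_%03d", seq_len(cfg$nBackground))
    G <- length(mk) + cfg$nBackground
    z <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, c(mk, bg)))
    for (j in seq_along(a1))
        z[, names(a1)[j]] <- a1[j] * F[, "F1"] +
            sqrt(1 - a1[j]^2) * rnorm(n)
    for (j in seq_along(a2))
        z[, names(a2)[j]] <- a2[j] * F[, "F2"] +
            sqrt(1 - a2[j]^2) * rnorm(n)

    cnt <- matrix(0L, G, n, dimnames = list(colnames(z), NULL))
    for (i in seq_len(n)) {
        w <- 2^(z[i, ] - max(z[i, ]))
        p <- w / sum(w)
        if (cfg$overdispersion > 0) {
            g <- rgamma(G, shape = p / cfg$overdispersion)
            p <- g / sum(g)
        }
        cnt[, i] <- rmultinom(1L, cfg$depth, p)
    }

    meta <- .simMetadata(group, sex)
    colnames(cnt) <- meta$sample_id
    truth <- data.frame(sample = meta$sample_id, F1 = F[, "F1"],
                        F2 = F[, "F2"], liability = F[, "L"],
                        label = label, group = group,
                        stringsAsFactors = FALSE)
    list(counts = MicrobiomeCounts(cnt, meta), metadata = meta,
         truth = truth, config = cfg)
}
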