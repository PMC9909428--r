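# Small fixtures built in code; nothing is read from disk.

tinyCounts <- function() {
    m <- matrix(c(12, 30, 4, 9, 25,
                  8, 41, 2, 11, 18,
                  15, 22, 7, 6, 30,
                  10, 35, 3, 12, 20,
                  20, 28, 5, 8, 24,
                  9, 33, 6, 10, 22), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    MicrobiomeCounts(m)
}

# one fully healthy female questionnaire row per sample id
healthyMeta <- function(ids, sex = "female") {
    n <- length(ids)
    data.frame(
        sample_id = ids, sex = rep(sex, n), age = rep(35L, n),
        bmi = rep(22, n), cesd = rep(5L, n),
        atopic_dermatitis = 0L, other_disease = 0L, medication = 0L,
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
}

# latent-model draw without the count layer: Gaussian indicators and a
# thresholded binary outcome, for estimator-level tests
drawLatentData <- function(n, a1 = c(0.54, 0.53, 0.44),
                           a2 = c(0.58, 0.42, 0.20),
                           b = c(0.32, -0.41), cc = 0.07,
                           prevalence = 0.123, seed = 1) {
    set.seed(seed)
    f1 <- rnorm(n)
    f2 <- cc * f1 + sqrt(1 - cc^2) * rnorm(n)
    X <- cbind(vapply(a1, function(a) a * f1 + sqrt(1 - a^2) * rnorm(n),
                      numeric(n)),
               vapply(a2, function(a) a * f2 + sqrt(1 - a^2) * rnorm(n),
                      numeric(n)))
    colnames(X) <- c(paste0("p", seq_along(a1)), paste0("q", seq_along(a2)))
    rownames(X) <- sprintf("s%04d", seq_len(n))
    resid <- 1 - (b[1]^2 + b[2]^2 + 2 * b[1] * b[2] * cc)
    L <- b[1] * f1 + b[2] * f2 + sqrt(resid) * rnorm(n)
    y <- as.integer(L > qnorm(1 - prevalence))
    list(X = X, y = y, f1 = f1, f2 = f2,
         spec = semSpec(paste0("p", seq_along(a1)),
                        paste0("q", seq_along(a2))))
}
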