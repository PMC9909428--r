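#' @describeIn semSyntax free-parameter model lines
#' @export
setMethod("semSyntax", "SemSpec", function(object) {
    c(paste("lv1 =~", paste(object@lv1, collapse = " + ")),
      paste("lv2 =~", paste(object@lv2, collapse = " + ")),
      paste(object@outcome, "~ lv1 + lv2"),
      "lv1 ~~ lv2")
})

.fixedTerm <- function(coef, var) sprintf("%.10g*%s", coef, var)

#' @describeIn semSyntax fixed-coefficient measurement-model lines
#' @export
setMethod("semSyntax", "MeasurementModel", function(object) {
    L <- object@loadings
    i1 <- rownames(L)[L[, 1L] != 0]
    i2 <- rownames(L)[L[, 2L] != 0]
    c(paste("lv1 =~", paste(.fixedTerm(L[i1, 1L], i1), collapse = " + ")),
      paste("lv2 =~", paste(.fixedTerm(L[i2, 2L], i2), collapse = " + ")),
      paste("lv1 ~~", .fixedTerm(object@latentCov, "lv2")),
      vapply(rownames(L), function(g)
          paste(g, "~~", .fixedTerm(object@theta[g], g)), character(1)))
})

#' Write a measurement model to a text file
#'
#' Model lines in the fixed-coefficient grammar plus \code{# scale}
#' comment lines carrying the standardization moments, so the model can
#' score new samples after round-tripping.
#'
#' @param m a \linkS4class{MeasurementModel}
#' @param path destination file
#' @export
writeMeasurementModel <- function(m, path) {
    scale <- vapply(rownames(m@loadings), function(g)
        sprintf("# scale %s %.10g %.10g", g, m@center[g], m@scale[g]),
        character(1))
    writeLines(c(semSyntax(m), scale), path)
    invisible(path)
}

#' Read a measurement model from a text file
#'
#' @param path file written by \code{\link{writeMeasurementModel}}
#' @return a \linkS4class{MeasurementModel}
#' @export
readMeasurementModel <- function(path) {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln)]
    scl <- ln[startsWith(ln, "# scale")]
    mod <- ln[!startsWith(ln, "#")]
    parseSide <- function(rhs) {
        terms <- strsplit(rhs, "\\+")[[1]]
        out <- numeric(0)
        for (t in terms) {
            kv <- strsplit(trimws(t), "\\*")[[1]]
            out[trimws(kv[2L])] <- as.numeric(kv[1L])
        }
        out
    }
    lv1 <- lv2 <- NULL
    theta <- numeric(0)
    latentCov <- 0
    for (l in mod) {
        if (grepl("^lv1 =~", l)) lv1 <- parseSide(sub("^lv1 =~", "", l))
        else if (grepl("^lv2 =~", l)) lv2 <- parseSide(sub("^lv2 =~", "", l))
        else if (grepl("^lv1 ~~", l))
            latentCov <- as.numeric(strsplit(trimws(sub("^lv1 ~~", "", l)),
                                             "\\*")[[1]][1L])
        else if (grepl("~~", l)) {
            parts <- strsplit(l, "~~")[[1]]
            kv <- strsplit(trimws(parts[2L]), "\\*")[[1]]
            theta[trimws(parts[1L])] <- as.numeric(kv[1L])
        }
    }
    center <- scale <- numeric(0)
    for (l in scl) {
        f <- strsplit(l, "\\s+")[[1]]
        center[f[3L]] <- as.numeric(f[4L])
        scale[f[3L]] <- as.numeric(f[5L])
    }
    measurementModel(lv1, lv2, theta = theta, latentCov = latentCov,
                     center = center, scale = scale)
}
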