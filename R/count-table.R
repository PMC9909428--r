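#' Construct a MicrobiomeCounts object
#'
#' @param counts genus x sample matrix of non-negative integers with
#'   unique dimnames.  Duplicate genus rows are summed element-wise.
#' @param metadata optional per-sample metadata (data.frame or DataFrame)
#'   whose rows match the count columns; matched by \code{sample_id}
#'   column or rownames when present.
#' @return a \linkS4class{MicrobiomeCounts}
#' @examples
#' m <- matrix(c(3, 1, 0, 5), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' MicrobiomeCounts(m)
#' @export
MicrobiomeCounts <- function(counts, metadata = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts need genus rownames and sample colnames")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample id: ",
             paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                   collapse = ", "))
    if (anyDuplicated(rownames(counts)))
        counts <- rowsum(counts, rownames(counts), reorder = FALSE)
    storage.mode(counts) <- "double"
    cd <- NULL
    if (!is.null(metadata)) {
        metadata <- as.data.frame(metadata)
        key <- if ("sample_id" %in% names(metadata)) metadata$sample_id
               else rownames(metadata)
        missing <- setdiff(colnames(counts), key)
        if (length(missing))
            stop("metadata missing for sample(s): ",
                 paste(missing, collapse = ", "))
        cd <- S4Vectors::DataFrame(metadata[match(colnames(counts), key), ,
                                            drop = FALSE])
        rownames(cd) <- colnames(counts)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = if (is.null(cd)) S4Vectors::DataFrame(row.names = colnames(counts)) else cd)
    new("MicrobiomeCounts", se)
}

#' Read a genus x sample count table
#'
#' Tab-separated text: first row sample ids, first column genus labels.
#' Duplicate genus rows are summed element-wise; duplicate sample ids and
#' non-integer or negative cells are errors that name the offending
#' row/column.
#'
#' @param path file path
#' @return a \linkS4class{MicrobiomeCounts}
#' @export
readCountTable <- function(path) {
    if (!file.exists(path)) stop("count table not found: ", path)
    raw <- read.delim(path, check.names = FALSE, row.names = NULL,
                      colClasses = "character")
    if (ncol(raw) < 3L) stop("need at least 2 samples in ", path)
    gl <- raw[[1L]]
    m <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                   dimnames = list(gl, colnames(m))))
    bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad))
        stop("invalid count at ", gl[bad[1L, 1L]], ", ",
             colnames(m)[bad[1L, 2L]], ": '", m[bad[1L, , drop = FALSE]], "'")
    MicrobiomeCounts(num)
}

#' Write a genus x sample count table
#'
#' Inverse of \code{\link{readCountTable}}.
#'
#' @param x a \linkS4class{MicrobiomeCounts} or count matrix
#' @param path destination file
#' @export
writeCountTable <- function(x, path) {
    m <- if (is(x, "MicrobiomeCounts")) counts(x) else as.matrix(x)
    df <- data.frame(genus = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
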