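# internal helpers shared across modules

# extract a counts matrix from SCE / Matrix / base matrix input
.getCounts <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    if (!(is.matrix(x) || methods::is(x, "Matrix")))
        stop("input must be a matrix, sparse Matrix or SingleCellExperiment",
             call. = FALSE)
    if (length(x) == 0 || nrow(x) == 0 || ncol(x) == 0)
        stop("empty input", call. = FALSE)
    x
}

.checkCountValues <- function(m) {
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
    if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(v != round(v)))
        stop("counts must be integers", call. = FALSE)
    invisible(TRUE)
}

# number of nonzero entries per row, works for dense and sparse input
.rowNonzero <- function(m) {
    if (methods::is(m, "sparseMatrix"))
        Matrix::rowSums(m != 0)
    else
        rowSums(m != 0)
}

.colZeroFraction <- function(m) {
    if (methods::is(m, "sparseMatrix"))
        1 - Matrix::colSums(m != 0) / nrow(m)
    else
        colMeans(m == 0)
}

# lower median: for even n take the smaller of the two central order stats
.lowerMedian <- function(x) {
    s <- sort(x)
    s[ceiling(length(s) / 2)]
}

# scale each cell (column) to the lower-median total count of positive cells
.normalizeToMedianTotal <- function(m) {
    tot <- Matrix::colSums(m)
    med <- .lowerMedian(tot[tot > 0])
    fac <- ifelse(tot > 0, med / tot, 0)
    if (methods::is(m, "sparseMatrix"))
        m %*% Matrix::Diagonal(x = fac)
    else
        sweep(m, 2, fac, "*")
}

# wrap a counts matrix (+ annotations) into a SingleCellExperiment
.makeSCE <- function(counts, rowData = NULL, colData = NULL,
                     metadata = list()) {
    counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                          "generalMatrix")
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("peak", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
    args <- list(assays = list(counts = counts), metadata = metadata)
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    do.call(SingleCellExperiment::SingleCellExperiment, args)
}
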