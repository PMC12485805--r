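#' Read a peak-by-cell count matrix
#'
#' Accepts either a directory with the MTX triplet (`matrix.mtx`,
#' `peaks.tsv`, `barcodes.tsv`) or a single dense TSV (peaks in rows, first
#' column peak IDs, header with cell IDs). Entries must be non-negative
#' integers; a dimension mismatch between the matrix and its annotation
#' files is an error naming the files.
#'
#' A `peaks.tsv` with columns `chrom`, `start`, `end` (BED-style 0-based
#' half-open, with or without an `id` column) attaches peak coordinates as
#' `rowRanges`.
#'
#' @param path directory (MTX triplet) or TSV file
#' @return a `SingleCellExperiment` with assay `counts`
#' @examples
#' dir <- tempfile()
#' sim <- simulateSingle(newPicParams(nPeaks = 50, nCells = 10))
#' writeCounts(sim, dir)
#' sce <- readCounts(dir)
#' @export
readCounts <- function(path) {
    if (dir.exists(path)) {
        mtx <- file.path(path, "matrix.mtx")
        pk <- file.path(path, "peaks.tsv")
        bc <- file.path(path, "barcodes.tsv")
        for (f in c(mtx, pk, bc))
            if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
        m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
        peaks <- utils::read.table(pk, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
        cells <- utils::read.table(bc, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
        if (nrow(peaks) != nrow(m))
            stop("dimension mismatch: ", mtx, " has ", nrow(m),
                 " rows but ", pk, " lists ", nrow(peaks), " peaks",
                 call. = FALSE)
        if (nrow(cells) != ncol(m))
            stop("dimension mismatch: ", mtx, " has ", ncol(m),
                 " columns but ", bc, " lists ", nrow(cells), " cells",
                 call. = FALSE)
        .checkCountValues(m)
        rownames(m) <- peaks[[1]]
        colnames(m) <- cells[[1]]
        sce <- .makeSCE(m)
        if (all(c("chrom", "start", "end") %in% names(peaks))) {
            gr <- GenomicRanges::GRanges(
                peaks$chrom,
                IRanges::IRanges(peaks$start + 1L, peaks$end))
            names(gr) <- peaks[[1]]
            SummarizedExperiment::rowRanges(sce) <- gr
        }
        sce
    } else if (file.exists(path)) {
        df <- utils::read.table(path, sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE)
        m <- as.matrix(df)
        .checkCountValues(m)
        .makeSCE(m)
    } else stop("no such file or directory: ", path, call. = FALSE)
}

#' Write a count matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `peaks.tsv` (IDs plus, when `rowRanges` carry
#' coordinates, BED-style `chrom`/`start`/`end`), `barcodes.tsv` and — if
#' the object has cell annotations — `cell_metadata.tsv`.
#'
#' @param sce a `SingleCellExperiment` (or count matrix)
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeCounts <- function(sce, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- .getCounts(sce)
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    peaks <- data.frame(id = rownames(m) %||%
                            paste0("peak", seq_len(nrow(m))))
    if (methods::is(sce, "SingleCellExperiment")) {
        rr <- SummarizedExperiment::rowRanges(sce)
        if (methods::is(rr, "GRanges") && length(rr) == nrow(m)) {
            peaks$chrom <- as.character(GenomicRanges::seqnames(rr))
            peaks$start <- GenomicRanges::start(rr) - 1L
            peaks$end <- GenomicRanges::end(rr)
        }
    }
    utils::write.table(peaks, file.path(dir, "peaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(barcode = colnames(m) %||%
                       paste0("cell", seq_len(ncol(m)))),
        file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (methods::is(sce, "SingleCellExperiment") &&
        ncol(SummarizedExperiment::colData(sce)) > 0)
        utils::write.table(
            as.data.frame(SummarizedExperiment::colData(sce)),
            file.path(dir, "cell_metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = TRUE)
    invisible(dir)
}

#' Read peak annotations from BED or GFF3
#'
#' Both conventions are converted to 1-based inclusive intervals
#' internally (BED is 0-based half-open, GFF3 1-based inclusive) and a
#' `midpoint` metadata column is attached, `floor((start + end) / 2)` in
#' 1-based space. Strand is ignored: accessibility is unstranded.
#'
#' @param path BED or GFF3 file
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`
#' @return `GRanges` with `midpoint` in `mcols` and peak names
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1", bed)
#' readPeakAnnotations(bed)
#' @export
readPeakAnnotations <- function(path, format = c("auto", "bed", "gff3")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
            stop("cannot infer format from extension '", ext,
                 "'; pass format=", call. = FALSE))
    }
    gr <- rtracklayer::import(path, format = format)
    gr <- methods::as(gr, "GRanges")
    if (any(GenomicRanges::width(gr) < 1))
        stop("zero-length interval in ", path, call. = FALSE)
    GenomicRanges::strand(gr) <- "*"
    mc <- S4Vectors::mcols(gr)
    nm <- if ("name" %in% names(mc)) mc$name
          else if ("ID" %in% names(mc)) mc$ID
          else paste0("peak", seq_along(gr))
    names(gr) <- nm
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        midpoint = floor((GenomicRanges::start(gr) +
                          GenomicRanges::end(gr)) / 2))
    gr
}

#' Write ground-truth tables
#'
#' Serializes a simulation's truth (as stored in
#' `metadata(sce)$Truth` by [simulatePopulation()], or assembled by hand)
#' to stable TSV schemas: `caqtl.tsv` (`peak`, `peak_id`, `snp`,
#' `snp_id`, `chrom`, `pos`, `effect`, `sign`, `distance`),
#' `condition_da.tsv` (`peak`, `condition`, `factor`) and
#' `da_factors.tsv` (`peak` plus one column per group). Empty components
#' produce headers-only files.
#'
#' @param truth list with any of `caqtl`, `conditionDA`, `DAFactors`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
writeGroundTruth <- function(truth, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    caqtl <- truth$caqtl
    if (is.null(caqtl))
        caqtl <- data.frame(peak = integer(0), peak_id = character(0),
                            snp = integer(0), snp_id = character(0),
                            chrom = character(0), pos = integer(0),
                            effect = numeric(0), sign = integer(0),
                            distance = integer(0))
    utils::write.table(caqtl, file.path(dir, "caqtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cond <- truth$conditionDA
    if (is.null(cond))
        cond <- data.frame(peak = integer(0), condition = character(0),
                           factor = numeric(0))
    utils::write.table(cond, file.path(dir, "condition_da.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    da <- truth$DAFactors
    if (is.null(da)) da <- matrix(numeric(0), 0, 0)
    daDf <- as.data.frame(da)
    if (ncol(daDf)) names(daDf) <- paste0("Group", seq_len(ncol(daDf)))
    daDf <- cbind(peak = seq_len(nrow(daDf)), daDf)
    utils::write.table(daDf, file.path(dir, "da_factors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read ground-truth tables written by [writeGroundTruth()]
#'
#' @param dir directory containing the truth TSVs
#' @return list with `caqtl`, `conditionDA` and `DAFactors`
#' @export
readGroundTruth <- function(dir) {
    rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                        header = TRUE,
                                        stringsAsFactors = FALSE)
    da <- rd("da_factors.tsv")
    list(caqtl = rd("caqtl.tsv"),
         conditionDA = rd("condition_da.tsv"),
         DAFactors = as.matrix(da[, -1, drop = FALSE]))
}
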