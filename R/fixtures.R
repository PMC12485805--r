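#' Generate a counts fixture with known truth
#'
#' Exact forward simulation from the single-sample generative model with
#' the generating parameters attached — the oracle input for estimation
#' tests. This is a thin, seeded wrapper around [simulateSingle()].
#'
#' @param nPeaks,nCells fixture dimensions
#' @param seed RNG seed
#' @param ... further [PicParams] overrides (e.g. `lib.mu`,
#'   `peak.shape`)
#' @return a `SingleCellExperiment`; `metadata(sce)$Params` holds the true
#'   parameters
#' @examples
#' fx <- generateCountsFixture(10, 10, seed = 1)
#' metadata(fx)$Params
#' @export
generateCountsFixture <- function(nPeaks = 1000, nCells = 200, seed = 1,
                                  ...) {
    params <- newPicParams(nPeaks = nPeaks, nCells = nCells, seed = seed,
                           ...)
    simulateSingle(params)
}

#' Generate Hardy-Weinberg genotypes
#'
#' SNP positions are drawn uniformly on `[1, chromLength]`, per-SNP
#' alternate-allele frequencies from `Uniform(mafLaw[1], mafLaw[2])`, and
#' genotypes under Hardy-Weinberg equilibrium, i.e. dosage
#' `G ~ Binomial(2, p)` (genotype probabilities `(1-p)^2`, `2p(1-p)`,
#' `p^2`). The stored `maf` is the empirical folded frequency computed
#' from the dosages, so a written VCF re-reads to the identical table.
#'
#' @param nIndividuals,nSnps cohort and marker counts
#' @param mafLaw allele-frequency range (default `c(0.05, 0.5)`)
#' @param chromLength chromosome length in bp
#' @param chrom chromosome name
#' @param seed RNG seed
#' @param file optional path; when given a VCF v4.2 is written there
#' @return a [GenotypeTable]
#' @examples
#' geno <- generateGenotypeFixture(10, 50, chromLength = 1e6, seed = 1)
#' geno
#' @export
generateGenotypeFixture <- function(nIndividuals, nSnps,
                                    mafLaw = c(0.05, 0.5),
                                    chromLength = 5e7, chrom = "chr22",
                                    seed = 1, file = NULL) {
    if (nSnps > 0 && nSnps > chromLength)
        stop("more SNPs than positions", call. = FALSE)
    geno <- withr::with_seed(.streamSeed(seed, "genotypes"), {
        pos <- sort(sample.int(chromLength, nSnps))
        p <- stats::runif(nSnps, mafLaw[1], mafLaw[2])
        dos <- matrix(stats::rbinom(nIndividuals * nSnps, 2,
                                    rep(p, each = nIndividuals)),
                      nrow = nIndividuals, ncol = nSnps,
                      dimnames = list(paste0("ind", seq_len(nIndividuals)),
                                      NULL))
        alleles <- c("A", "C", "G", "T")
        ref <- sample(alleles, nSnps, replace = TRUE)
        alt <- vapply(ref, function(r)
            sample(setdiff(alleles, r), 1), character(1))
        pHat <- colMeans(dos) / 2
        snps <- GenomicRanges::GRanges(
            rep(chrom, nSnps), IRanges::IRanges(pos, width = 1),
            id = sprintf("snp%d", seq_len(nSnps)),
            ref = unname(ref), alt = unname(alt),
            maf = pmin(pHat, 1 - pHat))
        GenotypeTable(dosages = dos, snps = snps)
    })
    if (!is.null(file)) .writeVcf(geno, file, contigLength = chromLength)
    geno
}

#' Generate non-overlapping peak annotations
#'
#' Sorted, non-overlapping intervals with widths drawn uniformly from
#' `widthRange`, written as matched BED (0-based half-open) and GFF3
#' (1-based inclusive) representations of the same peaks when file paths
#' are given.
#'
#' @param nPeaks number of peaks
#' @param chromLength chromosome length in bp
#' @param widthRange min/max peak width
#' @param chrom chromosome name
#' @param seed RNG seed
#' @param bedFile,gffFile optional output paths
#' @return `GRanges` (1-based inclusive) with peak names
#' @examples
#' peaks <- generatePeakFixture(20, chromLength = 1e6, seed = 1)
#' head(peaks)
#' @export
generatePeakFixture <- function(nPeaks, chromLength = 5e7,
                                widthRange = c(200, 1000),
                                chrom = "chr22", seed = 1,
                                bedFile = NULL, gffFile = NULL) {
    gr <- withr::with_seed(.streamSeed(seed, "peaks"), {
        widths <- sample(seq(widthRange[1], widthRange[2]), nPeaks,
                         replace = TRUE)
        avail <- chromLength - sum(widths)
        if (avail <= nPeaks)
            stop("peaks do not fit on a chromosome of length ",
                 chromLength, call. = FALSE)
        cuts <- sort(sample.int(avail - 1L, nPeaks))
        starts <- cuts + cumsum(c(0L, widths[-nPeaks]))
        GenomicRanges::GRanges(
            chrom, IRanges::IRanges(starts, width = widths))
    })
    names(gr) <- paste0("peak", seq_len(nPeaks))
    if (!is.null(bedFile)) {
        writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                           GenomicRanges::start(gr) - 1L,
                           GenomicRanges::end(gr), names(gr)),
                   bedFile)
    }
    if (!is.null(gffFile)) {
        writeLines(c("##gff-version 3",
                     sprintf("%s\tpicsim\tpeak\t%d\t%d\t.\t.\t.\tID=%s",
                             chrom, GenomicRanges::start(gr),
                             GenomicRanges::end(gr), names(gr))),
                   gffFile)
    }
    gr
}
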