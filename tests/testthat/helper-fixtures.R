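# shared helpers for the test suite: tiny in-code fixtures and oracles

# small deterministic count matrix with controllable nonzero pattern
tinyCounts <- function(nPeaks = 10, nCells = 10, seed = 99) {
    withr::with_seed(seed, {
        matrix(rpois(nPeaks * nCells, 2), nPeaks, nCells)
    })
}

# hand-built genotype table: dosage matrix + SNP positions
makeGenotypes <- function(dos, pos, chrom = "chr1", maf = NULL) {
    if (is.null(maf)) {
        p <- colMeans(dos, na.rm = TRUE) / 2
        maf <- pmin(p, 1 - p)
    }
    GenotypeTable(
        dosages = dos,
        snps = GenomicRanges::GRanges(
            chrom, IRanges::IRanges(pos, width = 1),
            id = paste0("snp", seq_along(pos)),
            ref = rep("A", length(pos)), alt = rep("C", length(pos)),
            maf = maf))
}

# brute-force version of the sorted-difference comparison metrics
# (equal-length vectors only); independent of the package implementation
bruteMetrics <- function(a, b) {
    a <- a[order(a)]
    b <- b[order(b)]
    d <- abs(a - b)
    c(MAD = median(d), MAE = sum(d) / length(d),
      RMSE = sqrt(sum(d^2) / length(d)),
      oneMinusPCC = 1 - cor(a, b))
}

# self-consistent single-sample parameters: peak-mean scale matched to the
# library size and per-cell sparsity just above the structural zero rate --
# the regime estimation from real data produces, in which the generative
# parameters are identifiable from the simulated matrix
selfConsistentParams <- function(nPeaks, nCells, eta = 0.8, kappa = 0.3,
                                 sigma = 0.35, seed = 11,
                                 piMargin = 0.005) {
    mu <- log(nPeaks * kappa * gamma(1 + 1 / eta))
    p0 <- newPicParams(nPeaks = nPeaks, nCells = nCells, seed = seed,
                       lib.mu = mu, lib.sigma = sigma,
                       peak.shape = eta, peak.scale = kappa,
                       sparsity = 0)
    z0 <- estimateSparsity(simulateSingle(p0, sparsify = FALSE))
    setParam(p0, "sparsity", pmin(unname(z0) + piMargin, 1))
}
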