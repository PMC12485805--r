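test_that("population baselines honor variance settings and bypasses", {
    pop <- newPicPopParams(var.scale = 0)
    base <- withr::with_seed(1,
        samplePopulationBaselines(pop, 100, paste0("i", 1:4)))
    # zero variance scaling: every individual equals the population mean
    expect_equal(base$means, matrix(base$lambda, 100, 4,
        dimnames = list(NULL, paste0("i", 1:4))))
    # empirical bypass reproduces supplied means exactly
    mns <- withr::with_seed(2, rgamma(100, 2, 1))
    byp <- withr::with_seed(3, samplePopulationBaselines(
        pop, 100, paste0("i", 1:3), empiricalMeans = mns))
    expect_equal(unname(byp$means[, 2]), mns)
    expect_error(samplePopulationBaselines(pop, 100, "a",
        empiricalMeans = 1:5), "length nPeaks")
})

test_that("across-individual variability follows the CV-bin draw", {
    # concentrated CV bin (mean 0.2, tiny spread) at 200 individuals
    pop <- newPicPopParams(cv.bins = data.frame(
        lo = 0, hi = Inf, alpha = 1600, beta = 8000, n = NA))
    base <- withr::with_seed(4, samplePopulationBaselines(
        pop, 300, paste0("i", 1:200),
        empiricalMeans = rep(10, 300)))
    empCV <- apply(base$means, 1, sd) / rowMeans(base$means)
    expect_lt(mean(abs(empCV - base$cv)), 0.05)
    expect_lt(abs(mean(empCV) - 0.2), 0.02)
})

test_that("caQTL assignment respects window, MAF range and the count", {
    geno <- generateGenotypeFixture(20, 3000, chromLength = 5e7,
                                    seed = 5)
    peaks <- generatePeakFixture(1000, chromLength = 5e7, seed = 5)
    pop <- newPicPopParams(ca.peaks = 0.7)
    asn <- withr::with_seed(6, assignCaqtlEffects(peaks, geno, pop))
    expect_equal(nrow(asn), 700)               # round(0.7 * 1000)
    expect_true(all(asn$distance <= getParam(pop, "ca.window")))
    maf <- snpRanges(geno)$maf[asn$snp]
    expect_true(all(maf >= 0.05 & maf <= 0.5))
    expect_true(all(asn$effect > 0))
    expect_true(all(asn$sign %in% c(-1L, 1L)))
    expect_false(any(duplicated(asn$peak)))
    # ca.peaks = 0: empty assignment table
    expect_equal(nrow(withr::with_seed(7, assignCaqtlEffects(
        peaks, geno, newPicPopParams(ca.peaks = 0)))), 0)
})

test_that("tight windows restrict assignment to midpoint SNPs", {
    # peak 101-200 has midpoint 150; only the SNP at 150 is within 1 bp
    peaks <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(101, 200))
    names(peaks) <- "pk1"
    geno <- makeGenotypes(matrix(c(0L, 1L, 2L, 1L, 0L, 1L), 3, 2),
                          pos = c(150, 155))
    pop <- newPicPopParams(ca.peaks = 1, ca.window = 1,
                           ca.mafRange = c(0.01, 0.5))
    asn <- withr::with_seed(8, assignCaqtlEffects(peaks, geno, pop))
    expect_equal(asn$snp, 1L)
    expect_equal(asn$pos, 150)
    # no eligible SNP anywhere: diagnostic error
    far <- makeGenotypes(matrix(c(0L, 1L, 2L), 3, 1), pos = 5000)
    expect_error(assignCaqtlEffects(peaks, far, pop), "MAF range")
})

test_that("genotype effects follow the dosage-linear factor", {
    base <- list(means = matrix(10, 2, 3,
        dimnames = list(NULL, c("a", "b", "c"))))
    geno <- makeGenotypes(
        matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(c("a", "b", "c"))),
        pos = 100)
    asn <- data.frame(peak = 1L, snp = 1L, effect = 0.5, sign = 1L)
    out <- applyGenotypeEffects(base, geno, asn)
    expect_equal(unname(out$means[1, ]), c(10, 12.5, 15))  # x1, x1.25, x1.5
    expect_equal(unname(out$means[2, ]), rep(10, 3))       # unassigned
    # strong negative effect clamps at zero with a warning
    asn2 <- data.frame(peak = 1L, snp = 1L, effect = 2, sign = -1L)
    expect_warning(out2 <- applyGenotypeEffects(base, geno, asn2),
                   "clamped")
    expect_equal(unname(out2$means[1, ]), c(10, 0, 0))
})

test_that("condition-level DA hits its fraction and direction", {
    pop <- newPicPopParams(cond.daProb = 0.2)
    base <- list(means = matrix(10, 5000, 4,
        dimnames = list(NULL, c("a", "b", "c", "d"))))
    # single cohort: no-op
    same <- withr::with_seed(9, applyConditionDA(base,
        setNames(rep("ctl", 4), c("a", "b", "c", "d")), pop))
    expect_equal(same$baselines$means, base$means)
    expect_equal(nrow(same$truth), 0)
    # two cohorts: binomial bound on the affected count
    conds <- setNames(c("ctl", "ctl", "case", "case"),
                      c("a", "b", "c", "d"))
    res <- withr::with_seed(10, applyConditionDA(base, conds, pop))
    n <- nrow(res$truth)
    expect_lt(abs(n - 1000), 3 * sqrt(5000 * 0.2 * 0.8))
    expect_equal(res$baselines$means[, c("a", "b")],
                 base$means[, c("a", "b")])  # reference untouched
    # forced negative DA: all factors below 1
    popDown <- newPicPopParams(cond.daProb = 0.3, cond.daLoc = 1.5,
                               cond.daScale = 0.3, cond.daDownProb = 1)
    down <- withr::with_seed(11, applyConditionDA(base, conds, popDown))
    expect_true(all(down$truth$factor < 1))
})

test_that("identical individuals yield matching pseudobulk profiles", {
    geno <- makeGenotypes(matrix(1L, 3, 5,
        dimnames = list(paste0("i", 1:3))),
        pos = c(100, 300, 500, 700, 900) * 100)
    pop <- newPicPopParams(var.scale = 0, ca.peaks = 0)
    sim <- simulatePopulation(
        newPicParams(seed = 12, nPeaks = 400, sparsity = 0), pop, geno,
        cellsPerIndividual = 50)
    pb <- aggregatePseudobulk(sim)
    expect_equal(ncol(pb), 3)
    expect_gt(cor(pb[, 1], pb[, 2]), 0.9)
    expect_gt(cor(pb[, 1], pb[, 3]), 0.9)
})

test_that("a one-individual population reduces to the group simulator", {
    p <- newPicParams(nPeaks = 200, nCells = 80, seed = 13,
                      nGroups = 2, group.probs = c(0.5, 0.5))
    g <- simulateGroups(p)
    lam <- rowData(g)$Lambda
    pop <- newPicPopParams(var.scale = 0, ca.peaks = 0)
    s <- simulatePopulation(p, pop, individuals = "only",
                            cellsPerIndividual = 80,
                            empiricalMeans = lam)
    expect_identical(unname(as.matrix(assay(s))),
                     unname(as.matrix(assay(g))))
})

test_that("pseudobulk aggregation and quantile normalization behave", {
    # one cell per individual: pseudobulk is that cell's profile
    m <- withr::with_seed(14, matrix(rpois(60, 5), 20, 3))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(Individual = c("a", "b", "c")))
    pb <- aggregatePseudobulk(sce, normalize = FALSE)
    expect_equal(unname(pb), m, check.attributes = FALSE)
    # constant matrix stays constant under mean aggregation
    sceC <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = matrix(2L, 4, 6)),
        colData = S4Vectors::DataFrame(Individual = rep(c("a", "b"), 3)))
    expect_true(all(aggregatePseudobulk(sceC) == 2))
    # quantile-normalized rows: mean 0, sd 1 (ties permitting)
    pbN <- aggregatePseudobulk(
        sce, normalize = TRUE, quantileNormalize = TRUE)
    keep <- apply(pbN, 1, function(x) any(x != 0))
    expect_true(all(abs(rowMeans(pbN[keep, ])) < 1e-9))
    expect_true(all(abs(apply(pbN[keep, ], 1, sd) - 1) < 1e-6))
})

test_that("assigned peaks correlate with dosage in pseudobulk", {
    geno <- generateGenotypeFixture(30, 2000, chromLength = 5e7,
                                    seed = 15)
    peaks <- generatePeakFixture(300, chromLength = 5e7, seed = 15)
    pop <- newPicPopParams(ca.peaks = 0.5)
    sim <- simulatePopulation(newPicParams(seed = 15), pop, geno, peaks,
                              cellsPerIndividual = 30)
    tr <- metadata(sim)$Truth$caqtl
    expect_equal(nrow(tr), 150)
    pb <- aggregatePseudobulk(sim, quantileNormalize = TRUE)
    dos <- dosages(geno)
    r <- vapply(seq_len(nrow(tr)), function(k)
        suppressWarnings(cor(pb[tr$peak[k], ], dos[, tr$snp[k]])),
        numeric(1))
    signed <- r * tr$sign
    expect_gt(mean(signed, na.rm = TRUE), 0.1)
    expect_gt(mean(sign(r) == tr$sign, na.rm = TRUE), 0.7)
})

test_that("ground-truth tables round-trip through TSV", {
    geno <- generateGenotypeFixture(10, 500, chromLength = 1e7, seed = 16)
    peaks <- generatePeakFixture(100, chromLength = 1e7, seed = 16)
    sim <- simulatePopulation(
        newPicParams(seed = 16, nGroups = 2, group.probs = c(0.5, 0.5)),
        newPicPopParams(ca.peaks = 0.4), geno, peaks,
        cellsPerIndividual = 5)
    truth <- metadata(sim)$Truth
    dir <- withr::local_tempdir()
    writeGroundTruth(truth, dir)
    back <- readGroundTruth(dir)
    expect_equal(nrow(back$caqtl), nrow(truth$caqtl))
    expect_equal(back$caqtl$effect, truth$caqtl$effect)
    expect_equal(unname(back$DAFactors), unname(truth$DAFactors))
    # empty truth: headers-only files
    dir2 <- withr::local_tempdir()
    writeGroundTruth(list(), dir2)
    expect_equal(nrow(readGroundTruth(dir2)$caqtl), 0)
})
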