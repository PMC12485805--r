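test_that("group assignment follows the membership probabilities", {
    expect_equal(withr::with_seed(1, assignGroups(20, 1)), rep(1L, 20))
    expect_equal(withr::with_seed(2, assignGroups(20, c(0, 1))),
                 rep(2L, 20))
    g <- withr::with_seed(3, assignGroups(10000, c(0.5, 0.25, 0.25)))
    expect_lt(abs(mean(g == 1) - 0.5), 0.015)
    # exact multinomial: chi-square goodness of fit
    gof <- chisq.test(table(factor(g, 1:3)), p = c(0.5, 0.25, 0.25))
    expect_gt(gof$p.value, 0.001)
    expect_error(assignGroups(10, c(0.5, 0.4)), "sum to 1")
})

test_that("DA factor tables have the configured density and direction", {
    expect_true(all(withr::with_seed(4,
        sampleDAFactors(500, 2, daProb = 0)) == 1))
    da <- withr::with_seed(5, sampleDAFactors(20000, 2))
    for (g in 1:2) {
        frac <- mean(da[, g] != 1)
        expect_lt(abs(frac - 0.13),
                  3 * sqrt(0.13 * 0.87 / 20000) + 1e-9)
    }
    expect_true(all(da > 0))
    # forced down-regulation: reciprocal of a well-separated log-normal
    down <- withr::with_seed(6,
        sampleDAFactors(2000, 1, daProb = 1, daLoc = 1.5, daScale = 0.3,
                        daDownProb = 1))
    expect_true(all(down < 1))
})

test_that("batch factors follow their per-batch log-normals", {
    b <- sampleBatchFactors(rep(1L, 5), mu = 0.4, sigma = 0)
    expect_equal(b, rep(exp(0.4), 5))
    two <- sampleBatchFactors(rep(1:2, each = 3), mu = c(0, 1),
                              sigma = c(0, 0))
    expect_equal(unique(two[4:6] / two[1:3]), exp(1))
    expect_equal(sampleBatchFactors(rep(1L, 4), mu = 0, sigma = 0),
                 rep(1, 4))
    expect_error(sampleBatchFactors(1:2, sigma = -1), "sigma")
})

test_that("BCV-gamma sampling preserves means and hits the target CV", {
    m <- matrix(c(0, 5), 2, 1000, byrow = FALSE)
    out <- withr::with_seed(7, sampleCellMeansBCV(m, 0.3, 10))
    expect_true(all(out[m == 0] == 0))
    # tiny BCV: gamma concentrates on the input means
    big <- matrix(1e6, 5, 100)
    conc <- withr::with_seed(8, sampleCellMeansBCV(big, 1e-3, 1e8))
    expect_lt(max(abs(conc / big - 1)), 1e-2)
    # closed-form CV: phi = 0.5, mean term and chi-squared factor ~ off
    one <- matrix(1e8, 1, 1e5)
    draws <- withr::with_seed(9, sampleCellMeansBCV(one, 0.5, 1e12))
    expect_lt(abs(sd(draws) / mean(draws) - 0.5), 0.01)
    expect_error(sampleCellMeansBCV(matrix(-1, 1, 1), 0.3, 10), ">= 0")
})

test_that("grouped simulation separates groups in PC space", {
    p <- newPicParams(nPeaks = 2000, nCells = 500, seed = 4,
                      nGroups = 2, group.probs = c(0.5, 0.5),
                      da.loc = 1.5, da.scale = 0.4)
    sim <- simulateGroups(p)
    expect_setequal(levels(sim$Group), c("Group1", "Group2"))
    pc <- prcomp(t(log1p(as.matrix(assay(sim)))), rank. = 2)$x
    sil <- cluster::silhouette(as.integer(sim$Group), dist(pc))
    expect_gt(mean(sil[, 3]), 0.2)
    # DA truth table: exactly 1 where not DA, all positive
    da <- metadata(sim)$DAFactors
    expect_equal(dim(da), c(2000L, 2L))
    expect_true(all(da > 0))
})

test_that("batch offsets separate batches in PC space", {
    p <- newPicParams(nPeaks = 2000, nCells = 400, seed = 5,
                      nBatches = 2, batch.mu = c(0.2, 1.2),
                      batch.sigma = c(0.1, 0.1))
    sim <- simulateGroups(p)
    expect_equal(as.integer(table(sim$Batch)), c(200L, 200L))
    pc <- prcomp(t(log1p(as.matrix(assay(sim)))), rank. = 2)$x
    sil <- cluster::silhouette(as.integer(sim$Batch), dist(pc))
    expect_gt(mean(sil[, 3]), 0.1)
    expect_true(all(sim$BatchFactor > 0))
})

test_that("neutral group/batch settings reduce to the single-type model", {
    base <- newPicParams(nPeaks = 300, nCells = 120, seed = 6)
    # da.prob = 0 makes the 2-group run bit-identical to the 1-group run
    twoNeutral <- simulateGroups(setParams(base, nGroups = 2,
                                           group.probs = c(0.5, 0.5),
                                           da.prob = 0))
    one <- simulateGroups(base)
    expect_identical(as.matrix(assay(twoNeutral)), as.matrix(assay(one)))
    # and expected column sums match the single-cell-type model
    p0 <- setParam(base, "sparsity", 0)
    g <- simulateGroups(p0)
    s <- simulateSingle(p0)
    expect_lt(abs(mean(colSums(as.matrix(assay(g)))) /
                  mean(colSums(as.matrix(assay(s)))) - 1), 0.05)
})

test_that("truth tables reconstruct expected counts analytically", {
    p <- newPicParams(nPeaks = 100, nCells = 40, seed = 7,
                      nGroups = 2, group.probs = c(0.5, 0.5),
                      nBatches = 2, batch.mu = c(0, 0.5))
    sim <- simulateGroups(p, keepIntermediates = TRUE)
    lam <- rowData(sim)$Lambda
    da <- metadata(sim)$DAFactors
    grp <- as.integer(sim$Group)
    adj <- metadata(sim)$AdjustedMeans
    idx <- withr::with_seed(8, cbind(sample(100, 10, TRUE),
                                     sample(40, 10, TRUE)))
    for (k in 1:10) {
        i <- idx[k, 1]; j <- idx[k, 2]
        rel <- lam * da[, grp[j]]
        expected <- rel[i] / sum(rel) * sim$LibSize[j] *
            sim$BatchFactor[j]
        expect_equal(adj[i, j], expected, tolerance = 1e-10)
    }
})
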