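test_that("filterPeaks keeps 'at least' the detection threshold", {
    # 100 cells: a peak seen in exactly 1 cell survives the 1% default
    m <- matrix(0L, 3, 100)
    m[1, 1] <- 5L           # detected in 1 cell
    m[2, 1:50] <- 1L        # detected in 50 cells
    expect_equal(nrow(filterPeaks(m, 0.01)), 2)   # all-zero row dropped
    # brute-force toy: rows nonzero in 0, 1 and 5 of 10 cells
    m2 <- matrix(0L, 3, 10)
    m2[2, 3] <- 1L
    m2[3, 1:5] <- 2L
    expect_equal(rownames(filterPeaks(
        `rownames<-`(m2, c("a", "b", "c")), 0.2)), "c")
    # idempotence
    f1 <- filterPeaks(m, 0.01)
    expect_identical(filterPeaks(f1, 0.01), f1)
    # errors
    expect_error(filterPeaks(matrix(0L, 0, 0)), "empty input")
    expect_error(filterPeaks(matrix(0L, 2, 10), 0.5), "threshold")
})

test_that("estimateLibSize matches the log-moment oracle", {
    # degenerate: all totals exp(5)
    m <- matrix(exp(5), 1, 10)
    est <- estimateLibSize(m)
    expect_equal(est$mu, 5)
    expect_equal(est$sigma, 0)
    # recovery from LN(8.5, 0.35) totals, oracle = moments of the logs
    tot <- withr::with_seed(21, rlnorm(2000, 8.5, 0.35))
    est <- estimateLibSize(matrix(tot, 1))
    expect_equal(est$mu, mean(log(tot)))
    expect_equal(est$sigma, sqrt(mean((log(tot) - mean(log(tot)))^2)))
    expect_lt(abs(est$mu - 8.5), 0.03)
    expect_lt(abs(est$sigma - 0.35), 0.03)
    # zero-total cell dropped with a warning
    m <- cbind(matrix(exp(5), 1, 5), 0)
    expect_warning(est <- estimateLibSize(m), "zero total")
    expect_equal(est$nCells, 5)
    expect_error(suppressWarnings(estimateLibSize(matrix(c(1, 0), 1))),
                 "at least 2")
})

test_that("estimateSparsity equals brute-force zero counting", {
    expect_equal(unname(estimateSparsity(
        matrix(c(0, 0, 1, 0, 2), ncol = 1))), 0.6)
    m <- cbind(rep(0, 5), rep(1, 5))   # all-zero and fully dense cells
    expect_equal(unname(estimateSparsity(m)), c(1, 0))
    for (seed in 1:5) {
        m <- tinyCounts(20, 15, seed)
        expect_equal(unname(estimateSparsity(m)), colMeans(m == 0))
        sp <- methods::as(Matrix::Matrix(m, sparse = TRUE),
                          "CsparseMatrix")
        expect_equal(unname(estimateSparsity(sp)), colMeans(m == 0))
    }
})

test_that("estimatePeakMeans recovers family parameters on direct draws", {
    # single-cell matrix: normalization is the identity, so the fit runs
    # on the drawn values themselves; oracle = MLE on those draws
    draws <- withr::with_seed(31, rweibull(10000, 0.8, 0.3))
    fit <- estimatePeakMeans(matrix(draws, ncol = 1), "weibull")
    expect_lt(abs(fit$shape / 0.8 - 1), 0.05)
    expect_lt(abs(fit$scale / 0.3 - 1), 0.05)
    oracle <- fitdistrplus::fitdist(draws, "weibull",
        start = list(shape = 1, scale = mean(draws)))
    expect_equal(fit$shape, unname(oracle$estimate["shape"]),
                 tolerance = 1e-3)
    gdraws <- withr::with_seed(32, rgamma(10000, shape = 2, scale = 0.5))
    gfit <- estimatePeakMeans(matrix(gdraws, ncol = 1), "gamma")
    expect_lt(abs(gfit$shape / 2 - 1), 0.05)
    expect_lt(abs(gfit$scale / 0.5 - 1), 0.05)
    # all-zero peak rows are excluded before fitting
    m <- rbind(matrix(draws[1:100], ncol = 1), 0)
    expect_equal(estimatePeakMeans(m)$nPeaks, 100)
    # constant matrix: identity normalization, degenerate fit flagged
    expect_error(estimatePeakMeans(matrix(1, 5, 4)), "degenerate")
    expect_error(estimatePeakMeans(tinyCounts(), "zipf"), "unknown")
})

test_that("estimatePeakMeans is invariant to per-cell scaling", {
    m <- withr::with_seed(41, matrix(rgamma(200 * 20, 1, 1), 200, 20))
    m2 <- m
    # scale the deepest cell: it stays above the median total, so the
    # median-total reference (and hence the fit) is unchanged
    j <- which.max(colSums(m))
    m2[, j] <- m2[, j] * 7.5   # real-valued intermediate, no rounding
    f1 <- estimatePeakMeans(m)
    f2 <- estimatePeakMeans(m2)
    expect_equal(f1$shape, f2$shape, tolerance = 1e-6)
    expect_equal(f1$scale, f2$scale, tolerance = 1e-6)
})

test_that("dispersion correction follows the linear formula and clamps", {
    expect_equal(correctDispersion(4), 0.3)
    expect_equal(correctDispersion(2), 1e-4)      # crosses zero, clamped
    expect_equal(correctDispersion(2, clamp = FALSE), 0)
    expect_equal(correctDispersion(1, clamp = FALSE) -
                 correctDispersion(0, clamp = FALSE), 0.15)
})

test_that("raw common dispersion agrees with a method-of-moments oracle", {
    npk <- 200; nc <- 500
    y <- withr::with_seed(51, {
        mu <- rgamma(npk, 2, scale = 4)
        matrix(rnbinom(npk * nc, mu = rep(mu, nc), size = 1 / 0.4),
               npk, nc)
    })
    est <- estimateDispersion(y)
    # oracle: pooled (var - mean) / mean^2 across peaks
    rm_ <- rowMeans(y); rv <- apply(y, 1, var)
    mom <- sum(rv - rm_) / sum(rm_^2)
    expect_lt(abs(est$phiRaw / mom - 1), 0.2)
    expect_gt(est$phi, 0)
    expect_gt(est$df0, 0)
    expect_error(estimateDispersion(matrix(3L, 5, 5)),
                 "no dispersion signal")
})

test_that("population estimation bins peaks by 50 and fits CV gammas", {
    pb <- withr::with_seed(61, matrix(rgamma(250 * 5, 2, scale = 2),
                                      250, 5))
    colnames(pb) <- paste0("ind", 1:5)
    pop <- estimatePopulation(pb)
    bins <- getParam(pop, "cv.bins")
    expect_equal(nrow(bins), 5)         # 250 peaks -> 5 bins of 50
    expect_equal(sum(bins$n), 250)
    expect_true(all(bins$lo < bins$hi))
    expect_true(all(diff(c(bins$lo, Inf)) >= 0))
    expect_equal(getParam(pop, "sample.ids"), colnames(pb))
    expect_length(getParam(pop, "sample.shape"), 5)
    # identical individuals -> all CVs zero -> sentinel with warning
    same <- matrix(rep(rgamma(60, 2, 1), 3), ncol = 3)
    expect_warning(popd <- estimatePopulation(same, nBinSize = 60),
                   "degenerate")
    expect_gte(getParam(popd, "cv.bins")$beta[1], 1e6)
    expect_error(estimatePopulation(pb[, 1:2]), "at least 3")
})

test_that("CV bin gamma fit equals the MLE oracle on constructed CVs", {
    # build a 50-peak x 3-individual matrix whose per-peak empirical CVs
    # are exactly the drawn values: rows (m, m+d, m-d) have sd/mean = d/m
    cvs <- withr::with_seed(71, rgamma(50, shape = 2, rate = 10))
    m0 <- withr::with_seed(72, runif(50, 10, 12))
    pb <- cbind(m0, m0 + cvs * m0, m0 - cvs * m0)
    colnames(pb) <- paste0("ind", 1:3)
    pop <- suppressWarnings(estimatePopulation(pb, nBinSize = 50))
    bins <- getParam(pop, "cv.bins")
    # empirical CV of (m, m+d, m-d) is d/m (denominator n-1): sd = d
    empCV <- apply(pb, 1, sd) / rowMeans(pb)
    oracle <- fitdistrplus::fitdist(empCV, "gamma",
        start = list(shape = 2, rate = 10))
    expect_equal(bins$alpha[1], unname(oracle$estimate["shape"]),
                 tolerance = 1e-3)
    expect_equal(bins$beta[1], unname(oracle$estimate["rate"]),
                 tolerance = 1e-3)
})

test_that("caQTL effect-size fitting recovers gamma parameters", {
    x <- withr::with_seed(81, rgamma(5000, shape = 1.5, rate = 3))
    fit <- estimateCaqtlParams(x)
    expect_lt(abs(fit$shape / 1.5 - 1), 0.05)
    expect_lt(abs(fit$rate / 3 - 1), 0.05)
    expect_error(estimateCaqtlParams(rep(2, 100)), "zero-variance")
    expect_warning(fitNeg <- estimateCaqtlParams(c(-x[1:100], x[1:100])),
                   "folded")
    expect_gt(fitNeg$shape, 0)
    expect_warning(fitFew <- estimateCaqtlParams(x[1:5]),
                   "method-of-moments")
    m <- mean(x[1:5]); v <- var(x[1:5])
    expect_equal(fitFew$shape, m^2 / v)
})

test_that("picEstimate assembles a coherent PicParams object", {
    sim <- simulateSingle(newPicParams(nPeaks = 400, nCells = 150,
                                       seed = 91))
    est <- picEstimate(sim, estimateBCV = FALSE)
    expect_s4_class(est, "PicParams")
    expect_equal(getParam(est, "nCells"), 150L)
    expect_lte(getParam(est, "nPeaks"), 400L)
    expect_length(getParam(est, "sparsity"), 150)
    expect_gt(getParam(est, "peak.shape"), 0)
})
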