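#' Assign cells to groups
#'
#' I.i.d. categorical assignment of cells to groups `1..nGroups` with the
#' given membership probabilities.
#'
#' @param nCells number of cells
#' @param groupProbs probability vector (one entry per group, sums to 1)
#' @return integer label vector of length `nCells`
#' @examples
#' set.seed(1)
#' table(assignGroups(1000, c(0.5, 0.25, 0.25)))
#' @export
assignGroups <- function(nCells, groupProbs) {
    if (any(groupProbs < 0) || abs(sum(groupProbs) - 1) > 1e-9)
        stop("groupProbs must be non-negative and sum to 1", call. = FALSE)
    sample.int(length(groupProbs), nCells, replace = TRUE,
               prob = groupProbs)
}

#' Sample differential-accessibility factors
#'
#' Per group, each peak is differentially accessible with probability
#' `daProb`; DA peaks get a multiplicative factor `exp(N(daLoc, daScale))`,
#' inverted (reciprocal) for a `daDownProb` fraction so that share of DA
#' peaks loses accessibility. Non-DA peaks get a factor of exactly 1.
#'
#' @param nPeaks number of peaks
#' @param nGroups number of groups (columns of the returned table)
#' @param daProb per-peak DA probability (default 0.13, the typical
#'   fraction of differentially accessible peaks in scATAC-seq data)
#' @param daLoc,daScale log-normal location/scale of the DA factors
#' @param daDownProb fraction of DA factors inverted below 1
#' @return peak-by-group matrix of positive factors, exactly 1 where not DA
#' @examples
#' set.seed(1)
#' da <- sampleDAFactors(1000, 2)
#' mean(da[, 1] != 1)  # about 0.13
#' @export
sampleDAFactors <- function(nPeaks, nGroups, daProb = 0.13, daLoc = 0.1,
                            daScale = 0.4, daDownProb = 0.5) {
    fac <- matrix(1, nPeaks, nGroups)
    for (g in seq_len(nGroups)) {
        isDA <- stats::runif(nPeaks) < daProb
        n <- sum(isDA)
        if (n) {
            f <- exp(stats::rnorm(n, daLoc, daScale))
            down <- stats::runif(n) < daDownProb
            f[down] <- 1 / f[down]
            fac[isDA, g] <- f
        }
    }
    fac
}

#' Sample per-cell batch scaling factors
#'
#' For each cell `j` in batch `b` the technical scaling factor is drawn as
#' `omega_jb = exp(N(mu_b, sigma_b))`.
#'
#' @param batches integer batch label per cell (`1..nBatches`)
#' @param mu,sigma per-batch log-normal location/scale, recycled to the
#'   number of batches
#' @return positive factor vector, one per cell
#' @examples
#' set.seed(1)
#' sampleBatchFactors(rep(1:2, each = 3), mu = c(0, 1), sigma = c(0, 0))
#' @export
sampleBatchFactors <- function(batches, mu = 0.1, sigma = 0.1) {
    nB <- max(batches)
    mu <- rep_len(mu, nB)
    sigma <- rep_len(sigma, nB)
    if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
    exp(stats::rnorm(length(batches), mu[batches], sigma[batches]))
}

#' Sample cell-level means with trended BCV noise
#'
#' Adds biological variability to a matrix of adjusted means. Each peak
#' draws a biological coefficient of variation
#' `BCV_i = (phi + 1/sqrt(mean_i)) * sqrt(df0 / chisq_df0)` — a scaled
#' inverse chi-squared draw around a mean-decreasing trend, so more
#' accessible peaks are less variable — and each entry is replaced by
#' `Gamma(shape = 1/BCV_i^2, scale = mean_ij * BCV_i^2)`, preserving the
#' expectation with CV `BCV_i`. Zero means stay exactly zero.
#'
#' @param means peak-by-cell matrix of non-negative adjusted means
#' @param phi common BCV
#' @param df0 prior degrees of freedom of the inverse chi-squared draw
#' @return matrix of the same dimensions; attribute `"bcv"` carries the
#'   realized per-peak BCV values
#' @examples
#' set.seed(1)
#' m <- matrix(5, 10, 4)
#' noisy <- sampleCellMeansBCV(m, phi = 0.3, df0 = 10)
#' @export
sampleCellMeansBCV <- function(means, phi, df0) {
    if (any(means < 0)) stop("means must be >= 0", call. = FALSE)
    np <- nrow(means); nc <- ncol(means)
    rm <- rowMeans(means)
    trend <- phi + 1 / sqrt(pmax(rm, .Machine$double.eps))
    bcv <- trend * sqrt(df0 / stats::rchisq(np, df = df0))
    shape <- 1 / bcv^2
    out <- matrix(stats::rgamma(np * nc,
                                shape = rep(shape, times = nc),
                                scale = as.vector(means) *
                                        rep(bcv^2, times = nc)),
                  np, nc)
    out[means == 0] <- 0
    attr(out, "bcv") <- bcv
    out
}

# even batch split when batchCells is not given
.resolveBatches <- function(nCells, nBatches, batchCells) {
    if (nBatches == 1L) return(rep(1L, nCells))
    if (!length(batchCells)) {
        base <- nCells %/% nBatches
        batchCells <- rep(base, nBatches)
        extra <- nCells - base * nBatches
        if (extra) batchCells[seq_len(extra)] <- base + 1L
    }
    rep(seq_len(nBatches), times = batchCells)
}

# core count sampler shared by the group and population pipelines:
# relMeans (peaks x cells) already carries DA/batch/genotype structure;
# columns are normalized to sum 1, scaled by sampled library sizes,
# BCV-gamma perturbed, Poisson sampled and sparsity-masked.
.simulateCells <- function(relMeans, params, seed, stream,
                           cellFactors = NULL,
                           keepIntermediates = FALSE) {
    nc <- ncol(relMeans)
    L <- .withStream(seed, paste0(stream, "/lib"),
        sampleLibrarySizes(nc, getParam(params, "lib.mu"),
                           getParam(params, "lib.sigma")))
    csum <- colSums(relMeans)
    if (any(csum <= 0))
        stop("cell with no positive peak means", call. = FALSE)
    lamBar <- sweep(relMeans, 2, csum, "/")
    # per-cell technical factors (batches) scale the effective depth:
    # a cell-wide scalar would otherwise cancel in the normalization
    eff <- if (is.null(cellFactors)) L else L * cellFactors
    adj <- sweep(lamBar, 2, eff, "*")
    cellMeans <- .withStream(seed, paste0(stream, "/bcv"),
        sampleCellMeansBCV(adj, getParam(params, "bcv.phi"),
                           getParam(params, "bcv.df0")))
    counts <- .withStream(seed, paste0(stream, "/counts"),
        matrix(stats::rpois(length(cellMeans), cellMeans),
               nrow(cellMeans), nc))
    pi <- .alignSparsity(.withStream(seed, paste0(stream, "/pi"),
        .resolveSparsity(getParam(params, "sparsity"), nc)), eff)
    counts <- .withStream(seed, paste0(stream, "/mask"),
        applySparsity(counts, pi))
    out <- list(counts = counts, libSize = L, pi = pi)
    if (keepIntermediates) out$adjustedMeans <- adj
    out
}

#' Simulate cell groups and batches for a single sample
#'
#' Extends [simulateSingle()] to heterogeneous samples: peak means get a
#' per-group multiplicative DA factor, are normalized per cell and scaled
#' by the library size times the cell's batch factor into adjusted means
#' (a cell-wide batch scalar acts on effective depth; applied before
#' normalization it would cancel), perturbed by trended BCV-gamma noise
#' ([sampleCellMeansBCV()]), Poisson sampled and sparsity-masked. Group/batch structure is read from `params`
#' (`nGroups`, `group.probs`, `da.*`, `nBatches`, `batchCells`,
#' `batch.*`). With one group no DA is applied; with one batch no batch
#' factors are applied.
#'
#' @param params a [PicParams] object
#' @param keepIntermediates keep the adjusted-mean matrix in
#'   `metadata(sce)$AdjustedMeans` (handy for verifying expectations on
#'   small runs; off by default to save memory)
#' @return a `SingleCellExperiment`; `colData` carries `Group`, `Batch`,
#'   `BatchFactor`, `LibSize`, `TargetSparsity`; `metadata` carries
#'   `Params` and the full `DAFactors` peak-by-group truth table
#' @examples
#' params <- newPicParams(nPeaks = 300, nCells = 100, nGroups = 2,
#'                        group.probs = c(0.5, 0.5), seed = 2)
#' sim <- simulateGroups(params)
#' table(sim$Group)
#' @export
simulateGroups <- function(params, keepIntermediates = FALSE) {
    methods::validObject(params)
    np <- getParam(params, "nPeaks")
    nc <- getParam(params, "nCells")
    nG <- getParam(params, "nGroups")
    nB <- getParam(params, "nBatches")
    seed <- getParam(params, "seed")

    pm <- .withStream(seed, "peakmeans",
        samplePeakMeans(np, getParam(params, "peak.family"),
                        getParam(params, "peak.shape"),
                        getParam(params, "peak.scale"),
                        getParam(params, "peak.extra")))
    groups <- .withStream(seed, "groups:1",
        assignGroups(nc, getParam(params, "group.probs")))
    da <- if (nG > 1) {
        .withStream(seed, "da",
            sampleDAFactors(np, nG, getParam(params, "da.prob"),
                            getParam(params, "da.loc"),
                            getParam(params, "da.scale"),
                            getParam(params, "da.downProb")))
    } else matrix(1, np, 1)
    batches <- .resolveBatches(nc, nB, getParam(params, "batchCells"))
    wb <- if (nB > 1) {
        .withStream(seed, "batch",
            sampleBatchFactors(batches, getParam(params, "batch.mu"),
                               getParam(params, "batch.sigma")))
    } else rep(1, nc)

    relMeans <- da[, groups, drop = FALSE] * pm$lambda
    res <- .simulateCells(relMeans, params, seed, "cells:1",
                          cellFactors = wb, keepIntermediates)

    meta <- list(Params = params, DAFactors = da)
    if (keepIntermediates) meta$AdjustedMeans <- res$adjustedMeans
    .makeSCE(res$counts,
        rowData = S4Vectors::DataFrame(Lambda = pm$lambda,
                                       LambdaBar = pm$lambdaBar),
        colData = S4Vectors::DataFrame(
            Group = factor(paste0("Group", groups)),
            Batch = factor(paste0("Batch", batches)),
            BatchFactor = wb,
            LibSize = res$libSize,
            TargetSparsity = res$pi),
        metadata = meta)
}
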