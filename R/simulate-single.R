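#' Sample cell library sizes
#'
#' Library sizes are log-normal: `L_j = exp(N(mu, sigma))`.
#'
#' @param nCells number of cells
#' @param mu,sigma parameters of the natural-log library size
#' @return positive numeric vector of length `nCells`
#' @examples
#' set.seed(1); sampleLibrarySizes(5, 8.5, 0.35)
#' @export
sampleLibrarySizes <- function(nCells, mu, sigma) {
    stats::rlnorm(nCells, meanlog = mu, sdlog = sigma)
}

#' Sample peak accessibility means
#'
#' Draws per-peak means from the configured family and returns both the raw
#' draws and their normalized version (summing to 1), which is what the
#' Poisson rates are built from.
#'
#' @param nPeaks number of peaks
#' @param family,shape,scale,extra family specification (see
#'   [estimatePeakMeans()])
#' @return list with `lambda` (raw means) and `lambdaBar`
#'   (`lambda / sum(lambda)`)
#' @examples
#' set.seed(1)
#' pm <- samplePeakMeans(100, "weibull", shape = 0.8, scale = 0.3)
#' sum(pm$lambdaBar)  # 1
#' @export
samplePeakMeans <- function(nPeaks, family = "weibull", shape = 0.8,
                            scale = 0.3, extra = list()) {
    lambda <- .sampleFamily(nPeaks, family, shape, scale, extra)
    list(lambda = lambda, lambdaBar = lambda / sum(lambda))
}

#' Simulate true Poisson counts
#'
#' `Y_ij ~ Poisson(lambdaBar_i * L_j)`, independent entries. Because the
#' normalized means sum to 1, each column sum is unbiased for its library
#' size.
#'
#' @param lambdaBar normalized peak means (non-negative)
#' @param libSizes per-cell library sizes (positive)
#' @return integer matrix of dimension `length(lambdaBar)` x
#'   `length(libSizes)`
#' @examples
#' set.seed(1)
#' simulateTrueCounts(c(0.5, 0.5), c(10, 20))
#' @export
simulateTrueCounts <- function(lambdaBar, libSizes) {
    np <- length(lambdaBar); nc <- length(libSizes)
    mu <- outer(lambdaBar, libSizes)
    matrix(stats::rpois(np * nc, mu), nrow = np, ncol = nc)
}

#' Apply calibrated Bernoulli sparsity
#'
#' `pi_j` is the *target final* zero fraction of cell `j`. Among currently
#' nonzero entries each is zeroed independently with probability
#' `q_j = max(0, (pi_j - z0_j) / (1 - z0_j))` where `z0_j` is the cell's
#' pre-existing zero fraction, so the expected final zero fraction equals
#' `pi_j` and counts never increase. Cells already sparser than their
#' target are left untouched.
#'
#' @param counts peak-by-cell matrix
#' @param pi per-cell target zero fraction in `[0, 1]` (recycled if
#'   scalar)
#' @return matrix of the same dimensions with additional zeros
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(200, 5), 20, 10)
#' sp <- applySparsity(m, 0.8)
#' colMeans(sp == 0)
#' @export
applySparsity <- function(counts, pi) {
    if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]", call. = FALSE)
    pi <- rep_len(pi, ncol(counts))
    for (j in seq_len(ncol(counts))) {
        col <- counts[, j]
        z0 <- mean(col == 0)
        q <- max(0, (pi[j] - z0) / max(1 - z0, .Machine$double.eps))
        if (q > 0) {
            nz <- which(col != 0)
            drop <- nz[stats::runif(length(nz)) < q]
            if (length(drop)) counts[drop, j] <- 0
        }
    }
    counts
}

# resolve a per-cell sparsity target vector from the stored parameter:
# recycle a scalar, pass through an exact-length vector, otherwise resample
# with replacement to preserve the empirical sparsity distribution
.resolveSparsity <- function(pi, nCells) {
    if (length(pi) == 1) rep(pi, nCells)
    else if (length(pi) == nCells) pi
    else sample(pi, nCells, replace = TRUE)
}

# pair sparsity targets with cells by depth rank: the deepest cell gets
# the smallest target. Sparsity and depth are strongly negatively coupled
# in scATAC-seq data (estimated pi_j falls with library size); ignoring
# the coupling would only ever add zeros on deep cells and deflate the
# re-simulated depth distribution.
.alignSparsity <- function(pi, libSizes) {
    sort(pi)[rank(-libSizes, ties.method = "first")]
}

#' Simulate a single-cell-type count matrix
#'
#' Composes the four sampling steps of the single-sample generative model:
#' log-normal library sizes, family-distributed peak means (normalized to
#' sum to 1), Poisson counts with rate `lambdaBar_i * L_j`, and calibrated
#' Bernoulli sparsity. Each step runs on its own named RNG substream of
#' `seed`, so the whole run is reproducible and e.g. changing `nCells`
#' leaves the peak-mean draw untouched.
#'
#' @param params a [PicParams] object
#' @param sparsify apply the sparsity-masking step? (default `TRUE`)
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`; `rowData` carries the realized `Lambda` and `LambdaBar`,
#'   `colData` the realized `LibSize` and per-cell `TargetSparsity`, and
#'   `metadata(sce)$Params` the parameters used (the full ground truth)
#' @examples
#' sim <- simulateSingle(newPicParams(nPeaks = 200, nCells = 50, seed = 3))
#' sim
#' @export
simulateSingle <- function(params, sparsify = TRUE) {
    methods::validObject(params)
    np <- getParam(params, "nPeaks")
    nc <- getParam(params, "nCells")
    seed <- getParam(params, "seed")

    pm <- .withStream(seed, "peakmeans",
        samplePeakMeans(np, getParam(params, "peak.family"),
                        getParam(params, "peak.shape"),
                        getParam(params, "peak.scale"),
                        getParam(params, "peak.extra")))
    L <- .withStream(seed, "lib",
        sampleLibrarySizes(nc, getParam(params, "lib.mu"),
                           getParam(params, "lib.sigma")))
    counts <- .withStream(seed, "counts",
        simulateTrueCounts(pm$lambdaBar, L))
    pi <- .alignSparsity(.withStream(seed, "pi",
        .resolveSparsity(getParam(params, "sparsity"), nc)), L)
    if (sparsify)
        counts <- .withStream(seed, "mask", applySparsity(counts, pi))

    .makeSCE(counts,
        rowData = S4Vectors::DataFrame(Lambda = pm$lambda,
                                       LambdaBar = pm$lambdaBar),
        colData = S4Vectors::DataFrame(LibSize = L, TargetSparsity = pi),
        metadata = list(Params = params))
}
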