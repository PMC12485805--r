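#' Filter peaks by detection rate
#'
#' Keeps peaks detected (nonzero) in at least `ceiling(minCellFrac * nCells)`
#' cells — "at least", so with 100 cells and the default 1% threshold a peak
#' seen in exactly one cell is retained. The cell set is unchanged and all
#' annotations are subset consistently.
#'
#' @param counts peak-by-cell count matrix, sparse matrix or
#'   [SingleCellExperiment::SingleCellExperiment]
#' @param minCellFrac minimum fraction of cells a peak must be detected in
#'   (default 0.01)
#' @return the input restricted to retained peaks (same class as input)
#' @examples
#' sim <- simulateSingle(newPicParams(nPeaks = 100, nCells = 50))
#' filtered <- filterPeaks(sim, minCellFrac = 0.05)
#' @export
filterPeaks <- function(counts, minCellFrac = 0.01) {
    m <- .getCounts(counts)
    if (minCellFrac < 0 || minCellFrac > 1)
        stop("minCellFrac must lie in [0, 1]", call. = FALSE)
    thresh <- ceiling(minCellFrac * ncol(m))
    keep <- .rowNonzero(m) >= thresh
    if (!any(keep))
        stop("all peaks removed at detection threshold ", thresh,
             " cells (minCellFrac = ", minCellFrac, ")", call. = FALSE)
    counts[keep, , drop = FALSE]
}

#' Estimate log-normal library-size parameters
#'
#' Library size (total counts per cell) is modeled as log-normal; this
#' returns the maximum-likelihood parameters of the natural-log totals.
#' Cells with zero total are dropped with a warning.
#'
#' @inheritParams filterPeaks
#' @return list with `mu` (mean of log totals), `sigma` (MLE sd of log
#'   totals) and `nCells` (positive-total cells used)
#' @examples
#' sim <- simulateSingle(newPicParams(nPeaks = 500, nCells = 100))
#' estimateLibSize(sim)
#' @export
estimateLibSize <- function(counts) {
    m <- .getCounts(counts)
    tot <- Matrix::colSums(m)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " cell(s) with zero total dropped before ",
                "library-size estimation")
        tot <- tot[tot > 0]
    }
    if (length(tot) < 2)
        stop("need at least 2 cells with positive totals", call. = FALSE)
    lt <- log(tot)
    mu <- mean(lt)
    list(mu = mu, sigma = sqrt(mean((lt - mu)^2)), nCells = length(tot))
}

#' Estimate the peak-mean distribution
#'
#' Each cell is scaled to the dataset's (lower) median total count, per-peak
#' means are taken across cells, all-zero peaks are excluded, and the chosen
#' family is fit by maximum likelihood to the nonzero means.
#'
#' @inheritParams filterPeaks
#' @param family distribution family for the nonzero peak means: one of
#'   `"weibull"` (default), `"gamma"`, `"pareto"`, `"lnorm"`, `"lngamma"`
#' @return list with `family`, `shape`, `scale`, `extra` (family-specific
#'   auxiliaries) and `nPeaks` (nonzero peaks used)
#' @examples
#' sim <- simulateSingle(newPicParams(nPeaks = 2000, nCells = 200))
#' fit <- estimatePeakMeans(sim)
#' c(fit$shape, fit$scale)
#' @export
estimatePeakMeans <- function(counts, family = "weibull") {
    m <- .getCounts(counts)
    .checkFamily(family)
    norm <- .normalizeToMedianTotal(m)
    pm <- Matrix::rowMeans(norm)
    pm <- pm[pm > 0]
    if (length(pm) < 3)
        stop("fewer than 3 nonzero peak means; cannot fit", call. = FALSE)
    fit <- .fitFamily(pm, family)
    fit$nPeaks <- length(pm)
    fit
}

#' Estimate per-cell sparsity
#'
#' The Bernoulli sparsity parameter of cell `j` is simply its observed zero
#' fraction: `pi_j = (# zero entries in cell j) / nPeaks`.
#'
#' @inheritParams filterPeaks
#' @return numeric vector `pi` with one zero-proportion per cell
#' @examples
#' m <- matrix(c(0, 0, 1, 0, 2), ncol = 1)
#' estimateSparsity(m)  # 0.6
#' @export
estimateSparsity <- function(counts) {
    m <- .getCounts(counts)
    pi <- .colZeroFraction(m)
    names(pi) <- colnames(m)
    pi
}

#' Apply the linear dispersion correction
#'
#' The raw common dispersion over-estimates the biological coefficient of
#' variation on synthetic data, so a fixed linear correction is applied:
#' `phi = -0.3 + 0.15 * phiRaw`, clamped below at `eps` (the corrected
#' value can cross zero while a BCV must stay positive).
#'
#' @param phiRaw raw common dispersion estimate(s)
#' @param clamp clamp the result below at `eps`? (default `TRUE`)
#' @param eps positive lower clamp (default 1e-4)
#' @return corrected dispersion, same length as `phiRaw`
#' @examples
#' correctDispersion(4)                  # 0.3
#' correctDispersion(2)                  # clamped to 1e-4
#' correctDispersion(2, clamp = FALSE)   # 0
#' @export
correctDispersion <- function(phiRaw, clamp = TRUE, eps = 1e-4) {
    phi <- -0.3 + 0.15 * phiRaw
    if (clamp) phi <- pmax(eps, phi)
    phi
}

#' Estimate the common biological coefficient of variation
#'
#' Fits the negative-binomial mean-dispersion model with
#' [edgeR::estimateDisp()] to obtain a raw common dispersion, applies the
#' linear correction of [correctDispersion()], and takes the prior degrees
#' of freedom `df0` of the scaled inverse chi-squared BCV distribution from
#' the spread of per-peak dispersions around the common trend (edgeR's
#' prior df; defaults to 8 when that estimate is unstable).
#'
#' @inheritParams filterPeaks
#' @param groups optional per-cell group labels used in the design
#' @param df0Default value used for `df0` when the prior-df estimate is
#'   non-finite (default 8)
#' @return list with `phi` (corrected, clamped), `phiRaw` and `df0`
#' @examples
#' sim <- simulateSingle(newPicParams(nPeaks = 300, nCells = 100))
#' estimateDispersion(sim)
#' @export
estimateDispersion <- function(counts, groups = NULL, df0Default = 8) {
    m <- .getCounts(counts)
    if (ncol(m) < 2) stop("need at least 2 cells", call. = FALSE)
    dense <- as.matrix(m)
    if (max(dense) == min(dense))
        stop("no dispersion signal: all counts are equal", call. = FALSE)
    if (is.null(groups)) groups <- rep(1L, ncol(dense))
    dge <- edgeR::DGEList(counts = dense, group = factor(groups))
    dge <- suppressMessages(edgeR::estimateDisp(dge))
    phiRaw <- dge$common.dispersion
    df0 <- stats::median(dge$prior.df)
    if (!is.finite(df0) || df0 <= 0) df0 <- df0Default
    list(phi = correctDispersion(phiRaw), phiRaw = phiRaw, df0 = df0)
}

#' Estimate all single-sample parameters from a count matrix
#'
#' Convenience wrapper running peak filtering, library-size, peak-mean,
#' sparsity and (optionally) dispersion estimation, returning a ready-to-use
#' [PicParams] object. Cells with zero total counts are dropped up front
#' with a warning.
#'
#' @inheritParams filterPeaks
#' @param family peak-mean family passed to [estimatePeakMeans()]
#' @param estimateBCV also run [estimateDispersion()]? (slower; default
#'   `TRUE`)
#' @param minCellFrac detection threshold passed to [filterPeaks()]
#' @return a [PicParams] object with `nPeaks`/`nCells` matching the
#'   filtered input
#' @examples
#' sim <- simulateSingle(newPicParams(nPeaks = 500, nCells = 100))
#' params <- picEstimate(sim, estimateBCV = FALSE)
#' params
#' @export
picEstimate <- function(counts, family = "weibull", estimateBCV = TRUE,
                        minCellFrac = 0.01) {
    m <- .getCounts(counts)
    tot <- Matrix::colSums(m)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " zero-total cell(s) dropped before ",
                "estimation")
        m <- m[, tot > 0, drop = FALSE]
    }
    m <- filterPeaks(m, minCellFrac)
    lib <- estimateLibSize(m)
    peak <- estimatePeakMeans(m, family)
    pi <- estimateSparsity(m)
    params <- newPicParams(
        nPeaks = nrow(m), nCells = ncol(m),
        lib.mu = lib$mu, lib.sigma = lib$sigma,
        peak.family = peak$family, peak.shape = peak$shape,
        peak.scale = peak$scale, peak.extra = peak$extra,
        sparsity = unname(pi))
    if (estimateBCV) {
        bcv <- estimateDispersion(m)
        params <- setParams(params, bcv.phi = bcv$phi, bcv.df0 = bcv$df0)
    }
    params
}
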