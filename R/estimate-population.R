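#' Estimate population-level parameters from pseudobulk
#'
#' From a peak-by-individual pseudobulk matrix this fits, per individual,
#' the configured family to that individual's nonzero peak means, and
#' captures the population mean-variance relationship by ordering peaks by
#' across-individual mean accessibility, chunking them into consecutive
#' bins of `nBinSize` peaks, computing each peak's coefficient of variation
#' (sd/mean across individuals) and fitting a gamma distribution to each
#' bin's CVs (shape `alpha_v`, rate `beta_v`). A trailing bin with fewer
#' than 3 peaks is merged into its predecessor.
#'
#' @param pseudobulk peak-by-individual numeric matrix (e.g. from
#'   [aggregatePseudobulk()])
#' @param nBinSize peaks per CV bin (default 50)
#' @param family peak-mean family for the per-individual fits
#' @return a [PicPopParams] object carrying the per-individual fits and CV
#'   bins (caQTL and condition-DA settings keep their defaults)
#' @examples
#' pb <- matrix(rgamma(250 * 5, 2, 1), 250, 5,
#'              dimnames = list(NULL, paste0("ind", 1:5)))
#' pop <- estimatePopulation(pb)
#' getParam(pop, "cv.bins")
#' @export
estimatePopulation <- function(pseudobulk, nBinSize = 50,
                               family = "weibull") {
    m <- as.matrix(pseudobulk)
    if (ncol(m) < 3)
        stop("need at least 3 individuals", call. = FALSE)
    ids <- colnames(m)
    if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(m)))

    shape <- scale <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        v <- m[, j]
        fit <- .fitFamily(v[v > 0], family)
        shape[j] <- fit$shape
        scale[j] <- fit$scale
    }

    mu <- rowMeans(m)
    keep <- mu > 0
    mu <- mu[keep]
    cv <- apply(m[keep, , drop = FALSE], 1, stats::sd) / mu
    ord <- order(mu)

    n <- length(ord)
    if (n < nBinSize) {
        warning("fewer peaks (", n, ") than one bin of ", nBinSize,
                "; using a single CV bin")
        binId <- rep(1L, n)
    } else {
        binId <- ceiling(seq_len(n) / nBinSize)
        # trailing runt merges into its predecessor
        last <- max(binId)
        if (sum(binId == last) < 3 && last > 1)
            binId[binId == last] <- last - 1L
    }

    bins <- lapply(split(seq_len(n), binId), function(idx) {
        pk <- ord[idx]
        vals <- cv[pk]
        lo <- min(mu[pk]); hi <- max(mu[pk])
        vals <- vals[is.finite(vals)]
        if (length(vals) < 3 || stats::sd(vals) == 0 || all(vals == 0)) {
            warning("degenerate CV bin [", format(lo, digits = 3), ", ",
                    format(hi, digits = 3),
                    "]: zero or constant variation; using sentinel fit")
            data.frame(lo = lo, hi = hi, alpha = 1, beta = 1e6,
                       n = length(idx))
        } else {
            vals <- vals[vals > 0]
            fit <- .fitFamily(vals, "gamma")
            data.frame(lo = lo, hi = hi, alpha = fit$shape,
                       beta = 1 / fit$scale, n = length(idx))
        }
    })
    bins <- do.call(rbind, bins)
    rownames(bins) <- NULL
    # widen to partition the full observed range
    bins$lo[1] <- 0
    bins$hi[nrow(bins)] <- Inf
    if (nrow(bins) > 1)
        bins$lo[-1] <- bins$hi[-nrow(bins)]

    newPicPopParams(peak.family = family, sample.ids = ids,
                    sample.shape = shape, sample.scale = scale,
                    cv.bins = bins)
}

#' Estimate the caQTL effect-size distribution
#'
#' Fits a gamma distribution by maximum likelihood to the magnitudes of
#' empirical caQTL effect sizes (signs are handled separately at
#' simulation). Negative inputs are folded to their absolute value with a
#' warning; with fewer than 10 values a method-of-moments fit is used.
#'
#' @param effectSizes numeric vector of effect sizes (magnitudes used)
#' @return list with gamma `shape` (alpha_c) and `rate` (beta_c)
#' @examples
#' estimateCaqtlParams(rgamma(500, shape = 1.5, rate = 3))
#' @export
estimateCaqtlParams <- function(effectSizes) {
    x <- effectSizes[is.finite(effectSizes)]
    if (any(x < 0)) {
        warning("negative effect sizes folded to magnitudes")
        x <- abs(x)
    }
    x <- x[x > 0]
    if (length(x) == 0)
        stop("no positive effect sizes provided", call. = FALSE)
    if (stats::sd(x) == 0)
        stop("zero-variance effect sizes", call. = FALSE)
    if (length(x) < 10) {
        warning("fewer than 10 effect sizes; using method-of-moments fit")
        m <- mean(x); v <- stats::var(x)
        return(list(shape = m^2 / v, rate = m / v))
    }
    fit <- .fitFamily(x, "gamma")
    list(shape = fit$shape, rate = 1 / fit$scale)
}
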