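#' PicParams: parameters of the single-sample generative model
#'
#' Holds every tunable of the single-sample simulation: matrix dimensions,
#' log-normal library-size parameters, the peak-mean distribution family and
#' its shape/scale, per-cell sparsity targets, the common biological
#' coefficient of variation (BCV) and its prior degrees of freedom, and the
#' group/batch configuration used by [simulateGroups()].
#'
#' Create objects with [newPicParams()] and manipulate them with
#' [getParam()]/[setParam()]/[setParams()] rather than touching slots.
#'
#' @section Parameters:
#' \describe{
#'   \item{nPeaks, nCells}{matrix dimensions.}
#'   \item{seed}{base seed; every sampling step derives a named substream
#'     from it so e.g. changing `nCells` does not perturb the peak-mean
#'     draw.}
#'   \item{lib.mu, lib.sigma}{mean and sd of the natural-log library size.}
#'   \item{peak.family}{one of `"weibull"`, `"gamma"`, `"pareto"`,
#'     `"lnorm"`, `"lngamma"` (lognormal-gamma mixture).}
#'   \item{peak.shape, peak.scale, peak.extra}{family parameters; `extra`
#'     carries family-specific auxiliaries (e.g. mixture weight).}
#'   \item{sparsity}{target final zero fraction per cell; scalar or a
#'     vector resampled with replacement to `nCells`.}
#'   \item{bcv.phi, bcv.df0}{common BCV and prior df of its scaled
#'     inverse chi-squared distribution.}
#'   \item{nGroups, group.probs}{cell groups and membership probabilities.}
#'   \item{da.prob, da.loc, da.scale, da.downProb}{per-peak probability of
#'     differential accessibility, log-normal location/scale of DA factors,
#'     and the fraction of DA factors inverted to be < 1.}
#'   \item{nBatches, batchCells, batch.mu, batch.sigma}{batch layout and
#'     per-batch log-normal factor parameters (recycled to `nBatches`).}
#' }
#'
#' @name PicParams
#' @aliases PicParams-class
#' @exportClass PicParams
setClass("PicParams",
    slots = c(
        nPeaks = "integer",
        nCells = "integer",
        seed = "integer",
        lib.mu = "numeric",
        lib.sigma = "numeric",
        peak.family = "character",
        peak.shape = "numeric",
        peak.scale = "numeric",
        peak.extra = "list",
        sparsity = "numeric",
        bcv.phi = "numeric",
        bcv.df0 = "numeric",
        nGroups = "integer",
        group.probs = "numeric",
        da.prob = "numeric",
        da.loc = "numeric",
        da.scale = "numeric",
        da.downProb = "numeric",
        nBatches = "integer",
        batchCells = "integer",
        batch.mu = "numeric",
        batch.sigma = "numeric"),
    prototype = list(
        nPeaks = 5000L,
        nCells = 500L,
        seed = 1L,
        lib.mu = 8.5,
        lib.sigma = 0.35,
        peak.family = "weibull",
        peak.shape = 0.8,
        peak.scale = 0.3,
        peak.extra = list(),
        sparsity = 0.9,
        bcv.phi = 0.2,
        bcv.df0 = 8,
        nGroups = 1L,
        group.probs = 1,
        da.prob = 0.13,
        da.loc = 0.1,
        da.scale = 0.4,
        da.downProb = 0.5,
        nBatches = 1L,
        batchCells = integer(0),
        batch.mu = 0.1,
        batch.sigma = 0.1))

setValidity("PicParams", function(object) {
    msg <- NULL
    if (object@nPeaks < 1L) msg <- c(msg, "nPeaks must be >= 1")
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (!is.finite(object@lib.mu)) msg <- c(msg, "lib.mu must be finite")
    if (object@lib.sigma < 0) msg <- c(msg, "lib.sigma must be >= 0")
    if (!object@peak.family %in% .peakFamilies)
        msg <- c(msg, paste0("peak.family must be one of: ",
                             paste(.peakFamilies, collapse = ", ")))
    if (object@peak.shape <= 0) msg <- c(msg, "peak.shape must be > 0")
    if (object@peak.scale <= 0) msg <- c(msg, "peak.scale must be > 0")
    if (any(object@sparsity < 0 | object@sparsity > 1))
        msg <- c(msg, "sparsity values must lie in [0, 1]")
    if (object@bcv.phi <= 0) msg <- c(msg, "bcv.phi must be > 0")
    if (object@bcv.df0 <= 0) msg <- c(msg, "bcv.df0 must be > 0")
    if (object@nGroups < 1L) msg <- c(msg, "nGroups must be >= 1")
    if (length(object@group.probs) != object@nGroups)
        msg <- c(msg, "group.probs must have length nGroups")
    if (any(object@group.probs < 0) ||
        abs(sum(object@group.probs) - 1) > 1e-9)
        msg <- c(msg, "group.probs must be non-negative and sum to 1")
    if (object@da.prob < 0 || object@da.prob > 1)
        msg <- c(msg, "da.prob must lie in [0, 1]")
    if (object@da.downProb < 0 || object@da.downProb > 1)
        msg <- c(msg, "da.downProb must lie in [0, 1]")
    if (object@nBatches < 1L) msg <- c(msg, "nBatches must be >= 1")
    if (length(object@batchCells) &&
        (length(object@batchCells) != object@nBatches ||
         sum(object@batchCells) != object@nCells))
        msg <- c(msg, "batchCells must have length nBatches and sum to nCells")
    if (any(object@batch.sigma < 0)) msg <- c(msg, "batch.sigma must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' PicPopParams: population-level parameters
#'
#' Parameters governing inter-individual variability and genetic effects:
#' per-individual peak-mean fits, mean-binned coefficient-of-variation gamma
#' fits, the caQTL effect-size gamma distribution, caQTL assignment settings
#' (fraction of peaks, MAF range, cis window), and condition-level
#' differential accessibility.
#'
#' Create with [newPicPopParams()] or estimate from a peak-by-individual
#' pseudobulk matrix with [estimatePopulation()].
#'
#' @section Parameters:
#' \describe{
#'   \item{peak.family}{family used when sampling population peak means.}
#'   \item{sample.ids, sample.shape, sample.scale}{per-individual peak-mean
#'     fits (shape eta_j, scale kappa_j).}
#'   \item{cv.bins}{data.frame with columns `lo`, `hi`, `alpha`, `beta`,
#'     `n`: gamma fits to within-bin coefficients of variation, bins of
#'     consecutive peaks ordered by mean accessibility.}
#'   \item{var.scale}{multiplier s on the sampled per-peak variability.}
#'   \item{ca.shape, ca.rate}{gamma parameters (alpha_c, beta_c) of caQTL
#'     effect-size magnitudes.}
#'   \item{ca.peaks}{fraction of peaks carrying a caQTL.}
#'   \item{ca.mafRange}{eligible SNP minor-allele-frequency range.}
#'   \item{ca.window}{maximum peak-midpoint-to-SNP distance in bp.}
#'   \item{ca.negProb}{probability a caQTL effect is negative.}
#'   \item{cond.daProb, cond.daLoc, cond.daScale, cond.daDownProb}{
#'     condition-level DA: fraction of peaks affected per non-reference
#'     cohort, log-normal factor location/scale, down-regulated fraction.}
#' }
#'
#' @name PicPopParams
#' @aliases PicPopParams-class
#' @exportClass PicPopParams
setClass("PicPopParams",
    slots = c(
        peak.family = "character",
        sample.ids = "character",
        sample.shape = "numeric",
        sample.scale = "numeric",
        cv.bins = "data.frame",
        var.scale = "numeric",
        ca.shape = "numeric",
        ca.rate = "numeric",
        ca.peaks = "numeric",
        ca.mafRange = "numeric",
        ca.window = "numeric",
        ca.negProb = "numeric",
        cond.daProb = "numeric",
        cond.daLoc = "numeric",
        cond.daScale = "numeric",
        cond.daDownProb = "numeric"),
    prototype = list(
        peak.family = "weibull",
        sample.ids = "sample1",
        sample.shape = 0.8,
        sample.scale = 0.3,
        cv.bins = data.frame(lo = 0, hi = Inf, alpha = 3, beta = 15,
                             n = NA_integer_),
        var.scale = 1,
        ca.shape = 1.5,
        ca.rate = 3,
        ca.peaks = 0.5,
        ca.mafRange = c(0.05, 0.5),
        ca.window = 1e5,
        ca.negProb = 0.5,
        cond.daProb = 0.1,
        cond.daLoc = 0.1,
        cond.daScale = 0.4,
        cond.daDownProb = 0.5))

setValidity("PicPopParams", function(object) {
    msg <- NULL
    if (!object@peak.family %in% .peakFamilies)
        msg <- c(msg, "unsupported peak.family")
    if (length(object@sample.shape) != length(object@sample.ids) ||
        length(object@sample.scale) != length(object@sample.ids))
        msg <- c(msg, "per-sample fits must match sample.ids in length")
    if (any(object@sample.shape <= 0) || any(object@sample.scale <= 0))
        msg <- c(msg, "per-sample shape/scale must be > 0")
    cb <- object@cv.bins
    if (!all(c("lo", "hi", "alpha", "beta") %in% names(cb)))
        msg <- c(msg, "cv.bins needs columns lo, hi, alpha, beta")
    else if (any(cb$lo >= cb$hi) || any(cb$alpha <= 0) || any(cb$beta <= 0))
        msg <- c(msg, "cv.bins must satisfy lo < hi, alpha > 0, beta > 0")
    if (object@var.scale < 0) msg <- c(msg, "var.scale must be >= 0")
    if (object@ca.shape <= 0 || object@ca.rate <= 0)
        msg <- c(msg, "ca.shape and ca.rate must be > 0")
    if (object@ca.peaks < 0 || object@ca.peaks > 1)
        msg <- c(msg, "ca.peaks must lie in [0, 1]")
    if (length(object@ca.mafRange) != 2 ||
        object@ca.mafRange[1] < 0 || object@ca.mafRange[2] > 0.5 ||
        object@ca.mafRange[1] > object@ca.mafRange[2])
        msg <- c(msg, "ca.mafRange must be an increasing pair within (0, 0.5]")
    if (object@ca.window <= 0) msg <- c(msg, "ca.window must be > 0")
    if (object@ca.negProb < 0 || object@ca.negProb > 1)
        msg <- c(msg, "ca.negProb must lie in [0, 1]")
    if (object@cond.daProb < 0 || object@cond.daProb > 1)
        msg <- c(msg, "cond.daProb must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' GenotypeTable: individuals-by-SNP dosage matrix
#'
#' Biallelic SNP dosages (0/1/2 copies of the alternate allele, `NA` for
#' missing) with SNP coordinates as a [GenomicRanges::GRanges] carrying
#' `id`, `ref`, `alt` and folded minor allele frequency `maf` in its
#' metadata columns. Rows of `dosages` are individuals.
#'
#' Build from a VCF with [readVcfGenotypes()] or synthesize under
#' Hardy-Weinberg equilibrium with [generateGenotypeFixture()].
#'
#' @name GenotypeTable
#' @aliases GenotypeTable-class
#' @exportClass GenotypeTable
setClass("GenotypeTable",
    slots = c(dosages = "matrix", snps = "GRanges"))

setValidity("GenotypeTable", function(object) {
    msg <- NULL
    if (ncol(object@dosages) != length(object@snps))
        msg <- c(msg, "ncol(dosages) must equal length(snps)")
    vals <- object@dosages[!is.na(object@dosages)]
    if (length(vals) && !all(vals %in% 0:2))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (!all(c("id", "maf") %in%
             names(S4Vectors::mcols(object@snps))))
        msg <- c(msg, "snps must carry 'id' and 'maf' metadata columns")
    else {
        maf <- S4Vectors::mcols(object@snps)$maf
        if (any(maf < 0 | maf > 0.5))
            msg <- c(msg, "maf must lie in [0, 0.5]")
    }
    if (is.null(msg)) TRUE else msg
})

.peakFamilies <- c("weibull", "gamma", "pareto", "lnorm", "lngamma")
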