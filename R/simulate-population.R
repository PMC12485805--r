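#' Sample per-individual baseline peak means
#'
#' Population-wide accessibility means `lambda_i` are drawn from the
#' configured family (per-individual fits pooled by averaging shape and
#' scale), each peak's coefficient of variation is drawn from the gamma fit
#' of the CV bin its mean falls into, giving `sigma_i = CV_i * lambda_i *
#' var.scale`, and per-individual baselines are `lambda_ij ~ N(lambda_i,
#' sigma_i)` clamped at 0. Supplying `empiricalMeans` (and optionally
#' `empiricalVars`) bypasses the sampling of `lambda_i` (and `sigma_i`)
#' and uses the empirical values directly.
#'
#' @param pop a [PicPopParams] object
#' @param nPeaks number of peaks
#' @param individuals character vector of individual IDs
#' @param empiricalMeans optional per-peak means used instead of sampling
#' @param empiricalVars optional per-peak variances used instead of the
#'   CV-bin draw
#' @return list with `means` (peak-by-individual matrix), `lambda`,
#'   `sigma`, `cv` and `nClamped` (negative draws clamped to 0)
#' @examples
#' pop <- newPicPopParams()
#' set.seed(1)
#' base <- samplePopulationBaselines(pop, 100, paste0("ind", 1:5))
#' dim(base$means)
#' @export
samplePopulationBaselines <- function(pop, nPeaks, individuals,
                                      empiricalMeans = NULL,
                                      empiricalVars = NULL) {
    methods::validObject(pop)
    s <- getParam(pop, "var.scale")
    if (is.null(empiricalMeans)) {
        lambda <- .sampleFamily(nPeaks, getParam(pop, "peak.family"),
                                mean(getParam(pop, "sample.shape")),
                                mean(getParam(pop, "sample.scale")))
    } else {
        if (length(empiricalMeans) != nPeaks)
            stop("empiricalMeans must have length nPeaks", call. = FALSE)
        lambda <- as.numeric(empiricalMeans)
    }
    bins <- getParam(pop, "cv.bins")
    if (is.null(empiricalVars)) {
        binIdx <- findInterval(lambda, c(bins$lo[1], bins$hi),
                               rightmost.closed = TRUE)
        binIdx <- pmin(pmax(binIdx, 1L), nrow(bins))
        cv <- stats::rgamma(nPeaks, shape = bins$alpha[binIdx],
                            rate = bins$beta[binIdx])
        sigma <- cv * lambda * s
    } else {
        if (length(empiricalVars) != nPeaks)
            stop("empiricalVars must have length nPeaks", call. = FALSE)
        sigma <- sqrt(as.numeric(empiricalVars)) * s
        cv <- ifelse(lambda > 0, sigma / lambda, 0)
    }
    nInd <- length(individuals)
    means <- matrix(stats::rnorm(nPeaks * nInd, mean = lambda, sd = sigma),
                    nPeaks, nInd,
                    dimnames = list(NULL, individuals))
    nClamped <- sum(means < 0)
    if (nClamped)
        means[means < 0] <- 0
    list(means = means, lambda = lambda, sigma = sigma, cv = cv,
         nClamped = nClamped)
}

#' Assign caQTL effects to peaks
#'
#' Selects `round(ca.peaks * nPeaks)` peaks uniformly among peaks that have
#' at least one eligible SNP (MAF within `ca.mafRange` and distance from
#' the peak midpoint at most `ca.window` bp), picks one eligible SNP per
#' peak uniformly, draws the effect-size magnitude `omega ~
#' Gamma(ca.shape, ca.rate)` and a negative sign with probability
#' `ca.negProb`.
#'
#' @param peaks `GRanges` of peak coordinates (1-based); midpoints are
#'   `floor((start + end) / 2)`
#' @param geno a [GenotypeTable]
#' @param pop a [PicPopParams] object
#' @return data.frame with columns `peak`, `peak_id`, `snp`, `snp_id`,
#'   `chrom`, `pos`, `effect`, `sign`, `distance` (one row per assignment)
#' @examples
#' geno <- generateGenotypeFixture(10, 200, chromLength = 1e6, seed = 1)
#' peaks <- generatePeakFixture(50, chromLength = 1e6, seed = 1)
#' pop <- newPicPopParams(ca.peaks = 0.5)
#' set.seed(1)
#' nrow(assignCaqtlEffects(peaks, geno, pop))  # 25
#' @export
assignCaqtlEffects <- function(peaks, geno, pop) {
    methods::validObject(pop)
    caPeaks <- getParam(pop, "ca.peaks")
    mafRange <- getParam(pop, "ca.mafRange")
    window <- getParam(pop, "ca.window")

    np <- length(peaks)
    nTarget <- round(caPeaks * np)
    empty <- data.frame(peak = integer(0), peak_id = character(0),
                        snp = integer(0), snp_id = character(0),
                        chrom = character(0), pos = integer(0),
                        effect = numeric(0), sign = integer(0),
                        distance = integer(0))
    if (nTarget == 0) return(empty)

    snps <- snpRanges(geno)
    maf <- S4Vectors::mcols(snps)$maf
    mafOK <- which(maf >= mafRange[1] & maf <= mafRange[2])
    mid <- floor((GenomicRanges::start(peaks) +
                  GenomicRanges::end(peaks)) / 2)
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(peaks),
        IRanges::IRanges(pmax(1, mid - window), mid + window))
    hits <- GenomicRanges::findOverlaps(win, snps[mafOK])
    elig <- split(mafOK[S4Vectors::subjectHits(hits)],
                  factor(S4Vectors::queryHits(hits), levels = seq_len(np)))
    nElig <- lengths(elig)
    eligible <- which(nElig > 0)
    if (length(eligible) == 0)
        stop("no peak has an eligible SNP (window = ", window,
             " bp, MAF range ", mafRange[1], "-", mafRange[2], ")",
             call. = FALSE)
    if (length(eligible) < nTarget) {
        warning(np - length(eligible), " peak(s) without eligible SNPs; ",
                "assigning caQTLs to all ", length(eligible),
                " eligible peaks instead of ", nTarget)
        chosen <- eligible
    } else {
        chosen <- sort(sample(eligible, nTarget))
    }

    snpIdx <- vapply(chosen, function(p) {
        cand <- elig[[p]]
        if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
    eff <- stats::rgamma(length(chosen), shape = getParam(pop, "ca.shape"),
                         rate = getParam(pop, "ca.rate"))
    sgn <- ifelse(stats::runif(length(chosen)) <
                  getParam(pop, "ca.negProb"), -1L, 1L)
    peakIds <- names(peaks) %||% paste0("peak", seq_len(np))
    snpIds <- S4Vectors::mcols(snps)$id
    data.frame(
        peak = chosen,
        peak_id = peakIds[chosen],
        snp = snpIdx,
        snp_id = snpIds[snpIdx],
        chrom = as.character(GenomicRanges::seqnames(snps)[snpIdx]),
        pos = GenomicRanges::start(snps)[snpIdx],
        effect = eff,
        sign = sgn,
        distance = abs(GenomicRanges::start(snps)[snpIdx] - mid[chosen]))
}

#' Apply genotype-driven effects to baselines
#'
#' For each caQTL assignment the baseline mean of the assigned peak in
#' individual `j` is multiplied by `1 + sign * omega * G_j / 2`, the
#' dosage-linear form with a half effect for heterozygotes. Individuals
#' with dosage 0 (or missing genotype) are unchanged; negative results are
#' clamped to 0 with a warning.
#'
#' @param baselines list from [samplePopulationBaselines()] (columns of
#'   `baselines$means` named by individual)
#' @param geno a [GenotypeTable]
#' @param assignments data.frame from [assignCaqtlEffects()]
#' @return the updated baselines list
#' @export
applyGenotypeEffects <- function(baselines, geno, assignments) {
    means <- baselines$means
    dos <- dosages(geno)
    ids <- colnames(means)
    if (!all(ids %in% rownames(dos)))
        stop("baseline individuals missing from genotype table",
             call. = FALSE)
    dos <- dos[ids, , drop = FALSE]
    nClamp <- 0
    for (k in seq_len(nrow(assignments))) {
        g <- dos[, assignments$snp[k]]
        g[is.na(g)] <- 0L
        fac <- 1 + assignments$sign[k] * assignments$effect[k] * g / 2
        neg <- fac < 0
        if (any(neg)) {
            nClamp <- nClamp + sum(neg)
            fac[neg] <- 0
        }
        means[assignments$peak[k], ] <-
            means[assignments$peak[k], ] * fac
    }
    if (nClamp)
        warning(nClamp, " genotype-effect factor(s) below 0 clamped to 0")
    baselines$means <- means
    baselines
}

#' Apply condition-level differential accessibility
#'
#' For each cohort beyond the reference (the first condition level), a
#' `cond.daProb` fraction of peaks receives a log-normal factor
#' `exp(N(cond.daLoc, cond.daScale))`, inverted for a `cond.daDownProb`
#' fraction, applied multiplicatively to the baselines of all individuals
#' in that cohort.
#'
#' @param baselines list from [samplePopulationBaselines()]
#' @param conditions character/factor of cohort labels named by individual
#'   (or ordered as the baseline columns)
#' @param pop a [PicPopParams] object
#' @return list with the updated `baselines` and a `truth` data.frame
#'   (`peak`, `condition`, `factor`)
#' @export
applyConditionDA <- function(baselines, conditions, pop) {
    means <- baselines$means
    ids <- colnames(means)
    if (!is.null(names(conditions))) conditions <- conditions[ids]
    if (length(conditions) != ncol(means))
        stop("conditions must cover all individuals", call. = FALSE)
    conditions <- as.character(conditions)
    levs <- unique(conditions)
    truth <- data.frame(peak = integer(0), condition = character(0),
                        factor = numeric(0))
    np <- nrow(means)
    for (cond in levs[-1]) {
        isDA <- which(stats::runif(np) < getParam(pop, "cond.daProb"))
        if (!length(isDA)) next
        f <- exp(stats::rnorm(length(isDA), getParam(pop, "cond.daLoc"),
                              getParam(pop, "cond.daScale")))
        down <- stats::runif(length(isDA)) <
            getParam(pop, "cond.daDownProb")
        f[down] <- 1 / f[down]
        cols <- which(conditions == cond)
        means[isDA, cols] <- means[isDA, cols, drop = FALSE] * f
        truth <- rbind(truth, data.frame(peak = isDA, condition = cond,
                                         factor = f))
    }
    baselines$means <- means
    list(baselines = baselines, truth = truth)
}

#' Simulate a population-scale cohort with genetic effects
#'
#' Composes the population pipeline: per-individual baselines
#' ([samplePopulationBaselines()]), genotype-driven caQTL effects
#' ([assignCaqtlEffects()] + [applyGenotypeEffects()]), condition-level DA
#' ([applyConditionDA()]), then per-individual single-cell simulation with
#' that individual's baselines as peak means (group DA factors shared
#' across individuals, batches assigned round-robin at the individual
#' level). The full ground truth is emitted in the metadata.
#'
#' @param params a [PicParams] object (library size, sparsity, BCV,
#'   group/batch settings; `nPeaks` is overridden by `length(peaks)` when
#'   peaks are supplied)
#' @param pop a [PicPopParams] object
#' @param geno optional [GenotypeTable]; required for caQTL effects
#' @param peaks optional `GRanges` of peak coordinates; required for caQTL
#'   effects
#' @param cellsPerIndividual cells simulated per individual (scalar or one
#'   value per individual)
#' @param individuals individual IDs; defaults to the genotype table's
#' @param conditions optional cohort labels named by individual
#' @param empiricalMeans,empiricalVars optional empirical bypass passed to
#'   [samplePopulationBaselines()]
#' @return a `SingleCellExperiment`; `colData` has `Individual`, `Group`,
#'   `Batch`, `Condition`, `LibSize`; `metadata` has `Params`,
#'   `PopParams`, `Baselines` (peak-by-individual expected means after all
#'   effects) and `Truth` (list: `caqtl`, `conditionDA`, `DAFactors`)
#' @examples
#' geno <- generateGenotypeFixture(6, 300, chromLength = 1e6, seed = 2)
#' peaks <- generatePeakFixture(80, chromLength = 1e6, seed = 2)
#' sim <- simulatePopulation(newPicParams(seed = 2), newPicPopParams(),
#'                           geno, peaks, cellsPerIndividual = 20)
#' table(sim$Individual)
#' @export
simulatePopulation <- function(params, pop, geno = NULL, peaks = NULL,
                               cellsPerIndividual = 100,
                               individuals = NULL, conditions = NULL,
                               empiricalMeans = NULL,
                               empiricalVars = NULL) {
    methods::validObject(params)
    methods::validObject(pop)
    seed <- getParam(params, "seed")
    if (is.null(individuals)) {
        if (is.null(geno))
            stop("supply either 'individuals' or a genotype table",
                 call. = FALSE)
        individuals <- individualIds(geno)
    }
    nInd <- length(individuals)
    np <- if (!is.null(peaks)) length(peaks)
          else getParam(params, "nPeaks")
    nCellsInd <- rep_len(cellsPerIndividual, nInd)

    base <- .withStream(seed, "popbase",
        samplePopulationBaselines(pop, np, individuals,
                                  empiricalMeans, empiricalVars))

    caqtl <- NULL
    if (!is.null(geno) && !is.null(peaks) &&
        getParam(pop, "ca.peaks") > 0) {
        caqtl <- .withStream(seed, "caqtl",
            assignCaqtlEffects(peaks, geno, pop))
        base <- applyGenotypeEffects(base, geno, caqtl)
    }
    condTruth <- NULL
    if (!is.null(conditions)) {
        res <- .withStream(seed, "condda",
            applyConditionDA(base, conditions, pop))
        base <- res$baselines
        condTruth <- res$truth
        if (!is.null(names(conditions)))
            conditions <- conditions[individuals]
    }

    nG <- getParam(params, "nGroups")
    da <- if (nG > 1) {
        .withStream(seed, "da",
            sampleDAFactors(np, nG, getParam(params, "da.prob"),
                            getParam(params, "da.loc"),
                            getParam(params, "da.scale"),
                            getParam(params, "da.downProb")))
    } else matrix(1, np, 1)
    nB <- getParam(params, "nBatches")
    batchOfInd <- ((seq_len(nInd) - 1L) %% nB) + 1L

    countList <- vector("list", nInd)
    cdList <- vector("list", nInd)
    for (j in seq_len(nInd)) {
        ncj <- nCellsInd[j]
        lam <- base$means[, j]
        if (all(lam <= 0))
            stop("individual ", individuals[j],
                 " has no positive baseline means", call. = FALSE)
        grp <- .withStream(seed, paste0("groups:", j),
            assignGroups(ncj, getParam(params, "group.probs")))
        wb <- if (nB > 1) {
            .withStream(seed, paste0("batch:", j),
                sampleBatchFactors(rep(batchOfInd[j], ncj),
                                   getParam(params, "batch.mu"),
                                   getParam(params, "batch.sigma")))
        } else rep(1, ncj)
        relMeans <- da[, grp, drop = FALSE] * lam
        res <- .simulateCells(relMeans, params, seed,
                              paste0("cells:", j), cellFactors = wb)
        countList[[j]] <- res$counts
        cdList[[j]] <- S4Vectors::DataFrame(
            Individual = rep(individuals[j], ncj),
            Group = paste0("Group", grp),
            Batch = paste0("Batch", batchOfInd[j]),
            Condition = if (is.null(conditions)) rep(NA_character_, ncj)
                        else rep(as.character(conditions[j]), ncj),
            LibSize = res$libSize,
            TargetSparsity = res$pi)
    }
    counts <- do.call(cbind, countList)
    colData <- do.call(rbind, cdList)
    colData$Individual <- factor(colData$Individual,
                                 levels = individuals)
    colData$Group <- factor(colData$Group)
    colData$Batch <- factor(colData$Batch)

    rn <- if (!is.null(peaks) && !is.null(names(peaks))) names(peaks)
          else paste0("peak", seq_len(np))
    rownames(counts) <- rn
    .makeSCE(counts,
        rowData = S4Vectors::DataFrame(Lambda = base$lambda,
                                       Sigma = base$sigma,
                                       row.names = rn),
        colData = colData,
        metadata = list(Params = params, PopParams = pop,
                        Baselines = base$means,
                        Truth = list(caqtl = caqtl,
                                     conditionDA = condTruth,
                                     DAFactors = da)))
}

#' Aggregate single cells into pseudobulk profiles
#'
#' Per-peak mean across each individual's cells, after (optionally)
#' scaling each cell to the dataset's median total count. With
#' `quantileNormalize = TRUE` each peak's values across individuals are
#' rank-transformed to a standard normal (mean 0, sd 1; constant rows stay
#' 0), the mapper-ready phenotype form for caQTL scans.
#'
#' @param sce a `SingleCellExperiment` whose `colData` carries the
#'   grouping column
#' @param by name of the `colData` column to aggregate by (default
#'   `"Individual"`)
#' @param normalize scale cells to the median total count first?
#' @param quantileNormalize rank-normalize each peak across individuals?
#' @return peak-by-individual numeric matrix
#' @examples
#' geno <- generateGenotypeFixture(5, 100, chromLength = 1e6, seed = 4)
#' sim <- simulatePopulation(newPicParams(nPeaks = 50, seed = 4),
#'                           newPicPopParams(ca.peaks = 0), geno,
#'                           cellsPerIndividual = 10)
#' pb <- aggregatePseudobulk(sim)
#' dim(pb)
#' @export
aggregatePseudobulk <- function(sce, by = "Individual", normalize = TRUE,
                                quantileNormalize = FALSE) {
    m <- .getCounts(sce)
    labels <- SummarizedExperiment::colData(sce)[[by]]
    if (is.null(labels))
        stop("colData column '", by, "' not found", call. = FALSE)
    if (normalize) m <- .normalizeToMedianTotal(m)
    labels <- factor(labels)
    pb <- vapply(levels(labels), function(l) {
        Matrix::rowMeans(m[, labels == l, drop = FALSE])
    }, numeric(nrow(m)))
    if (quantileNormalize)
        pb <- t(apply(pb, 1, .rankNormal))
    pb
}

# rank-based transform to a standard normal; exactly mean 0 / sd 1
# (constant rows return all zeros)
.rankNormal <- function(x) {
    r <- rank(x, ties.method = "average")
    z <- stats::qnorm((r - 0.5) / length(x))
    z <- z - mean(z)
    s <- stats::sd(z)
    if (s == 0) return(rep(0, length(x)))
    z / s
}
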