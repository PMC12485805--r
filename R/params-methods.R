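#' Create a new PicParams object
#'
#' @param ... `name = value` pairs overriding the defaults (see
#'   [PicParams] for the parameter list).
#' @return a validated [PicParams] object
#' @examples
#' params <- newPicParams(nPeaks = 1000, nCells = 200, seed = 7)
#' params
#' @export
newPicParams <- function(...) {
    setParams(new("PicParams"), ...)
}

#' Create a new PicPopParams object
#'
#' @param ... `name = value` pairs overriding the defaults (see
#'   [PicPopParams]).
#' @return a validated [PicPopParams] object
#' @examples
#' pop <- newPicPopParams(ca.peaks = 0.7, ca.window = 5e4)
#' @export
newPicPopParams <- function(...) {
    setParams(new("PicPopParams"), ...)
}

# slots that must stay integer even when users pass doubles
.integerSlots <- c("nPeaks", "nCells", "seed", "nGroups", "nBatches",
                   "batchCells")

.assignSlot <- function(object, name, value) {
    if (!name %in% methods::slotNames(object))
        stop("unknown parameter '", name, "' for class ",
             class(object), call. = FALSE)
    if (name %in% .integerSlots) {
        if (any(value != round(value)))
            stop("parameter '", name, "' must be a whole number",
                 call. = FALSE)
        value <- as.integer(value)
    }
    methods::slot(object, name) <- value
    object
}

.setParamImpl <- function(object, name, value) {
    object <- .assignSlot(object, name, value)
    methods::validObject(object)
    object
}

#' @rdname getParam
setMethod("getParam", "PicParams", function(object, name) {
    if (!name %in% methods::slotNames(object))
        stop("unknown parameter '", name, "'", call. = FALSE)
    methods::slot(object, name)
})

#' @rdname getParam
setMethod("getParam", "PicPopParams", function(object, name) {
    if (!name %in% methods::slotNames(object))
        stop("unknown parameter '", name, "'", call. = FALSE)
    methods::slot(object, name)
})

#' @rdname setParam
setMethod("setParam", "PicParams", .setParamImpl)

#' @rdname setParam
setMethod("setParam", "PicPopParams", .setParamImpl)

.setParamsImpl <- function(object, ...) {
    args <- list(...)
    if (length(args) == 0) {
        methods::validObject(object)
        return(object)
    }
    if (is.null(names(args)) || any(names(args) == ""))
        stop("all parameters must be named", call. = FALSE)
    # assign everything first, validate once: interdependent slots
    # (e.g. nGroups and group.probs) can then be updated together
    for (nm in names(args))
        object <- .assignSlot(object, nm, args[[nm]])
    methods::validObject(object)
    object
}

#' @rdname setParams
setMethod("setParams", "PicParams", .setParamsImpl)

#' @rdname setParams
setMethod("setParams", "PicPopParams", .setParamsImpl)

setMethod("show", "PicParams", function(object) {
    cat("PicParams object (single-sample simulation parameters)\n")
    cat("  matrix:   ", object@nPeaks, "peaks x", object@nCells,
        "cells, seed", object@seed, "\n")
    cat("  library:  lnN(mu =", format(object@lib.mu, digits = 4),
        ", sigma =", format(object@lib.sigma, digits = 4), ")\n")
    cat("  peaks:    ", object@peak.family,
        "(shape =", format(object@peak.shape, digits = 4),
        ", scale =", format(object@peak.scale, digits = 4), ")\n")
    cat("  sparsity:  mean pi =",
        format(mean(object@sparsity), digits = 4),
        paste0("(", length(object@sparsity), " value",
               if (length(object@sparsity) > 1) "s", ")"), "\n")
    cat("  BCV:       phi =", format(object@bcv.phi, digits = 4),
        ", df0 =", format(object@bcv.df0, digits = 4), "\n")
    cat("  groups:   ", object@nGroups,
        "( probs:", paste(format(object@group.probs, digits = 3),
                          collapse = ", "), ")\n")
    cat("  DA:        prob =", object@da.prob, ", LN(",
        object@da.loc, ",", object@da.scale, "), down =",
        object@da.downProb, "\n")
    cat("  batches:  ", object@nBatches, "\n")
})

setMethod("show", "PicPopParams", function(object) {
    cat("PicPopParams object (population-level parameters)\n")
    cat("  samples:  ", length(object@sample.ids), "individual fits (",
        object@peak.family, ")\n")
    cat("  CV bins:  ", nrow(object@cv.bins),
        "gamma fits; var.scale =", object@var.scale, "\n")
    cat("  caQTL:     Gamma(", format(object@ca.shape, digits = 4), ",",
        format(object@ca.rate, digits = 4), "), caPeaks =",
        object@ca.peaks, ", MAF", paste(object@ca.mafRange,
        collapse = "-"), ", window", object@ca.window, "bp\n")
    cat("  cond. DA:  prob =", object@cond.daProb, ", LN(",
        object@cond.daLoc, ",", object@cond.daScale, ")\n")
})

#' @rdname GenotypeTable
#' @param dosages individuals x SNPs integer matrix with values 0/1/2/NA
#' @param snps `GRanges` with mcols `id`, `ref`, `alt`, `maf`
#' @return `GenotypeTable()` returns a validated object.
#' @export
GenotypeTable <- function(dosages, snps) {
    storage.mode(dosages) <- "integer"
    methods::new("GenotypeTable", dosages = dosages, snps = snps)
}

#' @rdname GenotypeTable
setMethod("dosages", "GenotypeTable", function(object) object@dosages)

#' @rdname GenotypeTable
setMethod("snpRanges", "GenotypeTable", function(object) object@snps)

#' @rdname GenotypeTable
setMethod("individualIds", "GenotypeTable",
          function(object) rownames(object@dosages))

setMethod("show", "GenotypeTable", function(object) {
    cat("GenotypeTable:", nrow(object@dosages), "individuals x",
        ncol(object@dosages), "SNPs\n")
    maf <- S4Vectors::mcols(object@snps)$maf
    if (length(maf))
        cat("  MAF range:", format(min(maf), digits = 3), "-",
            format(max(maf), digits = 3), "\n")
    miss <- mean(is.na(object@dosages))
    cat("  missingness:", format(miss, digits = 3), "\n")
})
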