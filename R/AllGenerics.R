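#' Get a parameter value
#'
#' @param object a [PicParams] or [PicPopParams] object
#' @param name parameter name (slot name)
#' @return the parameter value
#' @examples
#' getParam(newPicParams(), "lib.mu")
#' @export
setGeneric("getParam", function(object, name) standardGeneric("getParam"))

#' Set a parameter value
#'
#' Returns a modified copy; the object is validated after the update.
#'
#' @param object a [PicParams] or [PicPopParams] object
#' @param name parameter name (slot name)
#' @param value new value
#' @return the updated object
#' @examples
#' params <- setParam(newPicParams(), "nCells", 100)
#' @export
setGeneric("setParam",
           function(object, name, value) standardGeneric("setParam"))

#' Set several parameters at once
#'
#' @param object a [PicParams] or [PicPopParams] object
#' @param ... `name = value` pairs
#' @return the updated object
#' @examples
#' params <- setParams(newPicParams(), nPeaks = 200, nCells = 50)
#' @export
setGeneric("setParams", function(object, ...) standardGeneric("setParams"))

#' @describeIn GenotypeTable dosage matrix (individuals x SNPs)
#' @param object a `GenotypeTable`
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @describeIn GenotypeTable SNP coordinates and annotation (`GRanges`)
#' @export
setGeneric("snpRanges", function(object) standardGeneric("snpRanges"))

#' @describeIn GenotypeTable individual identifiers
#' @export
setGeneric("individualIds",
           function(object) standardGeneric("individualIds"))
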