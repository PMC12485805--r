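#' Serialize parameters to JSON
#'
#' Writes a [PicParams] or [PicPopParams] object as a human-readable JSON
#' key-value file (with a `schema_version` field) that round-trips
#' losslessly through [readParams()].
#'
#' @param object a [PicParams] or [PicPopParams] object
#' @param path output file
#' @return `path`, invisibly
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeParams(newPicParams(), f)
#' identical(readParams(f), newPicParams())
#' @export
writeParams <- function(object, path) {
    if (!class(object) %in% c("PicParams", "PicPopParams"))
        stop("can only serialize PicParams or PicPopParams",
             call. = FALSE)
    sl <- methods::slotNames(object)
    params <- stats::setNames(
        lapply(sl, function(s) methods::slot(object, s)), sl)
    jsonlite::write_json(
        list(schema_version = 1L, class = class(object)[1],
             params = params),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
        dataframe = "columns")
    invisible(path)
}

#' Read parameters from JSON
#'
#' @param path file written by [writeParams()]
#' @return the reconstructed [PicParams] or [PicPopParams] object
#' @export
readParams <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$class) ||
        !obj$class %in% c("PicParams", "PicPopParams"))
        stop("not a picsim parameter file: ", path, call. = FALSE)
    out <- methods::new(obj$class)
    p <- obj$params
    for (nm in names(p)) {
        val <- p[[nm]]
        proto <- methods::slot(out, nm)
        if (is.data.frame(proto)) {
            # numeric columns may carry "Inf" strings (JSON has no Inf)
            val <- as.data.frame(lapply(val, function(col)
                as.numeric(unlist(col))), stringsAsFactors = FALSE)
        } else if (is.list(proto)) {
            if (length(val) == 0) val <- list()
        } else {
            val <- unlist(val)
            if (is.null(val)) val <- vector(class(proto), 0)
            storage.mode(val) <- storage.mode(proto)
        }
        methods::slot(out, nm) <- val
    }
    methods::validObject(out)
    out
}
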