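#' Summarize a count matrix
#'
#' Computes the cell-level and peak-level summary statistics used for
#' real-versus-simulated comparisons: per cell the library size (raw and
#' natural-log) and sparsity; per peak the mean, variance, zero proportion
#' and nonzero proportion (raw counts throughout).
#'
#' @inheritParams filterPeaks
#' @return list with data.frames `cells` (`libSize`, `logLibSize`,
#'   `sparsity`) and `peaks` (`mean`, `var`, `zeroProp`, `nonzeroProp`)
#' @examples
#' summarizeDataset(matrix(c(0, 4, 2, 0), 2))
#' @export
summarizeDataset <- function(counts) {
    m <- .getCounts(counts)
    lib <- Matrix::colSums(m)
    dense <- as.matrix(m)
    pkMean <- rowMeans(dense)
    pkVar <- apply(dense, 1, stats::var)
    zp <- rowMeans(dense == 0)
    list(
        cells = data.frame(
            libSize = as.numeric(lib),
            logLibSize = ifelse(lib > 0, log(as.numeric(lib)), NA),
            sparsity = as.numeric(.colZeroFraction(m))),
        peaks = data.frame(
            mean = pkMean, var = pkVar,
            zeroProp = zp, nonzeroProp = 1 - zp))
}

#' Compare two distributions with sorted-difference metrics
#'
#' Both vectors are sorted ascending; when lengths differ the longer one is
#' reduced to the shorter length by linear quantile interpolation. With
#' `d = |sorted real - sorted sim|` the metrics are `MAD = median(d)`,
#' `MAE = mean(d)`, `RMSE = sqrt(mean(d^2))` and `oneMinusPCC = 1 -
#' Pearson(sorted real, sorted sim)` (reported as `NA` with a warning when
#' either sorted vector has zero variance).
#'
#' @param real,sim nonempty numeric vectors
#' @return named numeric vector `c(MAD, MAE, RMSE, oneMinusPCC)`
#' @examples
#' compareDistributions(c(1, 2, 3), c(1, 2, 4))
#' @export
compareDistributions <- function(real, sim) {
    real <- sort(real)
    sim <- sort(sim)
    if (length(real) == 0 || length(sim) == 0)
        stop("both vectors must be nonempty", call. = FALSE)
    n <- min(length(real), length(sim))
    qreduce <- function(x) {
        if (length(x) == n) return(x)
        stats::approx(seq(0, 1, length.out = length(x)), x,
                      xout = seq(0, 1, length.out = n))$y
    }
    real <- qreduce(real)
    sim <- qreduce(sim)
    d <- abs(real - sim)
    pcc <- if (n < 2 || stats::sd(real) == 0 || stats::sd(sim) == 0) {
        warning("zero-variance vector: 1-PCC undefined")
        NA_real_
    } else 1 - stats::cor(real, sim)
    c(MAD = stats::median(d), MAE = mean(d), RMSE = sqrt(mean(d^2)),
      oneMinusPCC = pcc)
}

#' Compare a real and a simulated dataset
#'
#' Computes the metric quadruple of [compareDistributions()] for the three
#' core characteristics — library size (natural-log scale by default),
#' peak mean and cell sparsity — and optionally writes the metric table
#' (TSV) plus diagnostic overlay/relationship plots to a directory.
#'
#' @param real,sim count matrices or `SingleCellExperiment`s
#' @param dir optional output directory for `metrics.tsv` and PNG plots
#' @param logLibSize compare library sizes on the natural-log scale?
#' @return list with `metrics` (data.frame, one row per characteristic)
#'   and `plots` (named list of ggplot objects)
#' @examples
#' a <- simulateSingle(newPicParams(nPeaks = 200, nCells = 50, seed = 1))
#' b <- simulateSingle(newPicParams(nPeaks = 200, nCells = 50, seed = 2))
#' compareReport(a, b)$metrics
#' @export
compareReport <- function(real, sim, dir = NULL, logLibSize = TRUE) {
    sr <- summarizeDataset(real)
    ss <- summarizeDataset(sim)
    libReal <- if (logLibSize) sr$cells$logLibSize else sr$cells$libSize
    libSim <- if (logLibSize) ss$cells$logLibSize else ss$cells$libSize
    pairs <- list(
        library_size = list(stats::na.omit(libReal),
                            stats::na.omit(libSim)),
        peak_mean = list(sr$peaks$mean[sr$peaks$mean > 0],
                         ss$peaks$mean[ss$peaks$mean > 0]),
        cell_sparsity = list(sr$cells$sparsity, ss$cells$sparsity))
    metrics <- do.call(rbind, lapply(names(pairs), function(nm) {
        v <- compareDistributions(pairs[[nm]][[1]], pairs[[nm]][[2]])
        data.frame(characteristic = nm, MAD = v["MAD"], MAE = v["MAE"],
                   RMSE = v["RMSE"], oneMinusPCC = v["oneMinusPCC"],
                   row.names = NULL)
    }))

    ov <- data.frame(
        value = c(libReal, libSim, sr$cells$sparsity, ss$cells$sparsity),
        dataset = c(rep(c("real", "sim"),
                        c(length(libReal), length(libSim))),
                    rep(c("real", "sim"),
                        c(nrow(sr$cells), nrow(ss$cells)))),
        characteristic = rep(c("library size", "cell sparsity"),
                             c(length(libReal) + length(libSim),
                               nrow(sr$cells) + nrow(ss$cells))))
    rel <- rbind(
        data.frame(mean = sr$peaks$mean, zeroProp = sr$peaks$zeroProp,
                   dataset = "real"),
        data.frame(mean = ss$peaks$mean, zeroProp = ss$peaks$zeroProp,
                   dataset = "sim"))
    rel <- rel[rel$mean > 0, ]   # log-scale axis

    plots <- list(
        distributions = ggplot2::ggplot(ov,
                ggplot2::aes(x = value, fill = dataset)) +
            ggplot2::geom_density(alpha = 0.4) +
            ggplot2::facet_wrap(~characteristic, scales = "free") +
            ggplot2::theme_minimal(),
        mean_vs_zeros = ggplot2::ggplot(rel,
                ggplot2::aes(x = mean, y = zeroProp,
                             colour = dataset)) +
            ggplot2::geom_point(alpha = 0.3, size = 0.6) +
            ggplot2::scale_x_log10() +
            ggplot2::labs(x = "peak mean (log scale)",
                          y = "proportion of zeros") +
            ggplot2::theme_minimal())

    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        utils::write.table(metrics, file.path(dir, "metrics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        for (nm in names(plots))
            suppressMessages(ggplot2::ggsave(
                file.path(dir, paste0(nm, ".png")), plots[[nm]],
                width = 7, height = 4, dpi = 120))
    }
    list(metrics = metrics, plots = plots)
}
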