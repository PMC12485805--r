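#' Read genotype dosages from a VCF
#'
#' Parses biallelic SNP records from a VCF (v4.x) using the GT field;
#' phased (`|`) and unphased (`/`) separators are equivalent. Dosage is
#' the alternate-allele count (0/1/2). Per-SNP minor allele frequency is
#' computed from the dosages and folded to at most 0.5. Records are
#' dropped — with counts reported via `message()` — when multiallelic,
#' when genotype missingness exceeds `maxMissing`, or when the MAF falls
#' outside `mafRange`.
#'
#' @param path VCF file (plain text or gzipped)
#' @param mafRange keep SNPs with folded MAF inside this closed interval
#' @param maxMissing drop sites with a missing-genotype fraction above
#'   this (default 0.1)
#' @return a [GenotypeTable]
#' @examples
#' geno <- generateGenotypeFixture(5, 20, chromLength = 1e5, seed = 1,
#'                                 file = tempfile(fileext = ".vcf"))
#' @export
readVcfGenotypes <- function(path, mafRange = c(0, 0.5),
                             maxMissing = 0.1) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    if (ncol(vcf@gt) < 2)
        stop("VCF has no sample columns", call. = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                          dimnames = list(NULL, names(fix)))
    bi <- vcfR::is.biallelic(vcf)
    snp <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
        nchar(fix[, "ALT"]) == 1
    keep <- bi & snp
    if (sum(!keep))
        message(sum(!keep), " non-biallelic-SNP record(s) dropped")
    if (!any(keep)) stop("no biallelic SNP records in ", path,
                         call. = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]

    gt <- gsub("|", "/", gt, fixed = TRUE)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
    dos[gt == "0/0"] <- 0L
    dos[gt %in% c("0/1", "1/0")] <- 1L
    dos[gt == "1/1"] <- 2L
    malformed <- !is.na(gt) & is.na(dos) & gt != "./."
    if (any(malformed))
        message(sum(malformed), " malformed GT value(s) set to missing")

    missFrac <- rowMeans(is.na(dos))
    highMiss <- missFrac > maxMissing
    if (any(highMiss))
        message(sum(highMiss), " site(s) dropped for missingness > ",
                maxMissing)
    dos <- dos[!highMiss, , drop = FALSE]
    fix <- fix[!highMiss, , drop = FALSE]
    if (nrow(dos) == 0) stop("no sites left after missingness filter",
                             call. = FALSE)

    p <- rowMeans(dos, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    inRange <- maf >= mafRange[1] & maf <= mafRange[2]
    if (any(!inRange))
        message(sum(!inRange), " site(s) dropped outside MAF range [",
                mafRange[1], ", ", mafRange[2], "]")
    dos <- dos[inRange, , drop = FALSE]
    fix <- fix[inRange, , drop = FALSE]
    maf <- maf[inRange]
    if (nrow(dos) == 0) stop("no sites left after MAF filter",
                             call. = FALSE)

    ids <- fix[, "ID"]
    noId <- is.na(ids) | ids == "."
    ids[noId] <- paste0(fix[noId, "CHROM"], "_", fix[noId, "POS"])
    snps <- GenomicRanges::GRanges(
        fix[, "CHROM"],
        IRanges::IRanges(as.integer(fix[, "POS"]), width = 1),
        id = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
        maf = unname(maf))
    GenotypeTable(dosages = t(dos), snps = snps)
}

# plain-text VCF v4.2 writer for GenotypeTable objects (fixtures and
# mapper-ready export); dosage 0/1/2/NA -> GT 0/0, 0/1, 1/1, ./.
.writeVcf <- function(geno, file, contigLength = NULL) {
    dos <- dosages(geno)
    snps <- snpRanges(geno)
    mc <- S4Vectors::mcols(snps)
    chroms <- unique(as.character(GenomicRanges::seqnames(snps)))
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##source=picsim"),
             vapply(chroms, function(ch) {
                 len <- contigLength %||%
                     max(GenomicRanges::end(snps)[
                         as.character(
                             GenomicRanges::seqnames(snps)) == ch])
                 sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len))
             }, character(1)),
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", rownames(dos)),
                   collapse = "\t"))
    gtCode <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_along(snps), function(i) {
        g <- dos[, i]
        gt <- ifelse(is.na(g), "./.", gtCode[g + 1L])
        paste(c(as.character(GenomicRanges::seqnames(snps)[i]),
                GenomicRanges::start(snps)[i], mc$id[i],
                mc$ref[i] %||% "A", mc$alt[i] %||% "C",
                ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), file)
    invisible(file)
}

#' Export a mapper-ready phenotype file
#'
#' Writes a quantile-normalized peak-by-individual pseudobulk matrix as a
#' TSV (peaks in rows, individuals in columns) — the phenotype input of a
#' linear-mixed-model caQTL scan.
#'
#' @param pseudobulk peak-by-individual matrix (see
#'   [aggregatePseudobulk()])
#' @param file output TSV path
#' @return `file`, invisibly
#' @export
writePhenotypes <- function(pseudobulk, file) {
    df <- data.frame(peak_id = rownames(pseudobulk) %||%
                         paste0("peak", seq_len(nrow(pseudobulk))),
                     as.data.frame(pseudobulk), check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
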