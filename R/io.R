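## VCF and table input/output. Reading goes through VariantAnnotation;
## writing formats the data model directly (plain-text VCF 4.2). The
## round trip write -> read is lossless for every field in the model:
## coordinates, alleles, QUAL, the INFO quality annotations and dosages.

.gtCodes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write genotypes and site annotations as VCF
#'
#' Emits a multi-sample VCF 4.2 with INFO fields `DP`, `DP4`, `MQ`, `AC`,
#' `AN` (when present in the site annotations; `AC`/`AN` are computed
#' from the dosages when absent) and a per-sample `GT` field. Missing
#' genotypes become `./.`; positions are 1-based.
#'
#' @param x a [GenotypeExperiment-class].
#' @param path output path (plain text).
#' @return Invisibly, `path`.
#' @export
writeGenotypeVcf <- function(x, path) {
    stopifnot(is(x, "GenotypeExperiment"))
    si <- siteInfo(x)
    d <- dosageMatrix(x)
    ref <- if ("ref" %in% colnames(si)) si$ref else rep("A", nrow(si))
    alt <- if ("alt" %in% colnames(si)) si$alt else rep("C", nrow(si))
    qual <- if ("QUAL" %in% colnames(si)) sprintf("%.6g", si$QUAL)
            else rep(".", nrow(si))
    ac <- if ("AC" %in% colnames(si)) si$AC
          else as.integer(rowSums(d, na.rm = TRUE))
    an <- if ("AN" %in% colnames(si)) si$AN
          else 2L * rowSums(!is.na(d))
    info <- sprintf("AC=%d;AN=%d", ac, an)
    if ("DP" %in% colnames(si))
        info <- sprintf("%s;DP=%d", info, si$DP)
    if (all(c("DP4_RF", "DP4_RR", "DP4_AF", "DP4_AR") %in% colnames(si)))
        info <- sprintf("%s;DP4=%d,%d,%d,%d", info, si$DP4_RF, si$DP4_RR,
                        si$DP4_AF, si$DP4_AR)
    if ("MQ" %in% colnames(si))
        info <- sprintf("%s;MQ=%.6g", info, si$MQ)
    gt <- matrix(.gtCodes[as.character(d)], nrow(d))
    gt[is.na(d)] <- "./."
    scafLen <- tapply(si$pos, si$scaffold, max)
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=snpkin",
        sprintf("##contig=<ID=%s,length=%d>", names(scafLen),
                as.integer(scafLen)),
        "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
        "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
        "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref-fwd, ref-rev, alt-fwd, alt-rev read counts\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- paste(si$scaffold, si$pos, si$site, ref, alt, qual, ".",
                  info, "GT", apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a VCF into a GenotypeExperiment
#'
#' Parses a VCF 4.x (via `VariantAnnotation`) into the package's data
#' model. `GT` fields are recoded as alternate-allele dosages; any call
#' involving a missing allele, or an allele beyond the first alternate
#' (multi-allelic genotypes), becomes `NA`. Multi-allelic records are
#' kept with `nAlleles` set accordingly so the tri-allelic candidate
#' filter can see them.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A [GenotypeExperiment-class]; INFO fields `DP`, `DP4`, `MQ`,
#'   `AC`, `AN` populate the site annotations when present.
#' @export
readGenotypeVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altList <- VariantAnnotation::alt(vcf)
    alt <- vapply(altList, function(a) paste(as.character(a), collapse = ","),
                  "")
    nAlt <- lengths(altList)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field: ", path)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean %in% c("0/0")] <- 0L
    dos[clean %in% c("0/1", "1/0")] <- 1L
    dos[clean %in% c("1/1")] <- 2L
    info <- VariantAnnotation::info(vcf)
    siteData <- DataFrame(row.names = rownames(gt))
    siteData$nAlleles <- as.integer(nAlt + 1L)
    qv <- rr$QUAL
    if (!all(is.na(qv))) siteData$QUAL <- qv
    pick1 <- function(v) vapply(v, function(e)
        if (length(e)) as.numeric(e[[1L]]) else NA_real_, 0)
    if ("DP" %in% colnames(info)) siteData$DP <- as.integer(info$DP)
    if ("MQ" %in% colnames(info)) siteData$MQ <- as.numeric(info$MQ)
    if ("AN" %in% colnames(info)) siteData$AN <- as.integer(info$AN)
    if ("AC" %in% colnames(info)) siteData$AC <- as.integer(pick1(info$AC))
    if ("DP4" %in% colnames(info)) {
        dp4 <- do.call(rbind, lapply(info$DP4, function(v)
            unname(as.integer(v))[1:4]))
        dimnames(dp4) <- NULL
        siteData$DP4_RF <- dp4[, 1]; siteData$DP4_RR <- dp4[, 2]
        siteData$DP4_AF <- dp4[, 3]; siteData$DP4_AR <- dp4[, 4]
    }
    siteData$isIndel <- nchar(ref) != 1L |
        vapply(altList, function(a) any(nchar(as.character(a)) != 1L), TRUE)
    makeGenotypeExperiment(dos,
        scaffold = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr), ref = ref, alt = alt,
        siteData = siteData)
}

#' Read / write a three-column pedigree table
#'
#' Tab-separated `id`, `dam`, `sire`, with `"0"` marking an unknown
#' parent.
#'
#' @param path file path.
#' @return `readPedigreeTable`: a `data.frame`.
#' @export
readPedigreeTable <- function(path) {
    ped <- read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character")
    if (!all(c("id", "dam", "sire") %in% colnames(ped)))
        stop("pedigree table needs columns id, dam, sire")
    ped
}

#' @rdname readPedigreeTable
#' @param ped pedigree `data.frame` (or [PedigreeGraph-class], exported
#'   via [asPedigreeTable()]).
#' @export
writePedigreeTable <- function(ped, path) {
    if (is(ped, "PedigreeGraph")) ped <- asPedigreeTable(ped)
    write.table(ped[, c("id", "dam", "sire")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
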