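#' Build a GenotypeExperiment from a dosage matrix
#'
#' @param dosage numeric/integer matrix, sites in rows and samples in
#'   columns, coded 0/1/2 with `NA` for missing. Row and column names are
#'   the site and sample ids (generated when absent).
#' @param scaffold character vector of scaffold ids, one per site.
#' @param pos integer vector of 1-based positions, one per site.
#' @param ref,alt reference and alternate alleles (alternate may be a
#'   comma-separated string for multi-allelic sites). Optional.
#' @param siteData optional `DataFrame`/`data.frame` of further per-site
#'   annotation columns.
#'
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, NA), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' ge <- makeGenotypeExperiment(d, scaffold = c("sc1", "sc1"), pos = c(10, 20))
#' dosageMatrix(ge)
#' @export
makeGenotypeExperiment <- function(dosage, scaffold, pos, ref = NULL,
                                   alt = NULL, siteData = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- sprintf("site%05d", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("sample%03d", seq_len(ncol(dosage)))
    if (length(scaffold) != nrow(dosage) || length(pos) != nrow(dosage))
        stop("scaffold and pos must have one entry per site")
    rr <- GRanges(seqnames = scaffold, ranges = IRanges(start = pos, width = 1L))
    names(rr) <- rownames(dosage)
    rd <- DataFrame(row.names = rownames(dosage))
    if (!is.null(ref)) rd$ref <- ref
    if (!is.null(alt)) rd$alt <- alt
    if (!is.null(siteData)) {
        siteData <- as(siteData, "DataFrame")
        rd[colnames(siteData)] <- siteData
    }
    se <- SummarizedExperiment(assays = list(dosage = dosage), rowRanges = rr)
    rowData(se) <- rd
    new("GenotypeExperiment", se)
}

#' Extract the dosage matrix
#'
#' @param x a [GenotypeExperiment-class].
#' @return Integer matrix, sites x samples, values 0/1/2/`NA`.
#' @rdname dosageMatrix
#' @export
setMethod("dosageMatrix", "GenotypeExperiment",
          function(x) assay(x, "dosage"))

#' Per-site annotation table
#'
#' Returns the per-site annotations (`rowData`) together with `scaffold`
#' and `pos` columns, as a `DataFrame` keyed by site id.
#'
#' @param x a [GenotypeExperiment-class].
#' @rdname siteInfo
#' @export
setMethod("siteInfo", "GenotypeExperiment", function(x) {
    rd <- rowData(x)
    out <- DataFrame(site = rownames(x),
                     scaffold = as.character(seqnames(rowRanges(x))),
                     pos = start(rowRanges(x)))
    out[colnames(rd)] <- rd
    rownames(out) <- rownames(x)
    out
})

#' Per-sample call rate
#'
#' Proportion of non-missing genotypes per sample.
#'
#' @param x a [GenotypeExperiment-class] or dosage matrix (sites x samples).
#' @return Named numeric vector in \[0, 1\].
#' @export
sampleCallRate <- function(x) {
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    colMeans(!is.na(d))
}

setMethod("show", "GenotypeExperiment", function(object) {
    cat(sprintf("GenotypeExperiment: %d sites x %d samples\n",
                nrow(object), ncol(object)))
    d <- assay(object, "dosage")
    cat(sprintf("  missing: %.2f%%; scaffolds: %d\n",
                100 * mean(is.na(d)),
                length(unique(as.character(seqnames(rowRanges(object)))))))
    ann <- setdiff(colnames(rowData(object)), c("ref", "alt"))
    if (length(ann))
        cat("  site annotations:", paste(head(ann, 8), collapse = ", "),
            if (length(ann) > 8) "..." else "", "\n")
})
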