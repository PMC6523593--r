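## Panel selection: effect-class sites, fixed (all-homozygous) sites, and
## the windowed focal-point/tagSNP selection, then assembly under a probe
## budget with explicit shortfall reporting.

#' Select sites by predicted gene effect
#'
#' Returns sites annotated with a HIGH or MODERATE effect (mis-sense /
#' non-sense changes in predicted genes).
#'
#' @param x a [GenotypeExperiment-class] with an `effectClass` annotation.
#' @param classes effect classes to keep.
#' @return Character vector of site ids.
#' @export
selectEffectSnps <- function(x, classes = c("HIGH", "MODERATE")) {
    si <- .siteTable(x)
    .needCols(si, "effectClass", "selectEffectSnps")
    si$site[si$effectClass %in% classes]
}

#' Select all-homozygous (fixed-allele) sites
#'
#' Sites whose every non-missing genotype in the discovery panel is
#' homozygous, with at most `maxMissing` missing calls. Two published
#' wordings of this rule exist; both are available: the default
#' `mode = "either"` accepts homozygotes of either allele, while
#' `mode = "alt_only"` demands homozygous-alternate genotypes only.
#'
#' @param x a [GenotypeExperiment-class] (the discovery panel).
#' @param maxMissing maximum missing genotypes per site (default 3).
#' @param mode `"either"` or `"alt_only"`.
#' @return Character vector of site ids.
#' @export
selectAllHom <- function(x, maxMissing = 3, mode = c("either", "alt_only")) {
    mode <- match.arg(mode)
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    nMiss <- rowSums(is.na(d))
    hom <- if (mode == "either")
        rowSums(d == 1L, na.rm = TRUE) == 0L
    else
        rowSums(d != 2L, na.rm = TRUE) == 0L
    ok <- hom & nMiss <= maxMissing & nMiss < ncol(d)
    rownames(d)[ok]
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over their jointly
#' non-missing entries. With fewer than two complete pairs, or zero
#' variance in either vector, there is no LD information and `NA` is
#' returned (treated as r-squared 0 by the pruning routines).
#'
#' @param gi,gj numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or `NA`.
#' @examples
#' ldR2(c(0, 1, 2, 1, 0), c(0, 1, 1, 1, 0))
#' @export
ldR2 <- function(gi, gj) {
    ok <- !is.na(gi) & !is.na(gj)
    if (sum(ok) < 2L) return(NA_real_)
    x <- gi[ok]; y <- gj[ok]
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)^2
}

## r^2 of one site against each column of a site x ? ... here: candidate
## matrix is samples x sites; returns vector of r^2 (NA where undefined).
.r2Vec <- function(g, M) {
    apply(M, 2L, function(col) ldR2(g, col))
}

#' Tile scaffolds into focal-point windows
#'
#' Non-overlapping windows of `windowSize` bases tiled from position 1 of
#' each scaffold; the final partial window is kept. The focal point is the
#' window midpoint.
#'
#' @param scaffoldLengths named numeric vector of scaffold lengths.
#' @param windowSize window width in bases (default 10 kb).
#' @return `data.frame` with `scaffold`, `start`, `end`, `focal`.
#' @examples
#' makeWindows(c(sc1 = 25000))
#' @export
makeWindows <- function(scaffoldLengths, windowSize = 10000) {
    stopifnot(!is.null(names(scaffoldLengths)), windowSize >= 1)
    out <- lapply(names(scaffoldLengths), function(s) {
        len <- scaffoldLengths[[s]]
        start <- seq(1, len, by = windowSize)
        end <- pmin(start + windowSize - 1, len)
        data.frame(scaffold = s, start = start, end = end,
                   focal = floor((start + end) / 2))
    })
    do.call(rbind, out)
}

#' Windowed focal-point/tagSNP selection
#'
#' Within each 10-kb window: (1) discard sites that are all-heterozygous
#' or all-homozygous in the panel, or have more than `maxMissing` missing
#' genotypes; (2) select tag SNPs greedily in order of decreasing MAF
#' (ties by ascending position), accepting a candidate only if its
#' r-squared with every already-accepted site in the window is below
#' `r2Threshold`. A pair at exactly the threshold counts as too strongly
#' correlated. Undefined r-squared (no LD information) never blocks.
#'
#' @param x a [GenotypeExperiment-class].
#' @param r2Threshold LD threshold (default 0.81).
#' @param windowSize focal-point window width in bases (default 10 kb).
#' @param maxMissing maximum missing genotypes per candidate (default 6).
#' @return Character vector of selected site ids.
#' @export
selectTagSnps <- function(x, r2Threshold = 0.81, windowSize = 10000,
                          maxMissing = 6) {
    stopifnot(is(x, "GenotypeExperiment"))
    d <- dosageMatrix(x)
    scaffold <- as.character(seqnames(rowRanges(x)))
    pos <- start(rowRanges(x))
    nMiss <- rowSums(is.na(d))
    nObs <- ncol(d) - nMiss
    nHet <- rowSums(d == 1L, na.rm = TRUE)
    allHet <- nObs > 0L & nHet == nObs
    allHom <- nHet == 0L
    keep <- which(!allHet & !allHom & nMiss <= maxMissing)
    if (!length(keep)) return(character(0))
    p <- rowMeans(d[keep, , drop = FALSE], na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    win <- paste(scaffold[keep], (pos[keep] - 1L) %/% windowSize, sep = ":")
    sel <- character(0)
    for (w in unique(win)) {
        idx <- keep[win == w]
        o <- order(-maf[match(idx, keep)], pos[idx])
        idx <- idx[o]
        acc <- integer(0)
        for (i in idx) {
            if (!length(acc)) { acc <- i; next }
            r2 <- vapply(acc, function(j) ldR2(d[i, ], d[j, ]), 0)
            r2[is.na(r2)] <- 0
            if (all(r2 < r2Threshold)) acc <- c(acc, i)
        }
        sel <- c(sel, rownames(d)[acc])
    }
    sel
}

## probe cost: A/T and C/G alleles need one probe per allele
.probeCost <- function(ref, alt) {
    pair <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
    ifelse(pair %in% c("A/T", "C/G"), 2L, 1L)
}

#' Assemble the final array panel
#'
#' Takes the three selection sets, resolves overlaps with reason priority
#' `HIGH_MOD_EFF > ALL_HOM > INFP`, charges two probes to A/T and C/G
#' sites (retained despite the extra cost), and, when `targetTotal` or
#' `probeBudget` is exceeded, trims *only* focal-point (INFP) sites:
#' round-robin across windows, removing the lowest-MAF remaining INFP of
#' each window per round. An unreachable target is reported as a positive
#' `shortfall`, never silently.
#'
#' @param effect,allHom,tag character vectors of site ids from
#'   [selectEffectSnps()], [selectAllHom()], [selectTagSnps()].
#' @param x the [GenotypeExperiment-class] the ids refer to.
#' @param targetTotal optional panel-size target.
#' @param probeBudget optional maximum total probe count.
#' @param windowSize window width used for round-robin trimming.
#' @return A [SelectionResult-class].
#' @export
assemblePanel <- function(effect, allHom, tag, x, targetTotal = NULL,
                          probeBudget = NULL, windowSize = 10000) {
    stopifnot(is(x, "GenotypeExperiment"))
    si <- siteInfo(x)
    ids <- unique(c(effect, allHom, tag))
    if (!all(ids %in% si$site))
        stop("selection sets contain unknown site ids")
    reason <- ifelse(ids %in% effect, "HIGH_MOD_EFF",
                     ifelse(ids %in% allHom, "ALL_HOM", "INFP"))
    d <- dosageMatrix(x)[ids, , drop = FALSE]
    p <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    row <- match(ids, si$site)
    ref1 <- substr(si$ref[row], 1L, 1L)
    alt1 <- substr(si$alt[row], 1L, 1L)
    cost <- .probeCost(ref1, alt1)
    keep <- rep(TRUE, length(ids))
    isInfp <- reason == "INFP"
    win <- paste(si$scaffold[row], (si$pos[row] - 1L) %/% windowSize,
                 sep = ":")

    over <- function() {
        tooMany <- !is.null(targetTotal) && sum(keep) > targetTotal
        tooCost <- !is.null(probeBudget) && sum(cost[keep]) > probeBudget
        tooMany || tooCost
    }
    if (over()) {
        byWin <- split(which(isInfp), win[isInfp])
        byWin <- lapply(byWin, function(i) i[order(maf[i])])  # lowest first
        repeat {
            removed <- FALSE
            for (w in seq_along(byWin)) {
                if (!over()) break
                i <- byWin[[w]]
                i <- i[keep[i]]
                if (length(i)) {
                    keep[i[1L]] <- FALSE
                    removed <- TRUE
                }
            }
            if (!over() || !removed) break
        }
    }
    shortfall <- if (!is.null(targetTotal) && sum(keep) < targetTotal)
        as.integer(targetTotal - sum(keep)) else 0L
    if (shortfall > 0L)
        warning("panel target unreachable: short by ", shortfall, " sites")

    sel <- DataFrame(site = ids[keep], scaffold = si$scaffold[row][keep],
                     pos = si$pos[row][keep], ref = si$ref[row][keep],
                     alt = si$alt[row][keep], reason = reason[keep],
                     probeCost = cost[keep])
    totals <- table(factor(sel$reason,
                           levels = c("HIGH_MOD_EFF", "ALL_HOM", "INFP")))
    new("SelectionResult", sites = sel,
        totals = setNames(as.integer(totals), names(totals)),
        totalProbeCost = as.integer(sum(sel$probeCost)),
        targetTotal = if (is.null(targetTotal)) NA_integer_
                      else as.integer(targetTotal),
        shortfall = shortfall)
}

#' Write a selection result as TSV
#'
#' @param result a [SelectionResult-class].
#' @param path output path.
#' @return Invisibly, the result.
#' @export
writeSelectionResult <- function(result, path) {
    stopifnot(is(result, "SelectionResult"))
    write.table(as.data.frame(result@sites), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(result)
}
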