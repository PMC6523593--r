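## Pairwise relatedness from dosage genotypes: the KING-robust
## between-family kinship estimator and the proportion of zero-IBS sites
## (opposite homozygotes), plus the prefilters applied before estimation
## (sample call-rate QC, site missing-rate and MAF filters, LD pruning).
##
## For a pair (i, j), over their jointly non-missing sites, let N11 be the
## number of sites where both are heterozygous, N02 the number where they
## are opposite homozygotes, and Ni, Nj each sample's heterozygous-site
## counts. The robust kinship estimate is
##   k = (N11 - 2 N02) / (2 min(Ni, Nj)) + 1/2 - (Ni + Nj) / (4 min(Ni, Nj))
## and IBS0 = N02 / N(shared). Identical genotypes give k = 0.5 exactly;
## expected values are 0.25 for parent-offspring and full sibs, 0.125 for
## half sibs and 0 for unrelated pairs.

#' Sample call-rate quality control
#'
#' Excludes samples whose call rate is below `minCallRate` (strict `<`).
#'
#' @param x a [GenotypeExperiment-class].
#' @param minCallRate threshold (default 0.97).
#' @return A list: `genotypes` (retained samples) and `excluded`
#'   (`data.frame` of dropped samples with their call rates).
#' @export
sampleQC <- function(x, minCallRate = 0.97) {
    stopifnot(is(x, "GenotypeExperiment"), ncol(x) > 0L)
    cr <- sampleCallRate(x)
    drop <- cr < minCallRate
    if (all(drop))
        stop("all samples fall below the call-rate threshold")
    list(genotypes = x[, !drop],
         excluded = data.frame(sample = names(cr)[drop],
                               callRate = unname(cr[drop])))
}

#' Prune sites for linkage disequilibrium
#'
#' Position-ordered greedy pruning within sliding windows: walking each
#' scaffold in position order, a site is kept only if its r-squared with
#' every already-kept site within `windowBp` bases is at most `r2Max`.
#' Deterministic for a given input.
#'
#' @param x a [GenotypeExperiment-class].
#' @param r2Max maximum tolerated r-squared (default 0.25).
#' @param windowBp window width in bases (default 50 kb).
#' @return Character vector of retained site ids.
#' @export
ldPrune <- function(x, r2Max = 0.25, windowBp = 50000) {
    stopifnot(is(x, "GenotypeExperiment"))
    d <- dosageMatrix(x)
    scaffold <- as.character(seqnames(rowRanges(x)))
    pos <- start(rowRanges(x))
    keep <- character(0)
    for (s in unique(scaffold)) {
        idx <- which(scaffold == s)
        idx <- idx[order(pos[idx])]
        kept <- integer(0)
        for (i in idx) {
            near <- kept[pos[kept] >= pos[i] - windowBp]
            r2 <- vapply(near, function(j) ldR2(d[i, ], d[j, ]), 0)
            r2[is.na(r2)] <- 0
            if (all(r2 <= r2Max)) kept <- c(kept, i)
        }
        keep <- c(keep, rownames(d)[kept])
    }
    keep
}

#' Genotype-pair counts for one pair of samples
#'
#' Counts over the jointly non-missing sites of two dosage vectors:
#' both heterozygous (`nHetHet`), opposite homozygotes (`nOppHom`),
#' heterozygous in each sample (`nHetI`, `nHetJ`), and the shared total
#' (`nShared`).
#'
#' @param gi,gj numeric dosage vectors of equal length.
#' @return Named numeric vector; all `NA` when no site is jointly typed.
#' @examples
#' pairwiseCounts(c(0, 1, 2, 1), c(2, 1, 0, 1))
#' @export
pairwiseCounts <- function(gi, gj) {
    ok <- !is.na(gi) & !is.na(gj)
    if (!any(ok))
        return(c(nHetHet = NA_real_, nOppHom = NA_real_, nHetI = NA_real_,
                 nHetJ = NA_real_, nShared = NA_real_))
    a <- gi[ok]; b <- gj[ok]
    c(nHetHet = as.numeric(sum(a == 1 & b == 1)),
      nOppHom = as.numeric(sum(abs(a - b) == 2)),
      nHetI = as.numeric(sum(a == 1)), nHetJ = as.numeric(sum(b == 1)),
      nShared = as.numeric(length(a)))
}

#' KING-robust kinship and IBS0 from pair counts
#'
#' @param counts named vector or data.frame with `nHetHet`, `nOppHom`,
#'   `nHetI`, `nHetJ`, `nShared` (as from [pairwiseCounts()]).
#' @return `kingKinship`: the kinship estimate (NA when either sample has
#'   no heterozygous site among the shared ones, which leaves the
#'   estimator undefined). `ibs0`: the opposite-homozygote proportion.
#' @examples
#' kingKinship(pairwiseCounts(c(0, 1, 2, 1), c(2, 1, 0, 1)))  # -0.5
#' @export
kingKinship <- function(counts) {
    counts <- as.data.frame(as.list(counts))  # accepts vector or df
    m <- pmin(counts$nHetI, counts$nHetJ)
    k <- (counts$nHetHet - 2 * counts$nOppHom) / (2 * m) + 0.5 -
        (counts$nHetI + counts$nHetJ) / (4 * m)
    k[!is.na(m) & m == 0] <- NA_real_
    k
}

#' @rdname kingKinship
#' @export
ibs0 <- function(counts) {
    counts <- as.data.frame(as.list(counts))
    counts$nOppHom / counts$nShared
}

## All-pairs genotype-pair counts via matrix products; G is samples x sites.
.kingCountsMatrix <- function(G) {
    H <- (G == 1L); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
    A0 <- (G == 0L); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
    A2 <- (G == 2L); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
    M <- !is.na(G); storage.mode(M) <- "double"
    list(NHH = tcrossprod(H),
         NOPP = tcrossprod(A0, A2) + tcrossprod(A2, A0),
         NHETI = tcrossprod(H, M),          # [i, j] = het in i over shared
         NS = tcrossprod(M))
}

#' Pairwise relatedness for a whole collection
#'
#' Applies the standard prefilters -- drop sites with missing rate above
#' `maxMissingRate` or MAF below `minMaf`, then LD pruning ([ldPrune()])
#' -- and computes [pairwiseCounts()], [kingKinship()] and [ibs0()] for
#' every unordered sample pair on the pruned set.
#'
#' @param x a [GenotypeExperiment-class] (post sample QC).
#' @param maxMissingRate site missing-rate cutoff (default 0.2, strict >).
#' @param minMaf site MAF cutoff (default 0.05, strict <).
#' @param ldR2Max,ldWindowBp LD-pruning parameters (0.25, 50 kb).
#' @param prune set `FALSE` to skip all site prefilters.
#' @return `data.frame` with one row per pair: `i`, `j`, the five counts,
#'   `kinship` and `ibs0`. The number of sites used is in
#'   `attr(, "nSitesUsed")`. Undefined estimates are `NA`, not an error.
#' @export
relatednessMatrix <- function(x, maxMissingRate = 0.2, minMaf = 0.05,
                              ldR2Max = 0.25, ldWindowBp = 50000,
                              prune = TRUE) {
    stopifnot(is(x, "GenotypeExperiment"), ncol(x) >= 2L)
    if (prune) {
        d <- dosageMatrix(x)
        missRate <- rowMeans(is.na(d))
        p <- rowMeans(d, na.rm = TRUE) / 2
        maf <- pmin(p, 1 - p)
        ok <- missRate <= maxMissingRate & !is.na(maf) & maf >= minMaf
        x <- x[ok, ]
        keep <- ldPrune(x, r2Max = ldR2Max, windowBp = ldWindowBp)
        x <- x[keep, ]
    }
    G <- t(dosageMatrix(x))
    cm <- .kingCountsMatrix(G)
    n <- nrow(G)
    ut <- which(upper.tri(cm$NS), arr.ind = TRUE)
    counts <- data.frame(
        i = rownames(G)[ut[, 1L]], j = rownames(G)[ut[, 2L]],
        nHetHet = cm$NHH[ut], nOppHom = cm$NOPP[ut],
        nHetI = cm$NHETI[ut],
        nHetJ = t(cm$NHETI)[ut],
        nShared = cm$NS[ut])
    counts$nHetHet[counts$nShared == 0] <- NA_real_
    counts$nOppHom[counts$nShared == 0] <- NA_real_
    counts$kinship <- kingKinship(counts)
    counts$ibs0 <- ifelse(counts$nShared > 0,
                          counts$nOppHom / counts$nShared, NA_real_)
    attr(counts, "nSitesUsed") <- nrow(x)
    counts
}

#' Genotype concordance between two call sets
#'
#' Percentage of identical calls among jointly non-missing genotypes, per
#' sample and on average, over the sites and samples the two sets share.
#'
#' @param a,b [GenotypeExperiment-class] objects.
#' @param sampleMap optional `data.frame` with columns `a`, `b` mapping
#'   sample ids in `a` to ids in `b`; by default samples are matched by
#'   name.
#' @return A list: `perSample` (`data.frame` with `sample`, `nCompared`,
#'   `concordance` in percent) and `mean`.
#' @export
genotypeConcordance <- function(a, b, sampleMap = NULL) {
    stopifnot(is(a, "GenotypeExperiment"), is(b, "GenotypeExperiment"))
    sites <- intersect(rownames(a), rownames(b))
    if (!length(sites)) stop("no shared sites between the two call sets")
    if (is.null(sampleMap)) {
        shared <- intersect(colnames(a), colnames(b))
        sampleMap <- data.frame(a = shared, b = shared)
    }
    if (!nrow(sampleMap)) stop("no shared samples between the two call sets")
    da <- dosageMatrix(a)[sites, sampleMap$a, drop = FALSE]
    db <- dosageMatrix(b)[sites, sampleMap$b, drop = FALSE]
    ok <- !is.na(da) & !is.na(db)
    agree <- ok & da == db
    n <- colSums(ok)
    conc <- ifelse(n > 0, 100 * colSums(agree) / n, NA_real_)
    list(perSample = data.frame(sample = sampleMap$a, nCompared = n,
                                concordance = unname(conc)),
         mean = mean(conc, na.rm = TRUE))
}
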