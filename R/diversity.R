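## Per-SNP and per-set diversity statistics, robust-set derivation from
## Mendelian error counts, allele-frequency-scaled PCA, and UPGMA
## clustering on allele-sharing distance.

#' Per-site diversity statistics
#'
#' MAF (`min(p, 1 - p)` from non-missing dosages), observed
#' heterozygosity, and missing rate per site, plus unweighted set means.
#' All-missing sites have undefined statistics; they are excluded from
#' the means and counted.
#'
#' @param x a [GenotypeExperiment-class] or dosage matrix.
#' @param sites optional site ids to restrict to.
#' @return A list: `perSite` (`DataFrame` with `site`, `maf`, `het`,
#'   `missingRate`), `means` (named vector), `nUndefined`.
#' @export
snpStats <- function(x, sites = NULL) {
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    if (!is.null(sites)) d <- d[sites, , drop = FALSE]
    if (!nrow(d)) stop("no sites selected")
    nObs <- unname(rowSums(!is.na(d)))
    p <- ifelse(nObs > 0, unname(rowSums(d, na.rm = TRUE)) / (2 * nObs),
                NA_real_)
    maf <- pmin(p, 1 - p)
    het <- ifelse(nObs > 0, unname(rowSums(d == 1L, na.rm = TRUE)) / nObs,
                  NA_real_)
    missingRate <- 1 - nObs / ncol(d)
    perSite <- DataFrame(site = rownames(d), maf = maf, het = het,
                         missingRate = missingRate)
    list(perSite = perSite,
         means = c(maf = mean(maf, na.rm = TRUE),
                   het = mean(het, na.rm = TRUE),
                   missingRate = mean(missingRate)),
         nUndefined = sum(nObs == 0L))
}

#' Per-family fixation index
#'
#' For each family with at least `minFamilySize` members,
#' `F_IS = 1 - Ho / He` where `Ho` is the mean observed heterozygosity
#' and `He` the mean Hardy-Weinberg expectation `2p(1-p)` (allele
#' frequencies estimated within the family), both averaged over the
#' family's polymorphic sites. Negative values mark heterozygote excess.
#'
#' @param x a [GenotypeExperiment-class] or dosage matrix.
#' @param families named character/factor assigning samples to families.
#' @param minFamilySize smallest family evaluated (default 5).
#' @return `data.frame` with `family`, `n`, `nPolymorphic`, `ho`, `he`,
#'   `fis` (`NA` with zero polymorphic sites, reported not dropped).
#' @export
fisPerFamily <- function(x, families, minFamilySize = 5) {
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    stopifnot(!is.null(names(families)))
    families <- families[names(families) %in% colnames(d)]
    out <- list()
    for (fam in unique(as.character(families))) {
        ids <- names(families)[families == fam]
        if (length(ids) < minFamilySize) next
        dd <- d[, ids, drop = FALSE]
        nObs <- rowSums(!is.na(dd))
        p <- ifelse(nObs > 0, rowSums(dd, na.rm = TRUE) / (2 * nObs), NA)
        poly <- !is.na(p) & p > 0 & p < 1
        if (!any(poly)) {
            out[[fam]] <- data.frame(family = fam, n = length(ids),
                                     nPolymorphic = 0L, ho = NA_real_,
                                     he = NA_real_, fis = NA_real_)
            next
        }
        ho <- mean(rowSums(dd[poly, , drop = FALSE] == 1L, na.rm = TRUE) /
                   nObs[poly])
        he <- mean(2 * p[poly] * (1 - p[poly]))
        out[[fam]] <- data.frame(family = fam, n = length(ids),
                                 nPolymorphic = sum(poly), ho = ho, he = he,
                                 fis = 1 - ho / he)
    }
    if (!length(out))
        return(data.frame(family = character(), n = integer(),
                          nPolymorphic = integer(), ho = numeric(),
                          he = numeric(), fis = numeric()))
    ans <- do.call(rbind, out)
    rownames(ans) <- NULL
    ans
}

#' Derive robust SNP sets from Mendelian error counts
#'
#' The robust PHR set keeps PHR-class sites with zero Mendelian
#' inconsistencies across all tested trios and duos; the robust NMH+OTV
#' set is the union of the NMH, OTV, AAvar, ABvar and BBvar classes,
#' likewise restricted to zero errors. With no tested families every
#' error count is zero, so the robust sets equal the class sets; this
#' vacuous case warns.
#'
#' @param classLabels `data.frame` with columns `site`, `class`.
#' @param errorCounts named integer vector of per-site Mendelian error
#'   counts (as from [countMendelianErrors()]); sites absent from the
#'   vector count as zero errors.
#' @return A list: `robustPHR` and `robustNmhOtv` (character vectors).
#' @export
deriveRobustSets <- function(classLabels, errorCounts) {
    stopifnot(all(c("site", "class") %in% colnames(classLabels)))
    nf <- attr(errorCounts, "nFamiliesTested")
    if ((!is.null(nf) && nf == 0L) || !length(errorCounts))
        warning("no trios or duos tested; robust sets equal the class sets")
    err <- setNames(rep(0L, nrow(classLabels)), classLabels$site)
    hit <- intersect(names(errorCounts), names(err))
    err[hit] <- errorCounts[hit]
    zero <- classLabels$site[err[classLabels$site] == 0L]
    phr <- classLabels$site[classLabels$class == "PHR"]
    nmh <- classLabels$site[classLabels$class %in%
                            c("NMH", "OTV", "AAvar", "ABvar", "BBvar")]
    list(robustPHR = intersect(phr, zero),
         robustNmhOtv = intersect(nmh, zero))
}

#' Principal component analysis of SNP dosages
#'
#' Dosages are centred by twice the estimated allele frequency and scaled
#' by `sqrt(2p(1-p))` (the usual SNP normalisation); missing entries are
#' mean-imputed (zero after centring). Components come from the
#' eigendecomposition of the sample covariance of the scaled matrix;
#' variance-explained proportions sum to one over all components.
#'
#' @param x a [GenotypeExperiment-class] or dosage matrix.
#' @param sites optional site ids to restrict to.
#' @return A list: `scores` (samples x components, scaled by the root
#'   eigenvalue), `vectors`, `values`, `varprop`.
#' @export
snpPCA <- function(x, sites = NULL) {
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    if (!is.null(sites)) d <- d[sites, , drop = FALSE]
    if (ncol(d) < 2L) stop("need at least two samples")
    nObs <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * pmax(nObs, 1L))
    poly <- nObs > 0L & p > 0 & p < 1
    if (sum(poly) < 2L) stop("need at least two polymorphic sites")
    Z <- (d[poly, , drop = FALSE] - 2 * p[poly]) / sqrt(2 * p[poly] *
                                                        (1 - p[poly]))
    Z[is.na(Z)] <- 0
    S <- crossprod(Z) / sum(poly)     # samples x samples covariance
    eig <- eigen(S, symmetric = TRUE)
    vals <- pmax(eig$values, 0)
    if (sum(vals) == 0) stop("degenerate genotype matrix (rank 0)")
    scores <- eig$vectors %*% diag(sqrt(vals), nrow = length(vals))
    dimnames(scores) <- list(colnames(d),
                             paste0("PC", seq_along(vals)))
    list(scores = scores, vectors = eig$vectors, values = vals,
         varprop = vals / sum(vals))
}

#' Allele-sharing (1 - IBS) distance matrix
#'
#' For each pair, the mean proportion of shared alleles per jointly
#' non-missing site (IBS) is computed from the genotype-pair counts, and
#' the distance is `1 - IBS`. Identical genotypes give distance 0.
#'
#' @param x a [GenotypeExperiment-class] or dosage matrix.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
ibsDistance <- function(x) {
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    G <- t(d)
    cm <- .kingCountsMatrix(G)
    NHETI <- cm$NHETI
    hetHom <- NHETI + t(NHETI) - 2 * cm$NHH  # het in exactly one sample
    if (any(cm$NS == 0))
        stop("some sample pairs share no typed sites")
    dist <- (0.5 * hetHom + cm$NOPP) / cm$NS
    diag(dist) <- 0
    dimnames(dist) <- list(rownames(G), rownames(G))
    dist
}

#' UPGMA clustering of a distance matrix
#'
#' Agglomerative average-linkage (size-weighted) clustering producing a
#' rooted ultrametric tree: the nearest pair of clusters is merged at
#' height `d/2`, and distances to the merged cluster are the
#' size-weighted means of the members' distances. Ties in the nearest
#' pair break deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest member).
#'
#' @param d symmetric distance matrix with labelled rows, or a `dist`.
#' @return An [ape::phylo] tree with branch lengths; every leaf is
#'   equidistant from the root.
#' @examples
#' d <- matrix(c(0, .2, .5, .2, 0, .5, .5, .5, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' ape::write.tree(upgmaTree(d))
#' @export
upgmaTree <- function(d) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    stopifnot(isSymmetric(unname(d)), all(diag(d) == 0), all(d >= 0))
    labels <- rownames(d)
    if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
    n <- nrow(d)
    if (n < 2L) stop("need at least two taxa")
    if (any(is.na(d))) stop("undefined pair distances")
    size <- rep(1L, n)
    label <- labels                 # smallest member, for tie-breaking
    id <- -seq_len(n)               # hclust convention: negatives = leaves
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    D <- d
    activeIdx <- seq_len(n)
    for (step in seq_len(n - 1L)) {
        m <- length(activeIdx)
        best <- NULL
        for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
            ia <- activeIdx[a]; ib <- activeIdx[b]
            dd <- D[ia, ib]
            lab <- sort(c(label[ia], label[ib]))
            if (is.null(best) || dd < best$d - 1e-15 ||
                (abs(dd - best$d) <= 1e-15 &&
                 (lab[1L] < best$lab[1L] ||
                  (lab[1L] == best$lab[1L] && lab[2L] < best$lab[2L])))) {
                best <- list(a = ia, b = ib, d = dd, lab = lab)
            }
        }
        ia <- best$a; ib <- best$b
        merge[step, ] <- sort(c(id[ia], id[ib]))
        height[step] <- best$d
        for (ic in setdiff(activeIdx, c(ia, ib))) {
            newd <- (size[ia] * D[ia, ic] + size[ib] * D[ib, ic]) /
                (size[ia] + size[ib])
            D[ia, ic] <- newd; D[ic, ia] <- newd
        }
        size[ia] <- size[ia] + size[ib]
        label[ia] <- min(label[ia], label[ib])
        id[ia] <- step
        activeIdx <- setdiff(activeIdx, ib)
    }
    hc <- list(merge = merge, height = height, order = .hcOrder(merge, n),
               labels = labels, method = "upgma")
    class(hc) <- "hclust"
    ape::as.phylo(hc)               # leaf depth = height / 2 (ultrametric)
}

## leaf ordering consistent with the merge matrix (required by hclust)
.hcOrder <- function(merge, n) {
    expand <- function(node) {
        if (node < 0L) return(-node)
        c(expand(merge[node, 1L]), expand(merge[node, 2L]))
    }
    expand(n - 1L)
}
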