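## From pairwise relatedness to a validated pedigree: threshold
## calibration against recorded relationships, deterministic pair
## classification, Mendelian trio/duo testing, and parent assignment with
## explicit edge provenance.

## Trio impossibility lookup: impossible[p1+1, p2+1, c+1] under biallelic
## Mendelian transmission. Duo rule: child and parent opposite homozygous.
.trioImpossible <- local({
    arr <- array(FALSE, dim = c(3L, 3L, 3L))
    for (p1 in 0:2) for (p2 in 0:2) for (ch in 0:2) {
        g1 <- if (p1 == 1L) 0:1 else p1 / 2L    # transmittable alleles
        g2 <- if (p2 == 1L) 0:1 else p2 / 2L
        possible <- outer(g1, g2, `+`)
        arr[p1 + 1L, p2 + 1L, ch + 1L] <- !(ch %in% possible)
    }
    arr
})

#' Mendelian inconsistency rate for a duo or trio
#'
#' Duo rule: a site is inconsistent when child and parent are opposite
#' homozygotes. Trio rule: the child genotype is impossible under
#' biallelic Mendelian transmission from the two parent genotypes
#' (parents 0x0 with child 1 or 2, 0x1 with child 2, 0x2 with child 0 or
#' 2, 1x2 with child 0, 2x2 with child 0 or 1). The rate denominator is
#' the number of sites where child and all supplied parents are typed.
#'
#' @param child,parent1,parent2 dosage vectors (omit `parent2` for a duo).
#' @return A list: `rate`, `nErrors`, `nInformative`, and `flags`
#'   (logical per site; `NA` where not jointly typed).
#' @examples
#' mendelianInconsistency(c(1, 0), c(0, 0), c(0, 2))$flags
#' @export
mendelianInconsistency <- function(child, parent1, parent2 = NULL) {
    if (is.null(parent2)) {
        ok <- !is.na(child) & !is.na(parent1)
        if (!any(ok)) stop("no jointly typed sites for the duo")
        err <- abs(child - parent1) == 2
    } else {
        ok <- !is.na(child) & !is.na(parent1) & !is.na(parent2)
        if (!any(ok)) stop("no jointly typed sites for the trio")
        err <- .trioImpossible[cbind(parent1 + 1L, parent2 + 1L, child + 1L)]
    }
    err[!ok] <- NA
    nInf <- sum(ok)
    nErr <- sum(err[ok])
    list(rate = nErr / nInf, nErrors = nErr, nInformative = nInf,
         flags = err)
}

#' Calibrate relationship thresholds from recorded relationships
#'
#' Recomputes the operating points from pairs whose relationship is
#' historically recorded: the first-degree kinship bound is the lower
#' edge of the central 95% interval (2.5th percentile) of k over known
#' parent-offspring and full-sib pairs, and the parent-offspring IBS0
#' ceiling is the maximum IBS0 observed among known PO pairs. The
#' duplicate bound and the Mendelian rate cap keep their defaults unless
#' overridden.
#'
#' @param pairs pair table from [relatednessMatrix()].
#' @param known `data.frame` with columns `i`, `j`, `relation`
#'   (`"PO"`, `"FS"`, other values ignored for calibration).
#' @param defaults a [KinshipThresholds-class] supplying the
#'   non-calibrated values.
#' @return A list: `thresholds` ([KinshipThresholds-class]) and `report`
#'   (pairs used, the k interval, the PO IBS0 maximum). Without known PO
#'   pairs, calibration is unavailable: defaults are returned with a
#'   warning.
#' @export
calibrateThresholds <- function(pairs, known,
                                defaults = kinshipThresholds()) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    pk <- key(pairs$i, pairs$j)
    known <- known[known$relation %in% c("PO", "FS"), , drop = FALSE]
    m <- match(key(known$i, known$j), pk)
    known <- known[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
    po <- known$relation == "PO"
    if (!any(po)) {
        warning("no known parent-offspring pairs; using default thresholds")
        return(list(thresholds = defaults,
                    report = list(nFirstDegreeUsed = 0L, nPoUsed = 0L)))
    }
    kAll <- pairs$kinship[m]
    kLo <- unname(quantile(kAll, 0.025, na.rm = TRUE))
    poIbs0 <- max(pairs$ibs0[m][po], na.rm = TRUE)
    th <- kinshipThresholds(duplicateK = defaults@duplicateK,
                            firstDegreeK = kLo, poIbs0Max = poIbs0,
                            mendelMaxRate = defaults@mendelMaxRate)
    list(thresholds = th,
         report = list(nFirstDegreeUsed = length(kAll), nPoUsed = sum(po),
                       kInterval = unname(quantile(kAll, c(0.025, 0.975),
                                                   na.rm = TRUE)),
                       poIbs0Max = poIbs0))
}

#' Classify a pair from kinship and IBS0
#'
#' Deterministic mapping: `DUPLICATE` when k > `duplicateK`; otherwise
#' `PARENT_OFFSPRING` when k >= `firstDegreeK` and IBS0 <= `poIbs0Max`;
#' `FULL_SIB` when k >= `firstDegreeK` and IBS0 > `poIbs0Max`; else
#' `OTHER`. Vectorized.
#'
#' @param k,ibs0 numeric vectors.
#' @param th a [KinshipThresholds-class].
#' @return Character vector of calls (`NA` inputs give `NA`).
#' @examples
#' classifyPair(c(0.48, 0.25, 0.25, 0.10), c(0, 0.01, 0.05, 0.06),
#'              kinshipThresholds())
#' @export
classifyPair <- function(k, ibs0, th = kinshipThresholds()) {
    stopifnot(is(th, "KinshipThresholds"))
    out <- ifelse(k > th@duplicateK, "DUPLICATE",
           ifelse(k >= th@firstDegreeK & ibs0 <= th@poIbs0Max,
                  "PARENT_OFFSPRING",
           ifelse(k >= th@firstDegreeK, "FULL_SIB", "OTHER")))
    out[is.na(k) | is.na(ibs0)] <- NA_character_
    out
}

#' Per-site Mendelian error counts over a pedigree
#'
#' Sums, per site, the Mendelian inconsistency flags over every active
#' trio (child with two active parents) and duo (one active parent) of a
#' pedigree graph. Feeds [deriveRobustSets()].
#'
#' @param x a [GenotypeExperiment-class].
#' @param graph a [PedigreeGraph-class].
#' @return Named integer vector, one count per site; an attribute
#'   `nFamiliesTested` records how many trios/duos contributed.
#' @export
countMendelianErrors <- function(x, graph) {
    stopifnot(is(x, "GenotypeExperiment"), is(graph, "PedigreeGraph"))
    d <- dosageMatrix(x)
    counts <- setNames(integer(nrow(d)), rownames(d))
    fams <- 0L
    for (ch in unique(pedigreeEdges(graph, active = TRUE)$child)) {
        if (!ch %in% colnames(d)) next
        par <- activeParents(graph)[[ch]]
        par <- par[par %in% colnames(d)]
        if (!length(par)) next
        res <- if (length(par) >= 2L)
            mendelianInconsistency(d[, ch], d[, par[1L]], d[, par[2L]])
        else mendelianInconsistency(d[, ch], d[, par[1L]])
        f <- res$flags
        counts <- counts + ifelse(is.na(f), 0L, as.integer(f))
        fams <- fams + 1L
    }
    attr(counts, "nFamiliesTested") <- fams
    counts
}

## duo/trio rate helper on the dosage matrix; Inf when untestable
.mendelRate <- function(d, ch, p1, p2 = NULL) {
    r <- tryCatch(
        mendelianInconsistency(d[, ch], d[, p1],
                               if (is.null(p2)) NULL else d[, p2])$rate,
        error = function(e) Inf)
    if (is.nan(r)) Inf else r
}

#' Reconstruct and validate a pedigree from pairwise relatedness
#'
#' The assignment procedure:
#' \enumerate{
#'   \item Duplicate pairs (k above the duplicate bound) are collapsed
#'     first; the representative is the sample with the highest call rate,
#'     and recorded parents of collapsed samples are remapped.
#'   \item Recorded parents present in the panel are validated against
#'     the pairwise evidence: the pair must be kinship-classified
#'     `PARENT_OFFSPRING` *and* pass the duo Mendelian test (with a
#'     low-MAF marker set the duo rate alone discriminates poorly, so
#'     both checks are required). Passing records become
#'     `recorded_confirmed`, failing ones `recorded_rejected`. Recorded
#'     parents that were not genotyped are left on the review list, not
#'     guessed.
#'   \item Each sample's candidate parents are its PARENT_OFFSPRING-
#'     classified partners from an earlier generation; when `generation`
#'     cannot orient a pair, the pair goes to the review list.
#'   \item Free parent slots are filled from the candidates: the trio
#'     with the lowest inconsistency rate below the cap wins; otherwise
#'     the best duo. Ties break by lower rate, then lower IBS0. A
#'     candidate replacing a rejected record in the same role is marked
#'     `corrected`; otherwise `new`.
#'   \item Passing candidates beyond the two-parent limit are flagged for
#'     review, never silently dropped.
#' }
#'
#' @param x a [GenotypeExperiment-class] (post [sampleQC()]).
#' @param pairs pair table from [relatednessMatrix()].
#' @param recorded optional recorded pedigree `data.frame` (`id`, `dam`,
#'   `sire`; `"0"` = unknown).
#' @param th a [KinshipThresholds-class] (ideally calibrated).
#' @param generation optional named integer vector giving each sample's
#'   generation (founders lowest); used to orient parent-offspring pairs.
#' @return A [PedigreeGraph-class].
#' @export
assignParents <- function(x, pairs, recorded = NULL,
                          th = kinshipThresholds(), generation = NULL) {
    stopifnot(is(x, "GenotypeExperiment"))
    d <- dosageMatrix(x)
    samples <- colnames(d)
    calls <- classifyPair(pairs$kinship, pairs$ibs0, th)

    ## 1. collapse duplicates (connected components, best call rate wins)
    dup <- pairs[!is.na(calls) & calls == "DUPLICATE", c("i", "j")]
    repOf <- setNames(samples, samples)
    dupRows <- list()
    if (nrow(dup)) {
        cr <- sampleCallRate(x)
        groups <- list()
        for (r in seq_len(nrow(dup))) {
            hit <- which(vapply(groups, function(g)
                any(c(dup$i[r], dup$j[r]) %in% g), TRUE))
            merged <- unique(c(dup$i[r], dup$j[r],
                               unlist(groups[hit], use.names = FALSE)))
            groups[hit] <- NULL
            groups[[length(groups) + 1L]] <- merged
        }
        for (g in groups) {
            rep <- g[order(-cr[g], g)][1L]
            for (s in setdiff(g, rep)) {
                repOf[s] <- rep
                dupRows[[length(dupRows) + 1L]] <-
                    data.frame(sample = s, representative = rep)
            }
        }
    }
    active <- samples[repOf[samples] == samples]

    ## pair lookup tables keyed on the unordered pair, on representatives
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    pi <- unname(repOf[pairs$i]); pj <- unname(repOf[pairs$j])
    self <- pi == pj
    pKey <- key(pi, pj)[!self]
    callMap <- setNames(calls[!self], pKey)
    kMap <- setNames(pairs$kinship[!self], pKey)
    iMap <- setNames(pairs$ibs0[!self], pKey)
    callOf <- function(a, b) unname(callMap[key(a, b)])
    kOf <- function(a, b) unname(kMap[key(a, b)])
    ibs0Of <- function(a, b) unname(iMap[key(a, b)])
    poTab <- data.frame(i = pi[!self], j = pj[!self])[
        !is.na(calls[!self]) & calls[!self] == "PARENT_OFFSPRING", ,
        drop = FALSE]

    edges <- list()
    review <- list()
    addEdge <- function(parent, child, role, prov, rate = NA_real_) {
        edges[[length(edges) + 1L]] <<- data.frame(
            parent = parent, child = child, role = role, provenance = prov,
            k = kOf(parent, child), ibs0 = ibs0Of(parent, child),
            mendelRate = rate, stringsAsFactors = FALSE)
    }
    addReview <- function(a, b, why) {
        review[[length(review) + 1L]] <<- data.frame(
            i = a, j = b, reason = why, stringsAsFactors = FALSE)
    }

    recOf <- function(id) {
        if (is.null(recorded)) return(c(dam = "0", sire = "0"))
        r <- recorded[recorded$id == id, , drop = FALSE]
        if (!nrow(r)) return(c(dam = "0", sire = "0"))
        out <- c(dam = r$dam[1L], sire = r$sire[1L])
        out[out %in% names(repOf)] <- repOf[out[out %in% names(repOf)]]
        out
    }

    for (ch in active) {
        rec <- recOf(ch)
        slots <- c(dam = NA_character_, sire = NA_character_)
        rejected <- c(dam = FALSE, sire = FALSE)
        ## 2. validate genotyped recorded parents: the pair must be
        ## kinship-classified PARENT_OFFSPRING and pass the duo test
        for (role in c("dam", "sire")) {
            p <- rec[[role]]
            if (p == "0" || p == ch) next
            if (!p %in% samples) {
                addReview(p, ch, "recorded parent not genotyped")
                next
            }
            if (p %in% slots[!is.na(slots)]) {  # same id in both roles
                rejected[[role]] <- TRUE
                addEdge(p, ch, role, "recorded_rejected")
                next
            }
            rate <- .mendelRate(d, ch, p)
            cl <- callOf(p, ch)
            if (!is.na(cl) && cl == "PARENT_OFFSPRING" &&
                rate < th@mendelMaxRate) {
                slots[[role]] <- p
                addEdge(p, ch, role, "recorded_confirmed", rate)
            } else {
                rejected[[role]] <- TRUE
                addEdge(p, ch, role, "recorded_rejected", rate)
            }
        }
        ## 3. orientable PO candidates (earlier generation only)
        part <- unique(c(poTab$j[poTab$i == ch], poTab$i[poTab$j == ch]))
        part <- setdiff(part, slots[!is.na(slots)])
        cand <- character(0)
        for (p in part) {
            if (is.null(generation) || is.na(generation[p]) ||
                is.na(generation[ch])) {
                addReview(p, ch, "parent-offspring pair not orientable")
            } else if (generation[p] < generation[ch]) {
                cand <- c(cand, p)
            }                       # partner in a later generation: it is
        }                           # the child of ch, handled on its turn
        ## 4. fill free slots, best trio first, then best duo
        nFree <- sum(is.na(slots))
        if (length(cand) && nFree > 0L) {
            chosen <- character(0)
            if (nFree == 1L) {
                fixed <- slots[!is.na(slots)][1L]
                rates <- vapply(cand, function(p)
                    .mendelRate(d, ch, fixed, p), 0)
                rates[!rates < th@mendelMaxRate] <- NA_real_
                if (all(is.na(rates))) {
                    duoR <- vapply(cand, function(p) .mendelRate(d, ch, p), 0)
                    ok <- duoR < th@mendelMaxRate
                    if (any(ok)) {
                        o <- order(duoR, vapply(cand, ibs0Of, 0, b = ch))
                        chosen <- cand[o][ok[o]][1L]
                        chosenRate <- duoR[cand == chosen]
                    }
                } else {
                    o <- order(rates, vapply(cand, ibs0Of, 0, b = ch))
                    chosen <- cand[o][!is.na(rates[o])][1L]
                    chosenRate <- rates[cand == chosen]
                }
            } else {
                ## both slots free: best passing trio over candidate pairs
                best <- NULL
                if (length(cand) >= 2L) {
                    cmb <- combn(sort(cand), 2L)
                    tr <- apply(cmb, 2L, function(pp)
                        .mendelRate(d, ch, pp[1L], pp[2L]))
                    ok <- tr < th@mendelMaxRate
                    if (any(ok)) {
                        tie <- vapply(seq_len(ncol(cmb)), function(c2)
                            sum(ibs0Of(cmb[1L, c2], ch),
                                ibs0Of(cmb[2L, c2], ch)), 0)
                        o <- order(tr, tie)
                        o <- o[ok[o]]
                        best <- list(p = cmb[, o[1L]], rate = tr[o[1L]])
                    }
                }
                if (!is.null(best)) {
                    chosen <- best$p
                    chosenRate <- best$rate
                } else {
                    duoR <- vapply(cand, function(p) .mendelRate(d, ch, p), 0)
                    ok <- duoR < th@mendelMaxRate
                    if (any(ok)) {
                        o <- order(duoR, vapply(cand, ibs0Of, 0, b = ch))
                        o <- o[ok[o]]
                        chosen <- cand[o[1L]]
                        chosenRate <- duoR[cand == chosen]
                    }
                }
            }
            for (p in chosen) {
                role <- names(slots)[is.na(slots)][1L]
                prov <- if (rejected[[role]]) "corrected" else "new"
                roleOut <- if (rejected[[role]] ||
                               (!is.null(recorded) && rec[[role]] != "0"))
                    role else if (is.null(recorded)) "unknown" else role
                slots[[role]] <- p
                addEdge(p, ch, roleOut, prov,
                        if (length(chosen) == 2L) chosenRate
                        else chosenRate[1L])
            }
            for (p in setdiff(cand, chosen)) {
                duoR <- .mendelRate(d, ch, p)
                if (duoR < th@mendelMaxRate && !any(is.na(slots)))
                    addReview(p, ch, "passing candidate beyond two parents")
            }
        }
    }

    e <- if (length(edges)) do.call(rbind, edges)
         else data.frame(parent = character(), child = character(),
                         role = character(), provenance = character(),
                         k = numeric(), ibs0 = numeric(),
                         mendelRate = numeric())
    rv <- if (length(review)) unique(do.call(rbind, review))
          else data.frame(i = character(), j = character(),
                          reason = character())
    dupDf <- if (length(dupRows)) do.call(rbind, dupRows)
             else data.frame(sample = character(), representative = character())
    new("PedigreeGraph", nodes = active, edges = as(e, "DataFrame"),
        duplicates = as(dupDf, "DataFrame"), review = as(rv, "DataFrame"))
}

#' Derive generations from a recorded pedigree
#'
#' Iteratively assigns generation 0 to samples with no recorded parent and
#' `1 + max(parent generations)` otherwise; unresolvable entries (cycles
#' in a corrupted record) are `NA`.
#'
#' @param recorded `data.frame` with `id`, `dam`, `sire` (`"0"` unknown).
#' @return Named integer vector.
#' @export
pedigreeGenerations <- function(recorded) {
    gen <- setNames(rep(NA_integer_, nrow(recorded)), recorded$id)
    known <- function(p) p != "0" & p %in% recorded$id
    noParent <- !known(recorded$dam) & !known(recorded$sire)
    gen[noParent] <- 0L
    for (it in seq_len(nrow(recorded))) {
        changed <- FALSE
        for (i in which(is.na(gen))) {
            ps <- c(recorded$dam[i], recorded$sire[i])
            ps <- ps[known(ps)]
            pg <- gen[ps]
            if (!any(is.na(pg))) {
                gen[i] <- max(pg) + 1L
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    gen
}
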