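#' Create a simulation configuration
#'
#' Defaults emulate the study conditions the package is designed around: a
#' founder panel of 27 highly heterozygous trees (expected heterozygosity
#' about 0.26), sites spread over many scaffolds, a 1% per-genotype error
#' rate, low missingness, and 2% parent-record mislabeling.
#'
#' @param nFounders,nSites,nScaffolds,scaffoldLength panel dimensions.
#' @param mafDistribution allele-frequency law; see [SimConfig-class]. The
#'   default `Beta(0.6, 1.8)` rescaled to \[0.05, 0.5\] gives an expected
#'   Hardy-Weinberg heterozygosity close to `targetHet`.
#' @param targetHet expected founder heterozygosity (documentation value).
#' @param genoErrorRate,missingRate,mislabelRate error-process rates.
#' @param seed integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' simConfig(nSites = 1000, seed = 42)
#' @export
simConfig <- function(nFounders = 27, nSites = 10000, nScaffolds = 20,
                      scaffoldLength = 5e5,
                      mafDistribution = list(type = "beta", shape1 = 0.6,
                                             shape2 = 1.8, min = 0.05,
                                             max = 0.5),
                      targetHet = 0.26, genoErrorRate = 0.01,
                      missingRate = 0.003, mislabelRate = 0.02, seed = 1L) {
    new("SimConfig", nFounders = as.integer(nFounders),
        nSites = as.integer(nSites), nScaffolds = as.integer(nScaffolds),
        scaffoldLength = as.numeric(scaffoldLength),
        mafDistribution = mafDistribution, targetHet = targetHet,
        genoErrorRate = genoErrorRate, missingRate = missingRate,
        mislabelRate = mislabelRate, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d founders, %d sites on %d scaffolds ",
                       "(%.0f bp)\n"),
                object@nFounders, object@nSites, object@nScaffolds,
                object@scaffoldLength))
    cat(sprintf("  maf: %s; target Het %.2f; error %.3f; missing %.3f; mislabel %.3f; seed %d\n",
                object@mafDistribution$type, object@targetHet,
                object@genoErrorRate, object@missingRate,
                object@mislabelRate, object@seed))
})

#' Create relationship-calling thresholds
#'
#' @param duplicateK,firstDegreeK,poIbs0Max,mendelMaxRate see
#'   [KinshipThresholds-class].
#' @return A validated [KinshipThresholds-class] object.
#' @examples
#' kinshipThresholds()
#' @export
kinshipThresholds <- function(duplicateK = 0.45, firstDegreeK = 0.16,
                              poIbs0Max = 0.03, mendelMaxRate = 0.05) {
    new("KinshipThresholds", duplicateK = duplicateK,
        firstDegreeK = firstDegreeK, poIbs0Max = poIbs0Max,
        mendelMaxRate = mendelMaxRate)
}

setMethod("show", "KinshipThresholds", function(object) {
    cat(sprintf(paste0("KinshipThresholds: duplicate k > %.3g; first-degree",
                       " k >= %.3g;\n  PO if IBS0 <= %.3g; Mendelian rate < %.3g\n"),
                object@duplicateK, object@firstDegreeK, object@poIbs0Max,
                object@mendelMaxRate))
})

#' Define a crossing plan
#'
#' One row per planned family. `sire = "OPEN"` marks open pollination: the
#' actual sire is drawn uniformly from the eligible candidates at
#' simulation time (and recorded in the truth graph).
#'
#' @param dam,sire parent sample ids (`sire` may be `"OPEN"`).
#' @param n number of offspring per family.
#' @return `data.frame` with columns `dam`, `sire`, `n`.
#' @examples
#' crossPlan(dam = c("F01", "F02"), sire = c("F03", "OPEN"), n = c(10, 5))
#' @export
crossPlan <- function(dam, sire, n) {
    stopifnot(length(dam) == length(sire), length(dam) == length(n))
    if (any(dam == sire))
        stop("dam and sire must differ")
    if (any(n < 1)) stop("n must be positive")
    data.frame(dam = as.character(dam), sire = as.character(sire),
               n = as.integer(n), stringsAsFactors = FALSE)
}

## -- FilterReport accessors ------------------------------------------------

#' @describeIn FilterReport-class site ids passing all rules.
#' @param x a `FilterReport`.
#' @export
setMethod("passingSites", "FilterReport",
          function(x) x@results$site[x@results$pass])

#' @describeIn FilterReport-class first-fail removal counts per rule.
#' @export
setMethod("ruleCounts", "FilterReport", function(x) x@ruleCounts)

setMethod("show", "FilterReport", function(object) {
    cat(sprintf("FilterReport: %d sites in, %d pass (%.1f%%)\n",
                object@nInput, object@nPass,
                100 * object@nPass / max(1L, object@nInput)))
    rc <- object@ruleCounts[object@ruleCounts > 0]
    if (length(rc)) {
        cat("  removed (first failing rule):\n")
        for (r in names(rc)) cat(sprintf("    %-12s %d\n", r, rc[[r]]))
    }
})

## -- SelectionResult accessors ---------------------------------------------

#' @describeIn SelectionResult-class chosen sites, optionally one reason.
#' @param x a `SelectionResult`.
#' @param reason optional selection reason to restrict to.
#' @param ... unused.
#' @export
setMethod("selectedSites", "SelectionResult", function(x, reason = NULL, ...) {
    s <- x@sites
    if (!is.null(reason)) s <- s[s$reason %in% reason, , drop = FALSE]
    s$site
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d sites, %d probes\n",
                nrow(object@sites), object@totalProbeCost))
    for (r in names(object@totals))
        cat(sprintf("  %-12s %d\n", r, object@totals[[r]]))
    if (!is.na(object@targetTotal))
        cat(sprintf("  target %d%s\n", object@targetTotal,
                    if (object@shortfall > 0)
                        sprintf(" (SHORTFALL %d)", object@shortfall) else ""))
})

## -- PedigreeGraph accessors -----------------------------------------------

#' @describeIn PedigreeGraph-class edge table; `active = TRUE` restricts to
#'   edges currently part of the pedigree (excludes rejected records).
#' @param x a `PedigreeGraph`.
#' @param active logical.
#' @param ... unused.
#' @export
setMethod("pedigreeEdges", "PedigreeGraph", function(x, active = FALSE, ...) {
    e <- x@edges
    if (active) e <- e[e$provenance %in% .activeProv, , drop = FALSE]
    e
})

#' @describeIn PedigreeGraph-class named list of active parent ids per child.
#' @export
setMethod("activeParents", "PedigreeGraph", function(x, ...) {
    e <- pedigreeEdges(x, active = TRUE)
    split(e$parent, factor(e$child, levels = unique(e$child)))
})

setMethod("show", "PedigreeGraph", function(object) {
    e <- object@edges
    cat(sprintf("PedigreeGraph: %d nodes, %d edges\n",
                length(object@nodes), nrow(e)))
    if (nrow(e)) {
        tab <- table(e$provenance)
        for (p in names(tab)) cat(sprintf("  %-18s %d\n", p, tab[[p]]))
    }
    if (nrow(object@duplicates))
        cat(sprintf("  duplicates collapsed: %d\n", nrow(object@duplicates)))
    if (nrow(object@review))
        cat(sprintf("  flagged for review: %d\n", nrow(object@review)))
})

#' Export a pedigree graph as a dam/sire table
#'
#' Three-column convention: `id`, `dam`, `sire`, with `"0"` for unknown.
#' Active parents with role `unknown` fill the free slot (dam first).
#'
#' @param graph a [PedigreeGraph-class].
#' @return `data.frame` with columns `id`, `dam`, `sire`.
#' @export
asPedigreeTable <- function(graph) {
    stopifnot(is(graph, "PedigreeGraph"))
    e <- pedigreeEdges(graph, active = TRUE)
    out <- data.frame(id = graph@nodes, dam = "0", sire = "0",
                      stringsAsFactors = FALSE)
    rownames(out) <- out$id
    for (i in seq_len(nrow(e))) {
        ch <- e$child[i]
        role <- e$role[i]
        if (role == "unknown")
            role <- if (out[ch, "dam"] == "0") "dam" else "sire"
        if (out[ch, role] == "0") out[ch, role] <- e$parent[i]
    }
    rownames(out) <- NULL
    out
}
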