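## Central S4 classes. Validity methods enforce the data-model invariants;
## user code goes through the accessors in the module files, never slots.

#' GenotypeExperiment: sites x samples dosage container
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding one
#' assay `"dosage"`: an integer matrix (sites in rows, samples in columns)
#' coded 0/1/2 for homozygous-reference / heterozygous / homozygous-alternate
#' and `NA` for missing. `rowRanges` carries the scaffold and 1-based
#' position of each site; `rowData` carries the per-site VCF-style quality
#' annotations (`QUAL`, `MQ`, `DP`, `DP4_*`, `AC`, `AN`) and array-design
#' annotations (`effectClass`, flanking-variant flags, 16-mer multiplicity,
#' probe conversion scores) when available.
#'
#' @seealso [makeGenotypeExperiment()], [dosageMatrix()], [siteInfo()]
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        if (!is.numeric(d))
            msg <- c(msg, "dosage assay must be numeric")
        else {
            v <- d[!is.na(d)]
            if (length(v) && !all(v %in% c(0, 1, 2)))
                msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
        }
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "unique site ids (rownames) are required")
        if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
            msg <- c(msg, "unique sample ids (colnames) are required")
    }
    if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic founder panel
#'
#' Parameters of the synthetic-data generator. Defaults emulate the
#' discovery panel the package targets: 27 highly heterozygous founders
#' (expected heterozygosity about 0.26) genotyped at sites whose alternate
#' allele frequency is drawn from a low-skewed Beta distribution rescaled
#' to \[0.05, 0.5\].
#'
#' @slot nFounders number of founder individuals.
#' @slot nSites number of simulated variant sites.
#' @slot nScaffolds number of scaffolds sites are spread over.
#' @slot scaffoldLength scaffold length in bases.
#' @slot mafDistribution named list describing the allele-frequency draw:
#'   `list(type = "beta", shape1, shape2, min, max)`,
#'   `list(type = "uniform", min, max)` or `list(type = "fixed", value)`.
#' @slot targetHet expected founder heterozygosity implied by
#'   `mafDistribution` (documentation of the emulated panel, 0.26 default).
#' @slot genoErrorRate per-genotype probability of a symmetric code flip.
#' @slot missingRate per-genotype probability of a missing call.
#' @slot mislabelRate per-recorded-parent probability of a wrong id.
#' @slot seed integer RNG seed; identical configs give identical output.
#' @seealso [simConfig()], [simulateFounders()]
#' @export
setClass("SimConfig", slots = c(
    nFounders = "integer", nSites = "integer", nScaffolds = "integer",
    scaffoldLength = "numeric", mafDistribution = "list",
    targetHet = "numeric", genoErrorRate = "numeric",
    missingRate = "numeric", mislabelRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(nFounders = object@nFounders, nSites = object@nSites,
             nScaffolds = object@nScaffolds,
             scaffoldLength = object@scaffoldLength)
    if (any(is.na(cnt)) || any(cnt < 1))
        msg <- c(msg, "counts and lengths must be positive")
    rates <- c(object@genoErrorRate, object@missingRate, object@mislabelRate)
    if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    if (!is.character(object@mafDistribution$type) ||
        !object@mafDistribution$type %in% c("beta", "uniform", "fixed"))
        msg <- c(msg, "mafDistribution$type must be 'beta', 'uniform' or 'fixed'")
    if (!(object@targetHet > 0 && object@targetHet <= 1))
        msg <- c(msg, "targetHet must lie in (0, 1]")
    if (is.na(object@seed))
        msg <- c(msg, "seed must be a finite integer")
    if (length(msg)) msg else TRUE
})

#' Per-site report of the filtering stage
#'
#' @slot results `DataFrame` with one row per input site: `site`, `pass`,
#'   and `reasons` (comma-separated ids of every failed rule, `""` if none).
#' @slot ruleCounts named integer vector of removal counts under first-fail
#'   attribution (each removed site counted once, against the first failing
#'   rule in the documented rule order), so counts are disjoint.
#' @slot nInput,nPass input and surviving site counts.
#' @seealso [runSiteFilters()]
#' @export
setClass("FilterReport", slots = c(
    results = "DataFrame", ruleCounts = "integer",
    nInput = "integer", nPass = "integer"))

setValidity("FilterReport", function(object) {
    msg <- character()
    if (!all(c("site", "pass", "reasons") %in% colnames(object@results)))
        msg <- c(msg, "results needs columns site, pass, reasons")
    else {
        ok <- object@results$pass == (object@results$reasons == "")
        if (!all(ok)) msg <- c(msg, "pass must hold iff no rule failed")
        if (sum(object@results$pass) != object@nPass)
            msg <- c(msg, "nPass inconsistent with results")
    }
    if (length(msg)) msg else TRUE
})

#' Array panel selection result
#'
#' @slot sites `DataFrame` with one row per chosen site: `site`, `scaffold`,
#'   `pos`, `ref`, `alt`, `reason` (one of `HIGH_MOD_EFF`, `ALL_HOM`,
#'   `INFP`), `probeCost` (2 for A/T and C/G sites, else 1).
#' @slot totals named integer, chosen sites per selection reason.
#' @slot totalProbeCost total number of probes the panel consumes.
#' @slot targetTotal requested panel size (`NA` if unconstrained).
#' @slot shortfall sites short of `targetTotal` after trimming (0 when the
#'   target was met or no target was set); a positive value is an explicit
#'   unreachable-target report, never silent.
#' @seealso [assemblePanel()]
#' @export
setClass("SelectionResult", slots = c(
    sites = "DataFrame", totals = "integer", totalProbeCost = "integer",
    targetTotal = "integer", shortfall = "integer"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    s <- object@sites
    if (nrow(s)) {
        if (!all(s$reason %in% c("HIGH_MOD_EFF", "ALL_HOM", "INFP")))
            msg <- c(msg, "unknown selection reason")
        if (!all(s$probeCost %in% c(1L, 2L)))
            msg <- c(msg, "probeCost must be 1 or 2")
        if (anyDuplicated(s$site))
            msg <- c(msg, "selection reasons must be disjoint over sites")
    }
    if (sum(object@totals) != nrow(s))
        msg <- c(msg, "totals must sum to the number of chosen sites")
    if (nrow(s) && sum(s$probeCost) != object@totalProbeCost)
        msg <- c(msg, "totalProbeCost inconsistent with per-site costs")
    if (length(msg)) msg else TRUE
})

#' Relationship-calling thresholds
#'
#' Default values are the calibrated operating points used for a walnut
#' breeding-program collection: pairs with kinship k > 0.45 are genetically
#' identical; k >= 0.16 marks first-degree relatives; among first-degree
#' pairs IBS0 <= 0.03 separates parent-offspring from full sibs; a putative
#' parent (pair) is accepted when fewer than 5% of SNPs are Mendelian
#' inconsistent.
#'
#' @slot duplicateK kinship above which a pair is called duplicate (0.45).
#' @slot firstDegreeK kinship at/above which a pair is first-degree (0.16).
#' @slot poIbs0Max IBS0 at/below which a first-degree pair is
#'   parent-offspring rather than full-sib (0.03).
#' @slot mendelMaxRate maximum tolerated Mendelian inconsistency rate for
#'   accepting a trio or duo (0.05, strict `<`).
#' @seealso [kinshipThresholds()], [calibrateThresholds()], [classifyPair()]
#' @export
setClass("KinshipThresholds", slots = c(
    duplicateK = "numeric", firstDegreeK = "numeric",
    poIbs0Max = "numeric", mendelMaxRate = "numeric"))

setValidity("KinshipThresholds", function(object) {
    msg <- character()
    if (!(object@firstDegreeK > 0 && object@firstDegreeK < object@duplicateK &&
          object@duplicateK <= 0.5))
        msg <- c(msg, "need 0 < firstDegreeK < duplicateK <= 0.5")
    if (object@poIbs0Max < 0 || object@poIbs0Max > 1 ||
        object@mendelMaxRate < 0 || object@mendelMaxRate > 1)
        msg <- c(msg, "rates must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Directed pedigree graph with edge provenance
#'
#' Nodes are samples; each directed edge runs parent -> child with a role
#' (`dam`, `sire` or `unknown` when no record fixes the role) and a
#' provenance: `true` (simulation truth), `recorded_confirmed` (historical
#' record validated by the duo/trio Mendelian test), `recorded_rejected`
#' (record contradicted by the test; kept for audit, not an active edge),
#' `corrected` (replacement for a rejected record in the same parental
#' role), or `new` (relationship absent from the records). Duplicate
#' samples are collapsed to one representative before parent assignment;
#' pairs that could not be oriented or exceeded the two-parent limit are
#' kept in `review` rather than guessed.
#'
#' @slot nodes character vector of sample ids.
#' @slot edges `DataFrame`: `parent`, `child`, `role`, `provenance`, and
#'   supporting statistics (`k`, `ibs0`, `mendelRate`) where available.
#' @slot duplicates `DataFrame` mapping collapsed samples to their
#'   representative.
#' @slot review `DataFrame` of relationships flagged for manual review.
#' @seealso [assignParents()], [pedigreeEdges()]
#' @export
setClass("PedigreeGraph", slots = c(
    nodes = "character", edges = "DataFrame",
    duplicates = "DataFrame", review = "DataFrame"))

.activeProv <- c("true", "recorded_confirmed", "corrected", "new")

setValidity("PedigreeGraph", function(object) {
    msg <- character()
    e <- object@edges
    if (nrow(e)) {
        if (!all(c("parent", "child", "role", "provenance") %in% colnames(e)))
            msg <- c(msg, "edges needs parent, child, role, provenance")
        else {
            bad <- !e$provenance %in% c(.activeProv, "recorded", "recorded_rejected")
            if (any(bad)) msg <- c(msg, "unknown edge provenance")
            act <- e[e$provenance %in% .activeProv, , drop = FALSE]
            if (nrow(act)) {
                if (any(table(act$child) > 2))
                    msg <- c(msg, "active in-degree must be <= 2")
                if (any(act$parent == act$child))
                    msg <- c(msg, "self-parentage is not allowed")
                if (.hasCycle(act$parent, act$child))
                    msg <- c(msg, "active pedigree edges must be acyclic")
            }
        }
    }
    if (length(msg)) msg else TRUE
})

## Kahn-style cycle detection on a parent -> child edge list.
.hasCycle <- function(parent, child) {
    nodes <- unique(c(parent, child))
    repeat {
        indeg <- table(factor(child, levels = nodes))
        src <- nodes[indeg == 0L]
        if (!length(src)) break
        keep <- !(parent %in% src)
        parent <- parent[keep]
        child <- child[keep]
        nodes <- setdiff(nodes, src)
        if (!length(nodes)) return(FALSE)
    }
    length(nodes) > 0L
}
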