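## Quality and array-candidate filtering of variant sites. Every rule is a
## named, auditable predicate on the per-site annotation table; thresholds
## are configurable and boundary semantics follow the printed comparators
## exactly (QUAL <= 60 fails, AC/AN = 0.05 passes, and so on).

#' Filter configuration
#'
#' Thresholds of the site filters with their standard defaults: a site
#' fails quality when QUAL <= 60, MQ <= 20, total depth < 200 or > 4580,
#' its strand support is one-sided (see `strandLiteral`), fewer than 75%
#' of its reads are high quality (`sum(DP4)/DP < 0.75`), or its alternate
#' allele is very rare (`AC/AN < 0.05`) or very frequent (`> 0.95`). A
#' quality-passing site is dropped as an array candidate when it is an
#' indel, has more than two alleles, has predicted variants in both
#' 35-base flanks, a genome-wide 16-mer multiplicity above 300, or probe
#' conversion scores <= 0.6 on both strands.
#'
#' @param qualMax fail when `QUAL <=` this (60).
#' @param mqMax fail when `MQ <=` this (20).
#' @param dpMin,dpMax fail when `DP <` min (200) or `>` max (4580).
#' @param strandLiteral the strand rule has two readings. Default
#'   (`FALSE`): remove sites whose four DP4 components are *not* all > 1,
#'   i.e. keep only sites with both alleles seen more than once on both
#'   strands, the standard strand-balance practice. `TRUE` applies the
#'   literal converse (remove when all components > 1).
#' @param dp4RatioMin fail when `sum(DP4)/DP <` this (0.75).
#' @param freqMin,freqMax fail when `AC/AN <` min (0.05, strict) or
#'   `>` max (0.95, strict).
#' @param maxAlleles candidate rule: fail when `nAlleles >` this (2).
#' @param sixteenMerMax candidate rule: fail when count `>` this (300).
#' @param pConvertMin candidate rule: fail when both probe scores `<=`
#'   this (0.6).
#' @param strict abort on malformed records instead of counting them.
#' @return Named list of thresholds.
#' @export
filterConfig <- function(qualMax = 60, mqMax = 20, dpMin = 200, dpMax = 4580,
                         strandLiteral = FALSE, dp4RatioMin = 0.75,
                         freqMin = 0.05, freqMax = 0.95, maxAlleles = 2,
                         sixteenMerMax = 300, pConvertMin = 0.6,
                         strict = FALSE) {
    list(qualMax = qualMax, mqMax = mqMax, dpMin = dpMin, dpMax = dpMax,
         strandLiteral = strandLiteral, dp4RatioMin = dp4RatioMin,
         freqMin = freqMin, freqMax = freqMax, maxAlleles = maxAlleles,
         sixteenMerMax = sixteenMerMax, pConvertMin = pConvertMin,
         strict = strict)
}

.needCols <- function(si, cols, where) {
    miss <- setdiff(cols, colnames(si))
    if (length(miss))
        stop(where, ": missing site annotation field(s): ",
             paste(miss, collapse = ", "))
}

.siteTable <- function(x) {
    if (is(x, "GenotypeExperiment")) siteInfo(x)
    else as(x, "DataFrame")
}

## Each rule returns a logical fail vector; names fix the attribution order.
.qualityRules <- function(si, cfg) {
    dp4 <- cbind(si$DP4_RF, si$DP4_RR, si$DP4_AF, si$DP4_AR)
    allGt1 <- rowSums(dp4 > 1) == 4L
    frq <- ifelse(si$AN > 0, si$AC / si$AN, NA_real_)
    list(qual = si$QUAL <= cfg$qualMax,
         mq = si$MQ <= cfg$mqMax,
         depth = si$DP < cfg$dpMin | si$DP > cfg$dpMax,
         strand = if (cfg$strandLiteral) allGt1 else !allGt1,
         dp4_ratio = rowSums(dp4) / si$DP < cfg$dp4RatioMin,
         freq = is.na(frq) | frq < cfg$freqMin | frq > cfg$freqMax)
}

.candidateRules <- function(si, cfg) {
    list(indel = si$isIndel,
         multiallelic = si$nAlleles > cfg$maxAlleles,
         flank = si$flankVarLeft & si$flankVarRight,
         `16mer` = si$sixteenMerCount > cfg$sixteenMerMax,
         p_convert = si$pConvertFwd <= cfg$pConvertMin &
                     si$pConvertRev <= cfg$pConvertMin)
}

.applyRules <- function(rules) {
    failmat <- do.call(cbind, rules)
    reasons <- apply(failmat, 1L, function(f)
        paste(names(rules)[f], collapse = ","))
    list(pass = rowSums(failmat) == 0L, reasons = reasons, failmat = failmat)
}

#' Site quality filter
#'
#' Evaluates the six quality rules (see [filterConfig()]) on each site.
#'
#' @param x a [GenotypeExperiment-class] or per-site annotation table with
#'   columns `QUAL`, `MQ`, `DP`, `DP4_RF`/`DP4_RR`/`DP4_AF`/`DP4_AR`,
#'   `AC`, `AN`. A missing field is an error naming the field.
#' @param cfg a [filterConfig()] list.
#' @return `DataFrame` with `site`, `pass`, and `reasons` (comma-separated
#'   ids of all failed rules in rule order).
#' @examples
#' si <- S4Vectors::DataFrame(site = "s1", QUAL = 60, MQ = 30, DP = 1000,
#'     DP4_RF = 200, DP4_RR = 210, DP4_AF = 190, DP4_AR = 200,
#'     AC = 20, AN = 54)
#' qualityFilter(si)  # fails: QUAL <= 60 is inclusive
#' @export
qualityFilter <- function(x, cfg = filterConfig()) {
    si <- .siteTable(x)
    .needCols(si, c("QUAL", "MQ", "DP", "DP4_RF", "DP4_RR", "DP4_AF",
                    "DP4_AR", "AC", "AN"), "qualityFilter")
    r <- .applyRules(.qualityRules(si, cfg))
    DataFrame(site = if ("site" %in% colnames(si)) si$site
                     else rownames(si),
              pass = r$pass, reasons = r$reasons)
}

#' Array-candidate (probe convertibility) filter
#'
#' Evaluates the five array-design rules (see [filterConfig()]). Intended
#' for sites that already passed [qualityFilter()].
#'
#' @inheritParams qualityFilter
#' @return `DataFrame` with `site`, `pass`, `reasons`.
#' @export
arrayCandidateFilter <- function(x, cfg = filterConfig()) {
    si <- .siteTable(x)
    .needCols(si, c("isIndel", "nAlleles", "flankVarLeft", "flankVarRight",
                    "sixteenMerCount", "pConvertFwd", "pConvertRev"),
              "arrayCandidateFilter")
    r <- .applyRules(.candidateRules(si, cfg))
    DataFrame(site = if ("site" %in% colnames(si)) si$site
                     else rownames(si),
              pass = r$pass, reasons = r$reasons)
}

#' Run the full site-filtering stage
#'
#' Applies the quality rules, then the array-candidate rules, in the fixed
#' documented order. The report details *every* failed rule per site; the
#' per-rule summary counts attribute each removed site to its first
#' failing rule, so counts are disjoint and sum to the number removed.
#'
#' @param x a [GenotypeExperiment-class] with annotated sites.
#' @param cfg a [filterConfig()] list.
#' @return A list: `survivors` (the subset [GenotypeExperiment-class])
#'   and `report` (a [FilterReport-class]).
#' @examples
#' ge <- annotateSites(simulateFounders(simConfig(nSites = 300, seed = 3)))
#' res <- runSiteFilters(ge)
#' res$report
#' @export
runSiteFilters <- function(x, cfg = filterConfig()) {
    stopifnot(is(x, "GenotypeExperiment"))
    si <- siteInfo(x)
    if (nrow(si) == 0L) {
        rep <- new("FilterReport",
                   results = DataFrame(site = character(), pass = logical(),
                                       reasons = character()),
                   ruleCounts = setNames(integer(0), character(0)),
                   nInput = 0L, nPass = 0L)
        return(list(survivors = x, report = rep))
    }
    .needCols(si, c("QUAL", "MQ", "DP", "DP4_RF", "DP4_RR", "DP4_AF",
                    "DP4_AR", "AC", "AN", "isIndel", "nAlleles",
                    "flankVarLeft", "flankVarRight", "sixteenMerCount",
                    "pConvertFwd", "pConvertRev"), "runSiteFilters")
    rules <- c(.qualityRules(si, cfg), .candidateRules(si, cfg))
    bad <- Reduce(`|`, lapply(rules, is.na))
    if (any(bad)) {
        if (cfg$strict)
            stop("malformed annotation at site(s): ",
                 paste(head(si$site[bad], 5), collapse = ", "))
        rules <- lapply(rules, function(f) { f[is.na(f)] <- TRUE; f })
        rules$malformed <- bad
    }
    r <- .applyRules(rules)
    firstFail <- apply(r$failmat, 1L, function(f)
        if (any(f)) names(rules)[which(f)[1L]] else NA_character_)
    counts <- table(factor(firstFail, levels = names(rules)))
    report <- new("FilterReport",
                  results = DataFrame(site = si$site, pass = r$pass,
                                      reasons = r$reasons),
                  ruleCounts = setNames(as.integer(counts), names(counts)),
                  nInput = nrow(si), nPass = sum(r$pass))
    list(survivors = x[r$pass, ], report = report)
}

#' Write a filter report to disk
#'
#' Per-site detail as TSV and the per-rule summary as JSON.
#'
#' @param report a [FilterReport-class].
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
writeFilterReport <- function(report, tsv = NULL, json = NULL) {
    stopifnot(is(report, "FilterReport"))
    if (!is.null(tsv))
        write.table(as.data.frame(report@results), tsv, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    if (!is.null(json))
        jsonlite::write_json(
            list(nInput = report@nInput, nPass = report@nPass,
                 removedByRule = as.list(report@ruleCounts)),
            json, auto_unbox = TRUE, pretty = TRUE)
    invisible(report)
}
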