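## End-to-end driver: simulate -> annotate -> filter -> design ->
## relatedness -> pedigree -> diversity, with machine-readable reports.
## Also the arithmetic helpers for published classification-count tables.

#' Summarize a SNP classification count table
#'
#' Takes a table of SNP counts (selection modes in rows, genotyping
#' quality classes in columns, e.g. the bundled
#' `axiom_700k_category_counts.tsv`) and recomputes the per-class totals,
#' the grand total, and each class's percentage of the panel.
#'
#' @param counts numeric matrix or `data.frame` of counts (rows =
#'   selection modes, columns = quality classes).
#' @return A list: `classTotals`, `modeTotals`, `grandTotal`,
#'   `classPercent` (one decimal place, as conventionally printed).
#' @examples
#' tab <- read.delim(system.file("extdata", "axiom_700k_category_counts.tsv",
#'                               package = "snpkin"), row.names = 1)
#' summarizeClassCounts(tab)$classPercent["PHR"]
#' @export
summarizeClassCounts <- function(counts) {
    m <- as.matrix(counts)
    stopifnot(is.numeric(m))
    classTotals <- colSums(m)
    grand <- sum(m)
    list(classTotals = classTotals, modeTotals = rowSums(m),
         grandTotal = grand,
         classPercent = round(100 * classTotals / grand, 1))
}

#' Simulate a complete study data set
#'
#' Convenience wrapper tying the synthetic-data operations together:
#' founder panel, site annotations, multi-generation crosses, genotyping
#' error/missingness, and a (possibly mislabeled) recorded pedigree.
#'
#' @param cfg a [SimConfig-class].
#' @param plan a [crossPlan()]; by default 8 full-sib families of 12 plus
#'   one open-pollinated family of 6, crossed among the founders.
#' @return A list: `founders`, `genotypes` (error-injected, annotated),
#'   `truthGenotypes`, `truth` (the true [PedigreeGraph-class]),
#'   `recorded` (the corrupted pedigree table), `mislabeled`,
#'   `generation`, `errorMask`, `missingMask`.
#' @export
simulateStudy <- function(cfg = simConfig(), plan = NULL) {
    founders <- simulateFounders(cfg)
    founders <- annotateSites(founders, seed = cfg@seed + 1L)
    if (is.null(plan)) {
        dams <- sprintf("F%02d", seq(1, 16, by = 2))
        sires <- sprintf("F%02d", seq(2, 16, by = 2))
        plan <- crossPlan(dam = c(dams, "F17"),
                          sire = c(sires, rep("OPEN", 1)),
                          n = c(rep(12, 8), 6))
    }
    sim <- simulatePedigree(founders, plan, seed = cfg@seed + 2L)
    err <- injectErrors(sim$genotypes, cfg@genoErrorRate, cfg@missingRate,
                        seed = cfg@seed + 3L)
    rec <- corruptRecords(sim$pedigree, cfg@mislabelRate,
                          seed = cfg@seed + 4L,
                          candidates = colnames(founders))
    list(founders = founders, genotypes = err$genotypes,
         truthGenotypes = sim$genotypes, truth = sim$pedigree,
         recorded = rec$pedigree, mislabeled = rec$mislabeled,
         generation = sim$generation, errorMask = err$errorMask,
         missingMask = err$missingMask)
}

#' Run the full pipeline on simulated data
#'
#' Stages, in order: synthetic study generation, site filtering, panel
#' design, sample QC, pairwise relatedness, threshold calibration,
#' pedigree reconstruction, Mendelian error counting and diversity
#' statistics. Every stage's outputs and all effective thresholds (plus
#' the seed) land in `outDir` as TSV/VCF plus a JSON run report, so a
#' fixed configuration reproduces byte-identical reports.
#'
#' @param cfg a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param plan optional [crossPlan()].
#' @param filterCfg a [filterConfig()].
#' @param targetTotal optional panel-size target for [assemblePanel()].
#' @return Invisibly, a list with all intermediate objects and the report.
#' @export
runPipeline <- function(cfg = simConfig(), outDir, plan = NULL,
                        filterCfg = filterConfig(), targetTotal = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    study <- simulateStudy(cfg, plan)
    writeGenotypeVcf(study$founders, file.path(outDir, "founders.vcf"))

    filt <- runSiteFilters(study$founders, filterCfg)
    writeFilterReport(filt$report, tsv = file.path(outDir, "filter.tsv"),
                      json = file.path(outDir, "filter.json"))

    eff <- selectEffectSnps(filt$survivors)
    hom <- selectAllHom(filt$survivors)
    tag <- selectTagSnps(filt$survivors)
    panel <- assemblePanel(eff, hom, tag, filt$survivors,
                           targetTotal = targetTotal)
    writeSelectionResult(panel, file.path(outDir, "panel.tsv"))

    qc <- sampleQC(study$genotypes)
    pairs <- relatednessMatrix(qc$genotypes)
    write.table(pairs, file.path(outDir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    truthTab <- asPedigreeTable(study$truth)
    known <- do.call(rbind, lapply(seq_len(nrow(truthTab)), function(i) {
        ps <- c(truthTab$dam[i], truthTab$sire[i])
        ps <- ps[ps != "0"]
        if (!length(ps)) return(NULL)
        data.frame(i = ps, j = truthTab$id[i], relation = "PO")
    }))
    cal <- if (!is.null(known))
        calibrateThresholds(pairs, known)
    else list(thresholds = kinshipThresholds(), report = list())
    graph <- assignParents(qc$genotypes, pairs, recorded = study$recorded,
                           th = cal$thresholds,
                           generation = study$generation)
    writePedigreeTable(graph, file.path(outDir, "pedigree.tsv"))
    write.table(as.data.frame(pedigreeEdges(graph)),
                file.path(outDir, "pedigree_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    mendel <- countMendelianErrors(qc$genotypes, graph)
    stats <- snpStats(qc$genotypes)
    tree <- upgmaTree(ibsDistance(study$founders))
    ape::write.tree(tree, file.path(outDir, "founders_upgma.nwk"))

    report <- list(
        seed = cfg@seed,
        thresholds = list(
            filter = filterCfg[setdiff(names(filterCfg), "strict")],
            duplicateK = cal$thresholds@duplicateK,
            firstDegreeK = cal$thresholds@firstDegreeK,
            poIbs0Max = cal$thresholds@poIbs0Max,
            mendelMaxRate = cal$thresholds@mendelMaxRate),
        nSitesIn = filt$report@nInput,
        nSitesPass = filt$report@nPass,
        panel = as.list(panel@totals),
        panelProbes = panel@totalProbeCost,
        nSamplesQcPass = ncol(qc$genotypes),
        nPairs = nrow(pairs),
        nSitesKinship = attr(pairs, "nSitesUsed"),
        pedigree = as.list(table(pedigreeEdges(graph)$provenance)),
        meanMaf = unname(stats$means["maf"]),
        meanHet = unname(stats$means["het"]),
        meanMissing = unname(stats$means["missingRate"]))
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(study = study, filter = filt, panel = panel, qc = qc,
                   pairs = pairs, thresholds = cal$thresholds,
                   graph = graph, mendelErrors = mendel, stats = stats,
                   tree = tree, report = report))
}
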