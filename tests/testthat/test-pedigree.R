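test_that("the trio rule matches the transmission-probability oracle", {
    ## exhaustive enumeration of all 27 dosage combinations
    for (p1 in 0:2) for (p2 in 0:2) for (ch in 0:2) {
        res <- mendelianInconsistency(ch, p1, p2)
        expect_identical(res$flags, transmissionProb(p1, p2, ch) == 0,
                         label = sprintf("p1=%d p2=%d ch=%d", p1, p2, ch))
    }
})

test_that("the duo rule flags opposite homozygotes only", {
    expect_identical(mendelianInconsistency(2, 0)$nErrors, 1L)
    expect_identical(mendelianInconsistency(0, 2)$nErrors, 1L)
    for (ch in 0:2)   # a heterozygous parent is consistent with any child
        expect_identical(mendelianInconsistency(ch, 1)$nErrors, 0L)
    ## rate over jointly typed sites, with missing excluded
    r <- mendelianInconsistency(c(0, 2, NA, 1), c(2, 2, 0, NA))
    expect_identical(r$nInformative, 2L)
    expect_equal(r$rate, 0.5)
    expect_error(mendelianInconsistency(c(NA, NA), c(0, 1)), "jointly")
})

test_that("error-free trios are Mendelian-clean; parents 0x0 with het child fail", {
    fo <- simulateFounders(simConfig(nSites = 2000, seed = 101))
    sim <- simulatePedigree(fo, crossPlan("F01", "F02", 3), seed = 102)
    d <- dosageMatrix(sim$genotypes)
    for (kid in c("X01_001", "X01_002", "X01_003"))
        expect_identical(
            mendelianInconsistency(d[, kid], d[, "F01"], d[, "F02"])$rate, 0)
    expect_true(mendelianInconsistency(1, 0, 0)$flags)
})

test_that("threshold calibration reproduces its defining statistics", {
    ## known PO IBS0 {0, 0.01, 0.03} -> ceiling 0.03;
    ## k vector whose 2.5th percentile is the second order statistic
    k <- c(0.10, 0.16, seq(0.17, 0.35, length.out = 39))
    pairs <- data.frame(i = sprintf("a%02d", seq_along(k)),
                        j = sprintf("b%02d", seq_along(k)),
                        kinship = k,
                        ibs0 = c(0, 0.01, 0.03, rep(0.05, 38)))
    known <- data.frame(i = pairs$i, j = pairs$j,
                        relation = c("PO", "PO", "PO", rep("FS", 38)))
    cal <- calibrateThresholds(pairs, known)
    expect_equal(cal$thresholds@firstDegreeK, 0.16)
    expect_equal(cal$thresholds@poIbs0Max, 0.03)
    expect_identical(cal$thresholds@duplicateK, 0.45)
    ## no known PO pairs: defaults plus a warning
    expect_warning(
        def <- calibrateThresholds(pairs,
                                   data.frame(i = "x", j = "y",
                                              relation = "HS")),
        "default")
    expect_identical(def$thresholds@firstDegreeK, 0.16)
})

test_that("error-free simulated parent-offspring pairs calibrate IBS0 to zero", {
    fo <- simulateFounders(simConfig(nSites = 3000, seed = 103))
    sim <- simulatePedigree(fo, crossPlan(c("F01", "F03"), c("F02", "F04"),
                                          c(4, 4)), seed = 104)
    pairs <- relatednessMatrix(sim$genotypes, prune = FALSE)
    te <- pedigreeEdges(sim$pedigree)
    known <- data.frame(i = te$parent, j = te$child, relation = "PO")
    cal <- calibrateThresholds(pairs, known)
    expect_identical(cal$thresholds@poIbs0Max, 0)
})

test_that("pair classification follows the threshold table", {
    th <- kinshipThresholds()
    expect_identical(classifyPair(0.48, 0.001, th), "DUPLICATE")
    expect_identical(classifyPair(0.25, 0.01, th), "PARENT_OFFSPRING")
    expect_identical(classifyPair(0.25, 0.05, th), "FULL_SIB")
    expect_identical(classifyPair(0.10, 0.01, th), "OTHER")
    ## boundaries: k = firstDegreeK is first degree; ibs0 = ceiling is PO
    expect_identical(classifyPair(0.16, 0.03, th), "PARENT_OFFSPRING")
    expect_identical(classifyPair(c(0.25, NA), c(0.01, 0.01), th)[2],
                     NA_character_)
})

test_that("generations derive from records and survive unknowns", {
    rec <- data.frame(id = c("A", "B", "C", "D"),
                      dam = c("0", "0", "A", "C"),
                      sire = c("0", "0", "B", "A"))
    gen <- pedigreeGenerations(rec)
    expect_identical(unname(gen[c("A", "B", "C", "D")]), c(0L, 0L, 1L, 2L))
})

test_that("a complete truthful pedigree reconstructs as all-confirmed", {
    fo <- simulateFounders(simConfig(nSites = 3000, seed = 105))
    plan <- crossPlan(sprintf("F%02d", c(1, 3, 5, 7, 9)),
                      sprintf("F%02d", c(2, 4, 6, 8, 10)), rep(6, 5))
    sim <- simulatePedigree(fo, plan, seed = 106)
    pairs <- relatednessMatrix(sim$genotypes, prune = FALSE)
    graph <- assignParents(sim$genotypes, pairs,
                           recorded = asPedigreeTable(sim$pedigree),
                           generation = sim$generation)
    e <- pedigreeEdges(graph)
    expect_identical(unique(e$provenance), "recorded_confirmed")
    te <- pedigreeEdges(sim$pedigree)
    expect_setequal(paste(e$parent, e$child), paste(te$parent, te$child))
    expect_identical(nrow(graph@review), 0L)
})

test_that("a mislabeled dam is rejected and the true dam recovered as corrected", {
    fo <- simulateFounders(simConfig(nSites = 4000, seed = 107))
    sim <- simulatePedigree(fo, crossPlan(c("F01", "F03"), c("F02", "F04"),
                                          c(6, 6)), seed = 108)
    rec <- asPedigreeTable(sim$pedigree)
    rec$dam[rec$id == "X01_001"] <- "F05"   # wrong, unrelated founder
    err <- injectErrors(sim$genotypes, 0.01, 0.002, seed = 109)
    pairs <- relatednessMatrix(err$genotypes, prune = FALSE)
    graph <- assignParents(err$genotypes, pairs, recorded = rec,
                           generation = sim$generation)
    e <- pedigreeEdges(graph)
    rej <- e[e$provenance == "recorded_rejected", ]
    expect_identical(paste(rej$parent, rej$child), "F05 X01_001")
    cor <- e[e$provenance == "corrected", ]
    expect_identical(paste(cor$parent, cor$child, cor$role),
                     "F01 X01_001 dam")
})

test_that("an unrecorded sire of an open-pollinated offspring surfaces as new", {
    fo <- simulateFounders(simConfig(nSites = 4000, seed = 110))
    sim <- simulatePedigree(fo, crossPlan("F01", "OPEN", 5), seed = 111)
    rec <- asPedigreeTable(sim$pedigree)
    trueSires <- setNames(rec$sire, rec$id)
    rec$sire[rec$sire != "0"] <- "0"        # records know only the dam
    pairs <- relatednessMatrix(sim$genotypes, prune = FALSE)
    graph <- assignParents(sim$genotypes, pairs, recorded = rec,
                           generation = sim$generation)
    e <- pedigreeEdges(graph)
    new <- e[e$provenance == "new", ]
    for (kid in unique(pedigreeEdges(sim$pedigree)$child))
        expect_identical(new$parent[new$child == kid], trueSires[[kid]])
    expect_identical(unique(new$role), "sire")
})

test_that("duplicates collapse to the highest-call-rate representative", {
    fo <- simulateFounders(simConfig(nSites = 3000, seed = 112))
    d <- dosageMatrix(fo)
    dupe <- d[, "F01"]; dupe[1:50] <- NA    # lower call rate than F01
    d2 <- cbind(d, F01dup = dupe)
    ge <- geFrom(d2, scaffold = as.character(seqnames(rowRanges(fo))),
                 pos = start(rowRanges(fo)))
    pairs <- relatednessMatrix(ge, prune = FALSE)
    graph <- assignParents(ge, pairs,
                           generation = setNames(rep(0L, ncol(d2)),
                                                 colnames(d2)))
    expect_identical(as.data.frame(graph@duplicates),
                     data.frame(sample = "F01dup", representative = "F01"))
    expect_false("F01dup" %in% graph@nodes)
})

test_that("per-site Mendelian error counts accumulate over families", {
    d <- rbind(s1 = c(dam = 0L, sire = 0L, k1 = 1L, k2 = 0L),
               s2 = c(0L, 2L, 1L, 1L),
               s3 = c(2L, 2L, 0L, 2L))
    ge <- geFrom(d)
    g <- new("PedigreeGraph", nodes = colnames(d),
             edges = S4Vectors::DataFrame(
                 parent = c("dam", "sire", "dam", "sire"),
                 child = c("k1", "k1", "k2", "k2"),
                 role = c("dam", "sire", "dam", "sire"),
                 provenance = "true"),
             duplicates = S4Vectors::DataFrame(),
             review = S4Vectors::DataFrame())
    cnt <- countMendelianErrors(ge, g)
    ## s1: k1 impossible (0x0 -> het), k2 fine; s3: k1 impossible (2x2 -> 0)
    expect_identical(as.integer(cnt), c(1L, 0L, 1L))
    expect_identical(attr(cnt, "nFamiliesTested"), 2L)
})
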