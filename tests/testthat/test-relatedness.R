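test_that("sample QC drops call rates below the threshold, strictly", {
    d <- matrix(0L, 100, 3, dimnames = list(NULL, c("good", "edge", "bad")))
    d[1:3, "edge"] <- NA       # exactly 0.97
    d[1:4, "bad"] <- NA        # 0.96
    ge <- geFrom(d)
    qc <- sampleQC(ge)
    expect_setequal(colnames(qc$genotypes), c("good", "edge"))
    expect_identical(qc$excluded$sample, "bad")
    ## seeded missingness: exclusion equals an independent recount
    set.seed(80)
    d2 <- matrix(sample(0:2, 4000, TRUE), 200, 20,
                 dimnames = list(NULL, paste0("s", 1:20)))
    d2[sample(length(d2), 60)] <- NA
    d2[1:10, 1] <- NA                  # guarantee one clear failure
    expected <- colnames(d2)[colSums(!is.na(d2)) / nrow(d2) < 0.97]
    qc2 <- sampleQC(geFrom(d2))
    expect_setequal(qc2$excluded$sample, expected)
    expect_error(sampleQC(geFrom(matrix(NA_integer_, 5, 2,
        dimnames = list(NULL, c("a", "b"))))), "call-rate")
})

test_that("LD pruning removes duplicated sites and keeps independent ones", {
    base <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 1L, 2L)
    d <- rbind(a = base, b = base,
               c = c(2L, 0L, 1L, 0L, 2L, 1L, 0L, 1L, 2L, 0L))
    ge <- geFrom(d, pos = c(100L, 500L, 900L))
    kept <- ldPrune(ge)
    expect_true("a" %in% kept)
    expect_false("b" %in% kept)
    ## retained set satisfies the bound exhaustively within the window
    ge2 <- geWithLd(40, 1, 30000, seed = 81)
    kept2 <- ldPrune(ge2)
    d2 <- dosageMatrix(ge2)[kept2, , drop = FALSE]
    pos2 <- start(rowRanges(ge2))[match(kept2, rownames(ge2))]
    for (i in seq_along(kept2)[-1]) for (j in seq_len(i - 1)) {
        if (abs(pos2[i] - pos2[j]) > 50000) next
        v <- ldR2(d2[i, ], d2[j, ])
        if (!is.na(v)) expect_lte(v, 0.25)
    }
})

test_that("pairwise counts match hand enumeration and exclude missing", {
    expect_identical(pairwiseCounts(c(0, 1, 2, 1), c(2, 1, 0, 1)),
                     c(nHetHet = 2, nOppHom = 2, nHetI = 2, nHetJ = 2,
                       nShared = 4))
    ## identical vectors with h heterozygotes
    g <- c(0, 1, 1, 2, 1, 0)
    cnt <- pairwiseCounts(g, g)
    expect_identical(unname(cnt["nOppHom"]), 0)
    expect_identical(unname(cnt["nHetHet"]), 3)
    ## missing entries drop out of every count
    cnt2 <- pairwiseCounts(c(0, NA, 2, 1), c(2, 1, NA, 1))
    expect_identical(unname(cnt2["nShared"]), 2)
    expect_identical(unname(cnt2["nOppHom"]), 1)
})

test_that("the robust kinship estimator hits its closed-form anchors", {
    g <- c(0, 1, 1, 2, 1, 0, 2, 1)
    expect_identical(kingKinship(pairwiseCounts(g, g)), 0.5)
    ## worked example: counts (2,2,2,2,4) -> (2-4)/4 + 1/2 - 4/8 = -0.5
    expect_identical(kingKinship(c(nHetHet = 2, nOppHom = 2, nHetI = 2,
                                   nHetJ = 2, nShared = 4)), -0.5)
    ## no heterozygotes in one sample: undefined, not a number
    expect_true(is.na(kingKinship(c(nHetHet = 0, nOppHom = 1, nHetI = 0,
                                    nHetJ = 3, nShared = 10))))
    expect_equal(ibs0(c(nHetHet = 2, nOppHom = 2, nHetI = 2, nHetJ = 2,
                        nShared = 4)), 0.5)
})

test_that("relatedness matrix is complete, symmetric-invariant and flags duplicates", {
    fo <- simulateFounders(simConfig(nSites = 2000, nFounders = 8, seed = 90))
    pairs <- relatednessMatrix(fo, prune = FALSE)
    expect_identical(nrow(pairs), as.integer(choose(8, 2)))
    ## permuting samples leaves every pair value unchanged
    perm <- fo[, sample(ncol(fo))]
    pairs2 <- relatednessMatrix(perm, prune = FALSE)
    key <- function(p) paste(pmin(p$i, p$j), pmax(p$i, p$j))
    m <- match(key(pairs), key(pairs2))
    expect_equal(pairs$kinship, pairs2$kinship[m])
    expect_equal(pairs$ibs0, pairs2$ibs0[m])
    ## an injected duplicate is the only pair above the duplicate bound
    dup <- cbind(dosageMatrix(fo), F01copy = dosageMatrix(fo)[, "F01"])
    pairs3 <- relatednessMatrix(geFrom(dup), prune = FALSE)
    hot <- pairs3[pairs3$kinship > 0.45, ]
    expect_identical(nrow(hot), 1L)
    expect_setequal(c(hot$i, hot$j), c("F01", "F01copy"))
})

test_that("prefilters drop high-missing and low-MAF sites before pairing", {
    set.seed(91)
    d <- matrix(rbinom(100 * 10, 2, 0.3), 100, 10,
                dimnames = list(paste0("s", 1:100), paste0("i", 1:10)))
    d[1, 1:3] <- NA                     # missing rate 0.3 > 0.2
    d[2, ] <- c(1L, rep(0L, 9))         # MAF 0.05... exactly -> kept
    d[3, ] <- rep(0L, 10)               # monomorphic -> dropped
    pairs <- relatednessMatrix(geFrom(d))
    used <- attr(pairs, "nSitesUsed")
    expect_true(used < 100)
    ge <- geFrom(d)
    missRate <- rowMeans(is.na(d))
    p <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    expect_identical(used,
                     length(ldPrune(ge[missRate <= 0.2 & maf >= 0.05, ])))
})

test_that("simulated first-degree pairs land on their expected kinship", {
    set.seed(92)
    ks <- replicate(10, {
        fo <- simulateFounders(simConfig(nSites = 4000, nFounders = 4,
                                         seed = sample.int(1e6, 1)))
        sim <- simulatePedigree(fo, crossPlan("F01", "F02", 2), seed = 93)
        d <- dosageMatrix(sim$genotypes)
        c(po = kingKinship(pairwiseCounts(d[, "F01"], d[, "X01_001"])),
          fs = kingKinship(pairwiseCounts(d[, "X01_001"], d[, "X01_002"])),
          un = kingKinship(pairwiseCounts(d[, "F03"], d[, "F04"])))
    })
    expect_lt(abs(mean(ks["po", ]) - 0.25), 0.03)
    expect_lt(abs(mean(ks["fs", ]) - 0.25), 0.03)
    expect_lt(abs(mean(ks["un", ])), 0.03)
})

test_that("genotype concordance agrees exactly with the injected error mask", {
    ge <- simulateFounders(simConfig(nSites = 3000, nFounders = 10, seed = 94))
    expect_equal(genotypeConcordance(ge, ge)$mean, 100)
    ## one flipped call among 3000
    d <- dosageMatrix(ge)
    d2 <- d; d2[5, 1] <- (d2[5, 1] + 1L) %% 3L
    one <- genotypeConcordance(ge, geFrom(d2, scaffold = as.character(
        seqnames(rowRanges(ge))), pos = start(rowRanges(ge))))
    expect_equal(one$perSample$concordance[1], 100 * (1 - 1 / 3000))
    ## error-injected copy: concordance equals 1 - flips/shared, from the mask
    err <- injectErrors(ge, 0.02, 0.001, seed = 95)
    conc <- genotypeConcordance(ge, err$genotypes)
    shared <- !is.na(dosageMatrix(ge)) & !is.na(dosageMatrix(err$genotypes))
    expected <- 100 * colSums(shared & !err$errorMask) / colSums(shared)
    expect_equal(conc$perSample$concordance, unname(expected))
    expect_error(genotypeConcordance(ge[1:5, ], ge[6:10, ]), "shared")
})
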