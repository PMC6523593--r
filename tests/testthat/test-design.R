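test_that("effect-class selection keeps HIGH and MODERATE only", {
    si <- S4Vectors::DataFrame(
        site = paste0("s", 1:5),
        effectClass = c("HIGH", "MODERATE", "LOW", "MODIFIER", "NONE"))
    expect_identical(selectEffectSnps(si), c("s1", "s2"))
    expect_identical(selectEffectSnps(si[0, ]), character(0))
})

test_that("ALL_HOM selection honours both wordings and the missing bound", {
    d <- rbind(allAlt3miss = c(rep(2L, 24), NA, NA, NA),
               allAlt4miss = c(rep(2L, 23), NA, NA, NA, NA),
               mixedHom = c(rep(0L, 13), rep(2L, 14)),
               oneHet = c(1L, rep(2L, 26)),
               allRef = rep(0L, 27))
    colnames(d) <- sprintf("F%02d", 1:27)
    expect_setequal(selectAllHom(d),
                    c("allAlt3miss", "mixedHom", "allRef"))
    expect_setequal(selectAllHom(d, mode = "alt_only"), "allAlt3miss")
    expect_setequal(selectAllHom(d, maxMissing = 2),
                    c("mixedHom", "allRef"))
})

test_that("ldR2 matches the direct Pearson formula", {
    expect_identical(ldR2(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
    expect_equal(ldR2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
    ## hand-computed: r = 1.6 / sqrt(2.8 * 1.2), r^2 = 16/21
    expect_equal(ldR2(c(0, 1, 2, 1, 0), c(0, 1, 1, 1, 0)), 16 / 21)
    ## no LD information
    expect_true(is.na(ldR2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
    expect_true(is.na(ldR2(c(0, NA, NA, 2), c(0, 1, 2, NA))))
})

test_that("windows tile each scaffold with the final partial window kept", {
    w <- makeWindows(c(scA = 25000))
    expect_identical(w$start, c(1, 10001, 20001))
    expect_identical(w$end, c(10000, 20000, 25000))
    expect_identical(w$focal, floor((w$start + w$end) / 2))
    expect_true(all(w$end - w$start + 1 <= 10000))
})

test_that("perfect LD within a window collapses to the top-MAF site", {
    base <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
    d <- rbind(a = base, b = base, c = base,
               d = c(0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L))  # independent-ish
    ge <- geFrom(d, pos = c(100L, 200L, 300L, 9000L))
    sel <- selectTagSnps(ge)
    expect_identical(sum(c("a", "b", "c") %in% sel), 1L)
    expect_identical(sel[1], "a")   # equal MAF: earliest position wins
})

test_that("tag selection drops uninformative sites before the LD step", {
    d <- rbind(allHet = rep(1L, 9),
               allHom = c(0L, 0L, 2L, 2L, 0L, 0L, 2L, 2L, 0L),
               manyMissing = c(0L, 1L, NA, NA, NA, NA, NA, NA, NA),
               ok = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L))
    ge <- geFrom(d)
    expect_identical(selectTagSnps(ge), "ok")
})

test_that("greedy tag sets are valid and maximal on random windows", {
    for (seed in 1:5) {
        ge <- geWithLd(60, 2, 30000, seed = 100 + seed)
        sel <- selectTagSnps(ge)
        d <- dosageMatrix(ge)
        scaf <- as.character(seqnames(rowRanges(ge)))
        pos <- start(rowRanges(ge))
        win <- paste(scaf, (pos - 1L) %/% 10000L, sep = ":")
        names(win) <- rownames(d)
        nMiss <- rowSums(is.na(d))
        nHet <- rowSums(d == 1L, na.rm = TRUE)
        eligible <- rownames(d)[nHet > 0 & nHet < ncol(d) - nMiss &
                                nMiss <= 6]
        r2 <- function(i, j) { v <- ldR2(d[i, ], d[j, ]); if (is.na(v)) 0 else v }
        for (w in unique(win)) {
            s <- intersect(sel, names(win)[win == w])
            e <- intersect(eligible, names(win)[win == w])
            if (length(s) > 1)
                for (a in seq_along(s)[-1]) for (b in seq_len(a - 1))
                    expect_lt(r2(s[a], s[b]), 0.81)
            for (drop in setdiff(e, s))   # maximality
                expect_true(any(vapply(s, r2, 0, j = drop) >= 0.81))
        }
    }
})

test_that("panel assembly books reasons, probes and trimming correctly", {
    set.seed(60)
    ge <- annotateSites(simulateFounders(simConfig(nSites = 400, seed = 61)),
                        seed = 62, failFractions = list())
    si <- siteInfo(ge)
    eff <- si$site[1:5]; hom <- si$site[6:8]; tag <- si$site[9:20]
    res <- assemblePanel(eff, hom, tag, ge)
    expect_identical(unname(res@totals),
                     c(5L, 3L, 12L))
    expect_identical(length(selectedSites(res)), 20L)
    ## A/T and C/G sites cost two probes each
    pair <- paste(pmin(si$ref[1:20], substr(si$alt[1:20], 1, 1)),
                  pmax(si$ref[1:20], substr(si$alt[1:20], 1, 1)))
    expect_identical(res@totalProbeCost,
                     20L + sum(pair %in% c("A T", "C G")))
    ## overlap: reason priority HIGH_MOD_EFF > ALL_HOM > INFP
    both <- assemblePanel(eff, c(eff[1], hom), c(eff[1], tag), ge)
    expect_identical(sum(both@totals), 20L)
    expect_true(eff[1] %in% selectedSites(both, reason = "HIGH_MOD_EFF"))
})

test_that("trimming to a target removes only focal-point sites", {
    for (seed in c(70, 71)) {
        ge <- annotateSites(simulateFounders(simConfig(nSites = 300,
                                                       seed = seed)),
                            seed = seed + 1, failFractions = list())
        si <- siteInfo(ge)
        set.seed(seed)
        eff <- sample(si$site, 10); rest <- setdiff(si$site, eff)
        hom <- sample(rest, 5); tag <- sample(setdiff(rest, hom), 60)
        res <- assemblePanel(eff, hom, tag, ge, targetTotal = 40)
        expect_identical(sum(res@totals), 40L)
        expect_true(all(eff %in% selectedSites(res)))
        expect_true(all(hom %in% selectedSites(res)))
        expect_identical(res@shortfall, 0L)
    }
    ## unreachable target is an explicit shortfall, not silence
    ge <- annotateSites(simulateFounders(simConfig(nSites = 30, seed = 72)),
                        seed = 73, failFractions = list())
    si <- siteInfo(ge)
    expect_warning(res <- assemblePanel(si$site[1:3], character(0),
                                        si$site[4:6], ge, targetTotal = 10),
                   "short")
    expect_identical(res@shortfall, 4L)
})
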