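test_that("per-site statistics match hand arithmetic and brute force", {
    d <- rbind(s1 = c(0L, 1L, 1L, 2L),
               s2 = c(0L, 0L, 0L, 0L),
               s3 = c(NA, NA, NA, NA),
               s4 = c(2L, NA, 1L, 0L))
    st <- snpStats(d)
    expect_equal(st$perSite$maf[1], 0.5)
    expect_equal(st$perSite$het[1], 0.5)
    expect_equal(st$perSite$maf[2], 0)     # monomorphic
    expect_equal(st$perSite$het[2], 0)
    expect_true(is.na(st$perSite$maf[3]))
    expect_identical(st$nUndefined, 1L)
    expect_equal(st$perSite$missingRate[4], 0.25)
    ## random fixture against an independent recount
    set.seed(120)
    d2 <- matrix(sample(c(0:2, NA), 600, TRUE, prob = c(.3, .3, .3, .1)),
                 60, 10, dimnames = list(paste0("x", 1:60), NULL))
    st2 <- snpStats(d2)
    brute <- t(apply(d2, 1, function(g) {
        g <- g[!is.na(g)]
        p <- sum(g) / (2 * length(g))
        c(min(p, 1 - p), mean(g == 1))
    }))
    expect_equal(st2$perSite$maf, unname(brute[, 1]))
    expect_equal(unname(st2$means["het"]),
                 mean(brute[, 2], na.rm = TRUE))
})

test_that("family fixation index hits its closed-form anchors", {
    ## every member heterozygous at every site: F_IS = 1 - 1/0.5 = -1
    allHet <- matrix(1L, 20, 6, dimnames = list(paste0("s", 1:20),
                                                paste0("i", 1:6)))
    fam <- setNames(rep("A", 6), colnames(allHet))
    expect_equal(fisPerFamily(allHet, fam)$fis, -1)
    ## exact Hardy-Weinberg proportions: F_IS = 0
    hwe <- matrix(rep(c(0L, 1L, 1L, 2L), each = 1, times = 8), nrow = 8,
                  byrow = TRUE, dimnames = list(paste0("s", 1:8),
                                                paste0("i", 1:4)))
    famH <- setNames(rep("H", 4), colnames(hwe))
    expect_equal(fisPerFamily(hwe, famH, minFamilySize = 4)$fis, 0)
    ## families below the size floor are skipped
    expect_identical(nrow(fisPerFamily(allHet, fam, minFamilySize = 7)), 0L)
})

test_that("a random-mating panel has near-zero fixation index", {
    ge <- simulateFounders(simConfig(nSites = 10000, nFounders = 30,
                                     seed = 121))
    fam <- setNames(rep("panel", 30), colnames(ge))
    res <- fisPerFamily(ge, fam)
    expect_lt(abs(res$fis), 0.02)
    ## and matches a direct evaluation of 1 - Ho/He
    d <- dosageMatrix(ge)
    p <- rowMeans(d) / 2
    poly <- p > 0 & p < 1
    ho <- mean(rowMeans(d[poly, ] == 1))
    he <- mean(2 * p[poly] * (1 - p[poly]))
    expect_equal(res$fis, 1 - ho / he)
})

test_that("robust sets keep only zero-Mendelian-error sites of their classes", {
    labels <- data.frame(site = paste0("s", 1:6),
                         class = c("PHR", "PHR", "NMH", "OTV", "ABvar",
                                   "Other"))
    err <- setNames(c(1L, 0L, 0L, 2L, 0L, 0L), labels$site)
    attr(err, "nFamiliesTested") <- 3L
    rs <- deriveRobustSets(labels, err)
    expect_identical(rs$robustPHR, "s2")
    expect_setequal(rs$robustNmhOtv, c("s3", "s5"))
    ## monotone: an extra trio adding errors can only shrink the sets
    err2 <- err; err2["s3"] <- 1L
    rs2 <- deriveRobustSets(labels, err2)
    expect_true(all(rs2$robustPHR %in% rs$robustPHR))
    expect_true(all(rs2$robustNmhOtv %in% rs$robustNmhOtv))
    ## vacuous condition: no families tested
    err0 <- setNames(integer(6), labels$site)
    attr(err0, "nFamiliesTested") <- 0L
    expect_warning(rs0 <- deriveRobustSets(labels, err0), "robust")
    expect_setequal(rs0$robustPHR, c("s1", "s2"))
})

test_that("PCA is normalised, reorder-stable and separates populations", {
    set.seed(122)
    nA <- 12; nB <- 12
    d <- cbind(matrix(rbinom(200 * nA, 2, 0.15), 200, nA),
               matrix(rbinom(200 * nB, 2, 0.85), 200, nB))
    dimnames(d) <- list(paste0("s", 1:200),
                        c(paste0("A", 1:nA), paste0("B", 1:nB)))
    pc <- snpPCA(d)
    expect_equal(sum(pc$varprop), 1)
    ## PC1 separates the two populations with positive silhouette
    lab <- rep(c(1, 2), c(nA, nB))
    sil <- cluster::silhouette(lab, stats::dist(pc$scores[, 1]))
    expect_gt(mean(sil[, "sil_width"]), 0)
    ## duplicated samples get identical coordinates
    d2 <- cbind(d, A1copy = d[, "A1"])
    pc2 <- snpPCA(d2)
    expect_equal(pc2$scores["A1", 1:3], pc2$scores["A1copy", 1:3],
                 ignore_attr = TRUE, tolerance = 1e-8)
    ## sample order only permutes the rows (up to sign)
    perm <- sample(ncol(d))
    pc3 <- snpPCA(d[, perm])
    expect_equal(abs(pc3$scores[colnames(d), 1]), abs(pc$scores[, 1]),
                 tolerance = 1e-8)
    expect_error(snpPCA(matrix(0L, 5, 3)), "polymorphic")
})

test_that("allele-sharing distance has its closed-form values", {
    d <- cbind(a = c(0L, 0L, 1L, 2L), b = c(0L, 0L, 1L, 2L),
               c = c(2L, 2L, 1L, 0L), e = c(1L, 1L, 1L, 1L))
    dist <- ibsDistance(d)
    expect_equal(unname(dist["a", "b"]), 0)        # identical
    expect_equal(unname(dist["a", "c"]), 0.75)     # 3 opposite + 1 match
    expect_equal(unname(dist["a", "e"]), 3 / 8)    # het vs hom = 1/2 each
    expect_true(isSymmetric(dist))
})

test_that("UPGMA joins by average linkage with deterministic ties", {
    d <- matrix(c(0, .2, .5, .2, 0, .5, .5, .5, 0), 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    tr <- upgmaTree(d)
    cop <- ape::cophenetic.phylo(tr)
    expect_equal(cop["x", "y"], 0.2)    # joined at height 0.1 each
    expect_equal(unname(cop["x", "z"]), 0.5)
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
    ## identical samples join first at distance zero
    g <- cbind(p = c(0L, 1L, 2L), q = c(0L, 1L, 2L), r = c(2L, 1L, 0L))
    tr2 <- upgmaTree(ibsDistance(g))
    expect_equal(ape::cophenetic.phylo(tr2)["p", "q"], 0)
})

test_that("UPGMA agrees with the average-linkage oracle on small matrices", {
    for (seed in 1:10) {
        set.seed(130 + seed)
        n <- sample(4:6, 1)
        m <- matrix(runif(n * n, 0.1, 1), n)
        m <- (m + t(m)) / 2; diag(m) <- 0
        dimnames(m) <- list(letters[1:n], letters[1:n])
        mine <- upgmaTree(m)
        oracle <- ape::as.phylo(stats::hclust(stats::as.dist(m),
                                              method = "average"))
        expect_equal(ape::cophenetic.phylo(mine)[letters[1:n], letters[1:n]],
                     ape::cophenetic.phylo(oracle)[letters[1:n], letters[1:n]],
                     tolerance = 1e-12)
        expect_true(ape::is.ultrametric(mine, tol = 1e-9))
    }
})
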