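## Shared fixture builders. Everything is generated in code at test time.

## tiny GenotypeExperiment from an explicit dosage matrix
geFrom <- function(d, scaffold = NULL, pos = NULL, ...) {
    d <- as.matrix(d)
    if (is.null(scaffold)) scaffold <- rep("sc1", nrow(d))
    if (is.null(pos)) pos <- seq_len(nrow(d)) * 100L
    makeGenotypeExperiment(d, scaffold = scaffold, pos = pos, ...)
}

## founder panel with LD seeded by copying neighbouring site rows (with a
## few flipped genotypes), so pruning routines have real correlation to act on
geWithLd <- function(nSites, nScaffolds, scaffoldLength, seed,
                     copyFraction = 0.4, nFlips = 2) {
    ge <- simulateFounders(simConfig(nSites = nSites, nScaffolds = nScaffolds,
                                     scaffoldLength = scaffoldLength,
                                     seed = seed))
    set.seed(seed + 1L)
    d <- dosageMatrix(ge)
    scaf <- as.character(seqnames(rowRanges(ge)))
    for (i in which(runif(nSites) < copyFraction)) {
        j <- i - 1L
        if (j < 1L || scaf[j] != scaf[i]) next
        row <- d[j, ]
        flip <- sample(length(row), nFlips)
        row[flip] <- (row[flip] + 1L) %% 3L
        d[i, ] <- row
    }
    assay(ge, "dosage") <- d
    ge
}

## independent transmission-probability oracle: P(child | dam, sire) by
## enumerating gametes; a combination is Mendelian-impossible iff P = 0
transmissionProb <- function(p1, p2, child) {
    g1 <- if (p1 == 1) c(0, 1) else p1 / 2
    g2 <- if (p2 == 1) c(0, 1) else p2 / 2
    tot <- 0
    for (a in g1) for (b in g2)
        tot <- tot + (a + b == child) / (length(g1) * length(g2))
    tot
}

## expected joint genotype distribution of two full sibs at allele freq p,
## by exhaustive enumeration over parental genotypes and gamete draws
sibJointDist <- function(p) {
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    joint <- matrix(0, 3, 3)
    for (gm in 0:2) for (gf in 0:2) {
        pg <- hw[gm + 1] * hw[gf + 1]
        pc <- vapply(0:2, function(ch) transmissionProb(gm, gf, ch), 0)
        joint <- joint + pg * outer(pc, pc)
    }
    joint
}
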