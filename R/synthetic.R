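## Synthetic founder panels, crosses, error processes and site annotations.
## Everything is driven by explicit seeds: an identical configuration gives
## bit-identical output, which the test suite relies on.

.drawMaf <- function(n, dist) {
    switch(dist$type,
           beta = dist$min + (dist$max - dist$min) *
               rbeta(n, dist$shape1, dist$shape2),
           uniform = runif(n, dist$min, dist$max),
           fixed = rep(dist$value, n),
           stop("unknown mafDistribution type: ", dist$type))
}

.randomAlleles <- function(n) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    list(ref = ref, alt = unname(alt))
}

#' Simulate a founder discovery panel
#'
#' Draws one alternate-allele frequency per site from
#' `cfg@mafDistribution`, then founder genotypes under Hardy-Weinberg
#' equilibrium at that frequency. Site positions are scattered uniformly
#' over `nScaffolds` scaffolds. The drawn ("true") frequency of every site
#' is recorded in `rowData(x)$trueAltFreq`, the generator's truth table.
#'
#' @param cfg a [SimConfig-class].
#' @return A [GenotypeExperiment-class]; founders are named `F01`, `F02`,
#'   ... and `siteInfo()` includes `ref`, `alt` and `trueAltFreq`.
#' @examples
#' ge <- simulateFounders(simConfig(nSites = 200, seed = 7))
#' mean(dosageMatrix(ge) == 1)  # close to the configured heterozygosity
#' @export
simulateFounders <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(cfg@seed)
    n <- cfg@nSites
    scafIdx <- sort(sample.int(cfg@nScaffolds, n, replace = TRUE))
    pos <- integer(n)
    for (s in unique(scafIdx)) {
        i <- scafIdx == s
        pos[i] <- sort(sample.int(cfg@scaffoldLength, sum(i)))
    }
    scaffold <- sprintf("scaffold%03d", scafIdx)
    p <- .drawMaf(n, cfg@mafDistribution)
    d <- matrix(rbinom(n * cfg@nFounders, 2L, rep(p, times = cfg@nFounders)),
                nrow = n)
    rownames(d) <- sprintf("S%06d", seq_len(n))
    colnames(d) <- sprintf("F%02d", seq_len(cfg@nFounders))
    al <- .randomAlleles(n)
    makeGenotypeExperiment(d, scaffold = scaffold, pos = pos,
                           ref = al$ref, alt = al$alt,
                           siteData = DataFrame(trueAltFreq = p))
}

## One Mendelian gamete per site from a parental dosage vector.
.gamete <- function(dos) {
    g <- dos / 2                      # 0 -> 0, 2 -> 1
    het <- which(!is.na(dos) & dos == 1L)
    g[het] <- rbinom(length(het), 1L, 0.5)
    g
}

#' Simulate offspring from a crossing plan
#'
#' Each offspring receives one Mendelian allele draw per parent per site
#' from the parents' (error-free) genotypes. Plan rows are processed in
#' order, so earlier offspring can be named as parents of later families
#' (multi-generation pedigrees). A `sire` of `"OPEN"` simulates open
#' pollination: the true sire of each such offspring is drawn uniformly
#' from `openSireCandidates` (all individuals present before the family,
#' minus the dam, by default) and recorded in the returned truth graph.
#'
#' @param founders a [GenotypeExperiment-class] of parental genotypes.
#' @param plan a [crossPlan()] table.
#' @param seed integer RNG seed.
#' @param openSireCandidates optional character vector of eligible sires
#'   for open-pollinated families.
#' @return A list: `genotypes` (founders plus offspring), `pedigree` (the
#'   truth [PedigreeGraph-class], edge provenance `"true"`), and
#'   `generation` (named integer; founders are generation 0).
#' @examples
#' fo <- simulateFounders(simConfig(nSites = 100, seed = 1))
#' sim <- simulatePedigree(fo, crossPlan("F01", "F02", 4), seed = 2)
#' pedigreeEdges(sim$pedigree)
#' @export
simulatePedigree <- function(founders, plan, seed = 1L,
                             openSireCandidates = NULL) {
    stopifnot(is(founders, "GenotypeExperiment"))
    set.seed(seed)
    G <- dosageMatrix(founders)
    gen <- setNames(integer(ncol(G)), colnames(G))
    edges <- list()
    for (f in seq_len(nrow(plan))) {
        dam <- plan$dam[f]
        sire <- plan$sire[f]
        if (!dam %in% colnames(G))
            stop("unknown dam id: ", dam)
        open <- identical(sire, "OPEN")
        if (!open && !sire %in% colnames(G))
            stop("unknown sire id: ", sire)
        nOff <- plan$n[f]
        cand <- if (open) {
            oc <- if (is.null(openSireCandidates))
                setdiff(colnames(G), dam) else openSireCandidates
            if (!length(oc)) stop("no eligible open-pollination sires")
            oc
        }
        kidIds <- sprintf("X%02d_%03d", f, seq_len(nOff))
        kids <- matrix(NA_integer_, nrow(G), nOff,
                       dimnames = list(rownames(G), kidIds))
        sires <- if (open) sample(cand, nOff, replace = TRUE)
                 else rep(sire, nOff)
        for (k in seq_len(nOff)) {
            kids[, k] <- .gamete(G[, dam]) + .gamete(G[, sires[k]])
            edges[[length(edges) + 1L]] <- data.frame(
                parent = c(dam, sires[k]), child = kidIds[k],
                role = c("dam", "sire"), stringsAsFactors = FALSE)
        }
        gen[kidIds] <- pmax(gen[dam], max(gen[sires])) + 1L
        G <- cbind(G, kids)
    }
    e <- do.call(rbind, edges)
    graph <- new("PedigreeGraph", nodes = colnames(G),
                 edges = DataFrame(parent = e$parent, child = e$child,
                                   role = e$role, provenance = "true"),
                 duplicates = DataFrame(), review = DataFrame())
    ge <- makeGenotypeExperiment(G,
        scaffold = as.character(seqnames(rowRanges(founders))),
        pos = start(rowRanges(founders)), siteData = rowData(founders))
    list(genotypes = ge, pedigree = graph, generation = gen)
}

#' Inject genotyping error and missingness
#'
#' Every genotype is independently flipped to one of the two other dosage
#' codes with probability `genoErrorRate` (a symmetric error model that
#' produces both false heterozygotes and false homozygotes), then set
#' missing with probability `missingRate`. The two Boolean masks are
#' returned so tests can condition on the truth.
#'
#' @param x a [GenotypeExperiment-class] or dosage matrix.
#' @param genoErrorRate,missingRate per-genotype probabilities.
#' @param seed integer RNG seed.
#' @return A list: `genotypes` (same class as `x`), `errorMask`,
#'   `missingMask` (logical matrices).
#' @export
injectErrors <- function(x, genoErrorRate = 0.01, missingRate = 0.003,
                         seed = 1L) {
    stopifnot(genoErrorRate >= 0, genoErrorRate <= 1,
              missingRate >= 0, missingRate <= 1)
    set.seed(seed)
    d <- if (is(x, "GenotypeExperiment")) dosageMatrix(x) else as.matrix(x)
    errorMask <- matrix(runif(length(d)) < genoErrorRate, nrow(d),
                        dimnames = dimnames(d)) & !is.na(d)
    i <- which(errorMask)
    if (length(i))                      # uniform flip to a different code
        d[i] <- (d[i] + sample(1:2, length(i), replace = TRUE)) %% 3L
    missingMask <- matrix(runif(length(d)) < missingRate, nrow(d),
                          dimnames = dimnames(d))
    d[missingMask] <- NA_integer_
    out <- if (is(x, "GenotypeExperiment")) {
        y <- x
        assay(y, "dosage") <- d
        y
    } else d
    list(genotypes = out, errorMask = errorMask, missingMask = missingMask)
}

#' Corrupt a recorded pedigree with mislabeled parents
#'
#' Emulates mislabeling during sample collection or propagation: each
#' recorded (non-unknown) parent entry is independently replaced by a
#' wrong id with probability `mislabelRate`.
#'
#' @param truth a truth [PedigreeGraph-class] (e.g. from
#'   [simulatePedigree()]).
#' @param mislabelRate probability per recorded parent entry.
#' @param seed integer RNG seed.
#' @param candidates ids the wrong entry is drawn from (default: all nodes).
#' @param roles which parent roles are exposed to mislabeling.
#' @return A list: `pedigree` (3-column `id`/`dam`/`sire` table, `"0"` for
#'   unknown) and `mislabeled` (one row per corrupted entry: `id`, `role`,
#'   `trueParent`, `recordedParent`).
#' @export
corruptRecords <- function(truth, mislabelRate = 0.02, seed = 1L,
                           candidates = NULL, roles = c("dam", "sire")) {
    stopifnot(mislabelRate >= 0, mislabelRate <= 1)
    set.seed(seed)
    ped <- asPedigreeTable(truth)
    if (is.null(candidates)) candidates <- truth@nodes
    swapped <- list()
    for (role in roles) {
        known <- which(ped[[role]] != "0")
        hit <- known[runif(length(known)) < mislabelRate]
        for (i in hit) {
            pool <- setdiff(candidates,
                            c(ped$dam[i], ped$sire[i], ped$id[i]))
            wrong <- sample(pool, 1L)
            swapped[[length(swapped) + 1L]] <- data.frame(
                id = ped$id[i], role = role, trueParent = ped[[role]][i],
                recordedParent = wrong, stringsAsFactors = FALSE)
            ped[[role]][i] <- wrong
        }
    }
    mis <- if (length(swapped)) do.call(rbind, swapped)
           else data.frame(id = character(), role = character(),
                           trueParent = character(),
                           recordedParent = character())
    list(pedigree = ped, mislabeled = mis)
}

#' Generate VCF-style site annotations with seeded filter failures
#'
#' Fills `rowData` with the quality and array-design annotations the
#' filtering stage consumes. `AC`/`AN` are computed from the genotypes in
#' `x` (so the frequency rule's outcome is emergent, not seeded); every
#' other predicate gets a configurable fraction of sites seeded to fail
#' it. Truth labels `fail_*` record, per site, the realized outcome of
#' each predicate at the default thresholds, evaluated directly on the
#' generated values.
#'
#' @param x a [GenotypeExperiment-class] (typically the founder panel).
#' @param seed integer RNG seed.
#' @param failFractions named list of per-rule seeded failure fractions;
#'   names among `qual`, `mq`, `depth`, `dp4_ratio`, `strand`, `indel`,
#'   `multiallelic`, `flank`, `sixteen_mer`, `p_convert`.
#' @return `x` with annotation and `fail_*` truth columns in `rowData`.
#' @export
annotateSites <- function(x, seed = 1L,
                          failFractions = list(qual = 0.05, mq = 0.03,
                                               depth = 0.05,
                                               dp4_ratio = 0.04,
                                               strand = 0.04, indel = 0.02,
                                               multiallelic = 0.02,
                                               flank = 0.04,
                                               sixteen_mer = 0.04,
                                               p_convert = 0.04)) {
    stopifnot(is(x, "GenotypeExperiment"))
    set.seed(seed)
    n <- nrow(x)
    d <- dosageMatrix(x)
    ff <- function(nm) {
        fr <- failFractions[[nm]]
        if (is.null(fr)) fr <- 0
        runif(n) < fr
    }
    sQual <- ff("qual"); sMq <- ff("mq"); sDepth <- ff("depth")
    sRatio <- ff("dp4_ratio"); sStrand <- ff("strand")
    sIndel <- ff("indel"); sMulti <- ff("multiallelic")
    sFlank <- ff("flank"); sKmer <- ff("sixteen_mer"); sPcon <- ff("p_convert")

    QUAL <- ifelse(sQual, runif(n, 1, 60), runif(n, 61, 999))
    MQ <- ifelse(sMq, runif(n, 0, 20), runif(n, 21, 60))
    lowHigh <- runif(n) < 0.5
    DP <- round(ifelse(sDepth,
                       ifelse(lowHigh, runif(n, 50, 199), runif(n, 4581, 9000)),
                       runif(n, 300, 4000)))
    ratio <- ifelse(sRatio, runif(n, 0.40, 0.745), runif(n, 0.80, 0.99))
    hq <- pmax(floor(DP * ratio), 8L)

    AN <- 2L * rowSums(!is.na(d))      # per site: 2 x non-missing samples
    AC <- as.integer(rowSums(d, na.rm = TRUE))
    altFrac <- ifelse(AN > 0, AC / AN, 0.5)

    ## DP4: base 2 per component guarantees both alleles on both strands,
    ## the remainder is split ref/alt then fwd/rev binomially.
    rest <- hq - 8L
    altHq <- rbinom(n, rest, pmin(pmax(altFrac, 0.01), 0.99))
    refHq <- rest - altHq
    rf <- 2L + rbinom(n, refHq, 0.5); rr <- 2L + refHq - (rf - 2L)
    af <- 2L + rbinom(n, altHq, 0.5); ar <- 2L + altHq - (af - 2L)
    dp4 <- cbind(rf, rr, af, ar)
    ## seeded strand failures: collapse one component to 0 or 1 reads,
    ## moving its excess onto the opposite strand (sum preserved)
    iStr <- which(sStrand)
    if (length(iStr)) {
        comp <- sample(1:4, length(iStr), replace = TRUE)
        keep <- sample(0:1, length(iStr), replace = TRUE)
        mate <- c(2L, 1L, 4L, 3L)[comp]
        old <- dp4[cbind(iStr, comp)]
        dp4[cbind(iStr, comp)] <- keep
        dp4[cbind(iStr, mate)] <- dp4[cbind(iStr, mate)] + old - keep
    }

    si <- siteInfo(x)
    ref <- if ("ref" %in% colnames(si)) si$ref
           else .randomAlleles(n)$ref
    alt <- if ("alt" %in% colnames(si)) si$alt
           else .randomAlleles(n)$alt
    if (any(sIndel)) {
        ext <- sample(c("A", "C", "G", "T"), sum(sIndel), replace = TRUE)
        ref[sIndel] <- paste0(ref[sIndel], ext)
    }
    nAlleles <- rep(2L, n)
    if (any(sMulti)) {
        i <- which(sMulti)
        third <- vapply(i, function(j)
            sample(setdiff(c("A", "C", "G", "T"),
                           c(substr(ref[j], 1, 1), alt[j])), 1L), "")
        alt[i] <- paste(alt[i], third, sep = ",")
        nAlleles[i] <- 3L
    }

    fl <- runif(n) < 0.15; fr2 <- runif(n) < 0.15
    both <- fl & fr2 & !sFlank
    dropLeft <- runif(n) < 0.5
    fl[both & dropLeft] <- FALSE
    fr2[both & !dropLeft] <- FALSE
    fl[sFlank] <- TRUE; fr2[sFlank] <- TRUE

    kmer <- ifelse(sKmer, round(runif(n, 301, 2000)), round(runif(n, 1, 300)))
    pf <- runif(n, 0.61, 1); pr <- runif(n, 0, 1)
    swap <- runif(n) < 0.5
    tmp <- pf[swap]; pf[swap] <- pr[swap]; pr[swap] <- tmp
    pf[sPcon] <- runif(sum(sPcon), 0, 0.6); pr[sPcon] <- runif(sum(sPcon), 0, 0.6)

    effectClass <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER", "NONE"),
                          n, replace = TRUE,
                          prob = c(0.01, 0.05, 0.06, 0.18, 0.70))

    rd <- rowData(x)
    rd$ref <- ref; rd$alt <- alt
    rd$QUAL <- QUAL; rd$MQ <- MQ; rd$DP <- as.integer(DP)
    rd$DP4_RF <- as.integer(dp4[, 1]); rd$DP4_RR <- as.integer(dp4[, 2])
    rd$DP4_AF <- as.integer(dp4[, 3]); rd$DP4_AR <- as.integer(dp4[, 4])
    rd$AC <- AC; rd$AN <- as.integer(AN)
    rd$isIndel <- sIndel; rd$nAlleles <- nAlleles
    rd$effectClass <- effectClass
    rd$flankVarLeft <- fl; rd$flankVarRight <- fr2
    rd$sixteenMerCount <- kmer
    rd$pConvertFwd <- pf; rd$pConvertRev <- pr
    ## realized truth labels, evaluated with the default comparators
    rd$fail_qual <- QUAL <= 60
    rd$fail_mq <- MQ <= 20
    rd$fail_depth <- DP < 200 | DP > 4580
    rd$fail_strand <- !(dp4[, 1] > 1 & dp4[, 2] > 1 & dp4[, 3] > 1 & dp4[, 4] > 1)
    rd$fail_dp4_ratio <- rowSums(dp4) / DP < 0.75
    rd$fail_freq <- ifelse(AN > 0, AC / AN < 0.05 | AC / AN > 0.95, TRUE)
    rd$fail_indel <- sIndel
    rd$fail_multiallelic <- nAlleles > 2
    rd$fail_flank <- fl & fr2
    rd$fail_16mer <- kmer > 300
    rd$fail_pconvert <- pf <= 0.6 & pr <= 0.6
    rowData(x) <- rd
    x
}
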