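Package: snpkin
Title: SNP Array Panel Design, Kinship-Based Pedigree Reconstruction and
    Genetic Diversity for Outcrossing Tree Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a high-density SNP genotyping array panel
    from a multi-sample variant call set and for validating it on a
    pedigreed germplasm collection. Implements auditable site quality and
    probe-convertibility filters, effect-class and fixed-allele selection,
    windowed focal-point/tagSNP selection under linkage-disequilibrium
    pruning, KING-robust pairwise kinship with IBS0-based discrimination of
    parent-offspring from full-sib pairs, Mendelian-inconsistency trio/duo
    validation and pedigree reconstruction, per-SNP and per-family diversity
    statistics (MAF, heterozygosity, fixation index), allele-frequency
    scaled principal component analysis and UPGMA clustering on
    allele-sharing distance. A synthetic-data module simulates founder
    panels, multi-generation crosses, genotyping error and record
    mislabeling so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
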