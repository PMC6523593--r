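# snpkin

SNP array panel design, kinship-based pedigree reconstruction and genetic
diversity statistics for outcrossing tree crops.

Breeding programs for long-lived, highly heterozygous trees (the package's
defaults target a Persian walnut setting) depend on two things this package
computes: a well-chosen genotyping array panel, selected from millions of
resequencing variants, and a *verified* pedigree, because decades of
controlled crosses accumulate mislabeled and unknown parentage that
silently corrupts breeding values. `snpkin` implements the full desk-side
pipeline: auditable site filtering, panel selection, pairwise relatedness,
Mendelian validation, pedigree correction, and diversity summaries — plus
a synthetic pedigree simulator so every stage is testable without any
external data.

## The methods at the core

* **Site filters.** Quality predicates on VCF annotations (fail when
  QUAL ≤ 60, MQ ≤ 20, DP < 200 or > 4580, one-sided strand support,
  sum(DP4)/DP < 0.75, AC/AN < 0.05 or > 0.95) followed by probe
  convertibility predicates (indels, >2 alleles, variants in both 35-base
  flanks, 16-mer multiplicity > 300, both probe conversion scores ≤ 0.6).
* **Panel selection.** Gene-effect sites (HIGH/MODERATE), fixed-allele
  sites (ALL_HOM, ≤ 3 missing), and focal-point tagSNPs: 10-kb windows,
  greedy selection by descending MAF under an LD ceiling of r² = 0.81,
  with A/T and C/G sites charged two probes.
* **KING-robust kinship.** For a sample pair over jointly typed sites,
  with N11 both-heterozygous, N02 opposite-homozygous and Ni, Nj the
  per-sample heterozygote counts:

  k = (N11 − 2·N02) / (2·min(Ni, Nj)) + 1/2 − (Ni + Nj) / (4·min(Ni, Nj)),
  IBS0 = N02 / Nshared

  computed after call-rate QC (< 0.97 excluded), missing-rate (> 0.2) and
  MAF (< 0.05) filters and 50-kb / r² ≤ 0.25 LD pruning.
* **Classification and reconstruction.** k > 0.45 → duplicate;
  k ≥ 0.16 → first degree, split into parent-offspring (IBS0 ≤ 0.03)
  versus full sibs (IBS0 > 0.03); recorded parents validated and new
  trios/duos accepted when < 5% of SNPs are Mendelian-inconsistent.
  Edges carry provenance: `recorded_confirmed`, `recorded_rejected`,
  `corrected`, `new`.
* **Diversity.** Per-SNP MAF/heterozygosity/missing rate, per-family
  F_IS = 1 − Ho/He, robust SNP sets (zero Mendelian errors over all
  accepted trios and duos), allele-frequency-scaled PCA, and UPGMA on
  allele-sharing distance with newick export.

See `vignettes/snpkin-methods.Rmd` for assumptions, parameter rationale
and limitations.

## Worked example

```r
library(snpkin)
cfg   <- simConfig(nSites = 5000, seed = 42)   # 27 founders, Het ~ 0.26
study <- simulateStudy(cfg)                    # crosses, 1% error, 2% mislabels

filt <- runSiteFilters(study$founders)
filt$report
#> FilterReport: 5000 sites in, 3033 pass (60.7%)
#>   removed (first failing rule):
#>     qual         242
#>     mq           129
#>     depth        238
#>     ...

panel <- assemblePanel(selectEffectSnps(filt$survivors),
                       selectAllHom(filt$survivors),
                       selectTagSnps(filt$survivors), filt$survivors)
panel
#> SelectionResult: 3033 sites, 4072 probes
#>   HIGH_MOD_EFF 185
#>   ALL_HOM      0
#>   INFP         2848

qc    <- sampleQC(study$genotypes)
pairs <- relatednessMatrix(qc$genotypes, prune = FALSE)
graph <- assignParents(qc$genotypes, pairs, recorded = study$recorded,
                       generation = study$generation)
graph
#> PedigreeGraph: 129 nodes, 209 edges
#>   corrected          5
#>   recorded_confirmed 199
#>   recorded_rejected  5
```

The five rejected edges are exactly the mislabeled parent records the
simulator injected; each is replaced by the true parent (`corrected`),
recovered from the kinship/IBS0 classification and confirmed by the trio
Mendelian test. The top of the pair table shows first-degree pairs at the
expected k ≈ 0.25:

```r
head(pairs[order(-pairs$kinship), c("i", "j", "kinship", "ibs0")], 3)
#>            i       j   kinship       ibs0
#> 3649 X05_004 X05_011 0.2467794 0.01110214
#> 3648 X05_003 X05_011 0.2445141 0.01413000
#> 4752 X06_009 X06_011 0.2444838 0.01228105
```

A thin command-line front end over the same functions lives at
`inst/scripts/snpkin-cli.R` (subcommands `simulate`, `filter`, `design`,
`relate`, `pedigree`, `diversity`, `pipeline`).

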