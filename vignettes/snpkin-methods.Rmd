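---
title: "snpkin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snpkin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(snpkin)
```

# Scope

`snpkin` reimplements, as tested R functions, the computational pipeline
used to design and validate a high-density SNP genotyping array for an
outcrossing, highly heterozygous tree crop (its defaults are tuned to a
walnut breeding-program setting): candidate-site filtering from a
multi-sample variant call set, panel selection, KING-robust pairwise
kinship with IBS0, Mendelian trio/duo validation, pedigree
reconstruction, and genotype diversity statistics. Because the original
resequencing and array genotype data are not redistributable, the package
ships a synthetic-data module that emulates the study conditions; every
stage is exercised end to end on simulated pedigrees.

# Data model

Genotypes are alternate-allele dosages (0 = homozygous reference, 1 =
heterozygous, 2 = homozygous alternate, `NA` missing) in a
`GenotypeExperiment`, a `RangedSummarizedExperiment` with sites in rows
(scaffold and 1-based position in `rowRanges`, per-site quality and
design annotations in `rowData`) and samples in columns. All coordinates
follow the VCF convention.

# Site filtering

The quality filter removes a site when any of the following holds (all
thresholds configurable, defaults shown): `QUAL <= 60`; `MQ <= 20`; total
depth `DP < 200` or `> 4580`; one-sided strand support; fewer than 75% of
reads high-quality (`sum(DP4)/DP < 0.75`); alternate-allele frequency
`AC/AN < 0.05` or `> 0.95`. Boundary semantics follow the printed
comparators exactly: `QUAL = 60` fails (inclusive), `AC/AN = 0.05` passes
(strict).

**Strand rule.** The published phrasing of the strand-bias condition
("all DP4[i] > 1") taken literally would *remove* sites with both alleles
well supported on both strands. We read the parenthetical as describing
the retained-site property and remove a site when its four DP4 components
are **not** all greater than 1 — the standard strand-balance practice.
The literal reading remains available via
`filterConfig(strandLiteral = TRUE)`; neither interpretation is silently
mixed with the other.

The array-candidate (probe convertibility) filter then removes indels,
sites with more than two alleles, sites with predicted variants in both
35-base flanks, sites whose flanking 16-mers occur more than 300 times
genome-wide, and sites with probe conversion scores at or below 0.6 on
both strands. Rule evaluation is fully vectorised; the per-site report
lists *every* failed rule, while summary counts attribute each removed
site to its first failing rule in the documented order so that counts are
disjoint.

# Panel selection

Three selection routes feed the panel:

* `HIGH_MOD_EFF` — sites with a predicted HIGH or MODERATE gene effect.
* `ALL_HOM` — sites fixed (all non-missing genotypes homozygous) in the
  discovery panel with at most three missing calls. The two published
  wordings of this rule differ; `mode = "either"` (either allele,
  `<= 3` missing) is the default and `mode = "alt_only"` (alternate
  homozygotes only) is available. Both comparators are configurable.
* `INFP` — focal-point/tagSNP selection: scaffolds are tiled into
  non-overlapping 10-kb windows from position 1 (final partial window
  kept; the focal point is the window midpoint — the tiling carries no
  free parameters). Within a window, all-heterozygous, all-homozygous
  and `> 6`-missing sites are discarded; remaining candidates are
  scanned in order of decreasing MAF (ties by ascending position) and
  accepted only if their r² with every already-accepted site is below
  0.81. A pair at exactly 0.81 counts as too correlated. The descending-
  MAF greedy order is our choice (the source pipeline does not state
  one): it maximises the informativeness of the retained tags and makes
  the procedure deterministic.

`assemblePanel()` unions the three sets with reason priority
`HIGH_MOD_EFF > ALL_HOM > INFP`, charges two probes to A/T and C/G sites
(which are retained despite the cost), and, if a panel-size target or
probe budget is exceeded, trims only INFP sites — round-robin across
windows, lowest-MAF first within a window — so that effect and fixed
sites are never sacrificed. An unreachable target yields an explicit
shortfall report. The quota rule (how the original design trimmed its
candidate list to the final panel size) is not published; round-robin
trimming is our declared convention.

# Relatedness

Before estimation: samples with call rate below 0.97 are excluded; sites
with missing rate above 0.2 or MAF below 0.05 are dropped; the remainder
is LD-pruned (position-ordered greedy within 50-kb sliding windows,
keeping a site only if r² <= 0.25 with every kept site in the window).
Window semantics (step, in-window order) are not published; stepping one
site in position order matches common pruning practice and is
deterministic.

For a pair over its jointly non-missing sites, with N11 both-het, N02
opposite-homozygote, and Ni, Nj per-sample het counts, the KING-robust
between-family estimator is

    k = (N11 - 2 N02) / (2 min(Ni, Nj)) + 1/2 - (Ni + Nj) / (4 min(Ni, Nj))

and IBS0 = N02 / N(shared). The named algorithm prints no formula in the
source pipeline; this is the estimator the cited KING method defines.
Identical genotypes give k = 0.5 exactly; expectations are 0.25 for
parent-offspring (PO) and full sibs (FS), 0.125 for half sibs, 0 for
unrelated pairs; IBS0 of an error-free PO pair is exactly 0. The IBS0
denominator is the jointly non-missing site count, and kinship and IBS0
are computed on the same pruned set. Pairs in which either sample has no
heterozygous site leave the estimator undefined; they are reported as
`NA`, never silently dropped. All-pairs computation uses four matrix
cross-products, so a thousand-sample collection is tractable.

# Pair classification and thresholds

`classifyPair()` maps (k, IBS0) deterministically: DUPLICATE if
k > 0.45; else PARENT_OFFSPRING if k >= 0.16 and IBS0 <= 0.03; FULL_SIB
if k >= 0.16 and IBS0 > 0.03; else OTHER. These defaults are the
operating point calibrated on a real breeding-program collection and are
the package's reference thresholds.

`calibrateThresholds()` recomputes the two data-driven values from
recorded relationships: the first-degree bound as the 2.5th percentile
(lower edge of the central 95% interval) of k over known PO and FS
pairs, and the PO IBS0 ceiling as the maximum IBS0 among known PO pairs.
Two properties are worth understanding:

* On an error-free simulation the calibrated IBS0 ceiling is exactly 0 —
  a true parent and offspring cannot be opposite homozygotes.
* The 2.5th-percentile rule *by construction* places about 2.5% of the
  calibration pairs below the bound. When the recorded relationships are
  clean, this caps PO recall near 97.5%; its practical value is
  robustness when a small fraction of records is wrong (the bad pairs
  occupy the trimmed tail). For this reason the reconstruction
  procedures default to the reference thresholds above, and calibration
  is an explicit, reportable step rather than an implicit one.

# Pedigree reconstruction

`assignParents()` proceeds: (1) duplicate pairs are collapsed first, the
highest-call-rate sample representing each group; (2) genotyped recorded
parents are validated — the pair must be classified PARENT_OFFSPRING
*and* pass the duo Mendelian test. The kinship gate matters: with a
low-MAF marker set an unrelated duo's opposite-homozygote rate can fall
under the 5% Mendelian cap, so the duo test alone cannot reject a wrong
record; (3) candidate parents are PO-classified partners from an earlier
generation — orientation of a PO pair is not decidable from k/IBS0, so
pairs without generation metadata go to a review list rather than being
guessed; (4) free slots are filled by the candidate trio with the lowest
Mendelian inconsistency rate below 0.05 (strict), else the best duo;
ties break by lower rate then lower IBS0. A candidate replacing a
rejected record in the same role is `corrected`, otherwise `new`.
Candidates passing the bound beyond the two-parent limit are flagged for
review, never dropped silently.

The duo rule flags opposite homozygotes; the trio rule flags child
genotypes impossible under biallelic transmission (parents 0x0 with
child 1 or 2; 0x1 with child 2; 0x2 with child 0 or 2; 1x2 with child 0;
2x2 with child 0 or 1), with the rate computed over sites where child
and all supplied parents are typed.

# Diversity statistics

Per-site MAF, observed heterozygosity and missing rate; unweighted set
means; per-family fixation index `F_IS = 1 - Ho/He` with `He = 2p(1-p)`
from family allele frequencies, averaged over the family's polymorphic
sites (the estimator is our declared choice; the source names only
"fixation index"). Robust SNP sets keep, per quality class, the sites
with zero Mendelian inconsistencies across all accepted trios and duos;
with no tested families the condition is vacuous and the function warns.

PCA centres dosages by 2p and scales by sqrt(2p(1-p)) — the conventional
SNP normalisation — with mean imputation of missing entries, then
eigendecomposes the sample covariance; variance proportions sum to one.
UPGMA operates on allele-sharing distance (1 − IBS, our choice of
genetic distance; configurable by supplying any distance matrix) with
size-weighted average linkage, merging at height d/2 so the tree is
ultrametric; nearest-pair ties break by the lexicographically smallest
cluster labels for determinism. The implementation is cross-checked in
the test suite against average-linkage `hclust` as an independent
oracle.

# The synthetic-data generator

`simulateFounders()` draws one alternate-allele frequency per site and
founder genotypes under Hardy-Weinberg at that frequency. The default
frequency law, Beta(0.6, 1.8) rescaled to [0.05, 0.5], was chosen once
so that expected founder heterozygosity is about 0.26 — the value
reported for the emulated 27-founder discovery panel — and is not a
tuning knob. `simulatePedigree()` transmits one Mendelian allele per
parent per site and records the truth graph; open-pollinated families
draw the sire uniformly from a configurable candidate list (the simplest
testable null; no pollen-cloud model is attempted). `injectErrors()`
applies a symmetric code-flip error (default 1%) and missingness
(default 0.3%); `corruptRecords()` mislabels recorded parent entries
(default 2%). The error and mislabel defaults are explicitly arbitrary —
the emulated study does not report its realised rates.

What the generator does *not* emulate: linkage (sites are independent,
i.e. the output behaves like an already LD-pruned marker set — LD-aware
routines are exercised on fixtures with seeded correlation), population
structure and admixture, batch effects, and the intensity-clustering
process that assigns array quality classes (class labels are inputs
here). Passing tests on simulated data therefore demonstrate
correctness of the algorithms under their stated models, not robustness
to every artefact of real array data.

Site annotations (`annotateSites()`) are generated directly rather than
derived from simulated sequence — the filters are predicates on
annotations, and no reference genome is in scope. A configurable
fraction of sites is seeded to fail each predicate; `AC`/`AN` are always
consistent with the simulated genotypes, so the frequency rule's outcome
is emergent. Truth labels record realised predicate outcomes.

# Problem sizes and numerical choices

The test suite and the acceptance script work at the study scale the
package targets: 27 founders, 10,000 unlinked sites, 100 replicates for
sampling distributions of kinship, and a 520-offspring multi-family
pedigree for reconstruction. Ultrametricity is asserted to 1e-9;
UPGMA tie detection uses a 1e-15 band; LD r² with fewer than two
complete pairs or zero variance is treated as "no information" (never
blocks a candidate, prunes nothing). Undefined kinship (no heterozygous
sites) and undefined pair distances raise explicit signals rather than
numbers.

# Known limitations

* PO orientation requires generation metadata; unoriented pairs are
  reported for review, not guessed.
* Dam and sire are genetically indistinguishable from autosomal dosages:
  a record listing the true sire in the dam column is rejected as a
  *role* error and the true dam recovered, but which slot each parent
  occupies follows the records, not the genetics.
* The duplicate-collapse representative (highest call rate) and the
  trio tie-breaks are conventions; the emulated study does not state
  its rules.
* Likelihood-based parentage, IBD-segment methods, imputation, and the
  within-family KING variant are out of scope.
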