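# Bundled data

- `axiom_700k_category_counts.tsv` — published classification counts for a
  700K walnut SNP genotyping array: number of SNPs per Axiom genotyping
  quality class (columns) and selection mode (rows), observed after
  genotyping a 1284-tree breeding-program collection. Input for the
  table-arithmetic helpers (`summarizeClassCounts`).
- `axiom_700k_robust_counts.tsv` — for the same array, the number of SNPs
  per non-PHR quality class with zero Mendelian inconsistencies across all
  tested trios and duos; summing them gives the size of the robust
  NMH + OTV set.
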