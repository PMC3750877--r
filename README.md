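# cnvmir

Quantifies and compares the microRNA (miRNA) and protein-coding-gene
content of clinically distinct copy-number-variant (CNV) classes.  It is
aimed at clinical and regulatory genomics analysts who have CNV calls for
a case cohort (typically probands with intellectual disability or other
neurodevelopmental phenotypes), a control cohort, and a pathogenic
reference set, and who want to know whether the non-coding content of
*de novo* or pathogenic CNVs differs from that of benign common CNVs.

## What it computes

* **Classification.** A CNV is *common* when the union of overlapping
  known variants (DGV-style table, optionally augmented with internal
  controls) covers 100% of its bases with support from ≥ 2 distinct
  studies; *rare* when < 50% of its bases are covered, splitting into
  *de novo* or *familial* by inheritance.  Undecided coverage
  (50–100%, or full coverage from a single study) is flagged `ambiguous`.
* **CNVR merging.** Overlapping CNVs of one subgroup (≥ 1 shared bp)
  merge transitively into CNV regions (CNVRs).
* **Content and densities.** For each CNVR, the miRNAs and genes
  overlapping it by ≥ 1 bp; per-group totals, counts per megabase
  (count / exact bp length × 10⁻⁶), and the size-weighted lower median of
  per-CNVR densities

  `wmed = min { v_(i) : Σ_{j ≤ i} w_(j) ≥ ½ Σ w }`,  with `w` = CNVR size (Mb).
* **Group comparisons.** Two-sided Wilcoxon rank-sum on per-CNVR
  densities; two-sided Fisher's exact tests on count fractions;
  Benjamini–Hochberg adjustment.
* **Coverage null.** For a subgroup covering an observed fraction of all
  genome-wide features, a resampled null redraws region sets with the same
  length list at random positions (chromosome chosen ∝ valid starts,
  uniform start; 1000 replicates by default) and reports
  `p = min(1, 2(1 + min(#{null ≥ obs}, #{null ≤ obs})) / (R + 1))`.
* **Target enrichment.** Fraction of subgroup genes present in a
  miRNA→target map; upper-tail hypergeometric over-representation
  `P(X ≥ k)` of gene sets with BH-adjusted p, top-10 ranking; reverse
  lookup of targeting miRNAs; brain-annotation fractions over miRNAs with
  expression data.

A seeded synthetic-cohort generator (`generate_cohort()`) emits every
input format with recorded ground truth, so the full pipeline is testable
offline; `spike_worked_example()` writes a miniature hand-checkable
fixture whose miRNA loci sit at real mature-miRNA coordinates.

## Worked example

```r
library(cnvmir)
fx <- spike_worked_example()            # miniature fixture on disk
g     <- read_genome(fx[["genome"]])
cnvs  <- read_cnv_table(fx[["cnvs"]], g)
known <- read_known_variants(fx[["known"]], g)
mir   <- read_gff3_mirnas(fx[["mirna"]], g)

part <- partition_cohort(cnvs, known)
#> subgroup counts: de_novo=4, familial=1, common_case=1, common_control=0, decipher=0

dn   <- merge_to_cnvrs(part$subgroups$de_novo, "de_novo")
summ <- summarize_cnvrs(dn, mir, read_bed_genes(fx[["genes"]], g))
summ[, c("cnvr_id", "chrom", "size_mb", "n_mirna", "mirna_density")]
#>             cnvr_id chrom  size_mb n_mirna mirna_density
#> 1 de_novo_cnvr_0001  chr1 0.010001       2    199.980002
#> 2 de_novo_cnvr_0002 chr19 0.050001       0      0.000000
#> 3 de_novo_cnvr_0003 chr20 0.665001       2      3.007514
#> 4 de_novo_cnvr_0004  chr7 0.010001       3    299.970003

gs <- summarize_group("de_novo", part$subgroups$de_novo, dn, summ)
format_group_summary(gs)[, c("subgroup", "n_cnvs", "n_cnvrs", "total_mb",
                             "total_mirna", "mirna_per_mb", "mirna_per_cnvr",
                             "wmedian_mirna_per_mb")]
#>   subgroup n_cnvs n_cnvrs total_mb total_mirna mirna_per_mb mirna_per_cnvr
#> 1  de_novo      4       4      0.7           7         9.52            1.8
#>   wmedian_mirna_per_mb
#> 1                    3

run_coverage_null(dn, mir, g, null_config(replicates = 999, seed = 1),
                  "de_novo", "mirna")
#> coverage null [de_novo, mirna]: observed 0.5385, null mean 0.0005 (999 replicates), p = 0.002
```

Reading the output: the four de novo CNVRs span 0.7 Mb and contain 7
distinct miRNAs (9.52/Mb overall; the size-weighted median per-CNVR
density is 3.0/Mb, dominated by the large chr20 region).  They cover 7 of
the fixture's 13 miRNAs (53.85%), far above the null mean of 0.05% for
random regions of the same lengths, giving the smallest two-tailed
empirical p attainable at 999 replicates (0.002).

`run_pipeline(pipeline_config(...))` chains every stage and writes
TSV reports (classification, CNVRs, per-CNVR content, group summary,
pairwise comparisons, coverage null, targeted genes, enrichment, brain
fractions) plus a `manifest.json` with input checksums, seed and row
counts; identical config and inputs give byte-identical outputs.

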