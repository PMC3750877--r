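---
title: "Quantifying miRNA and gene content of CNV subgroups"
author: "cnvmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA and gene content of CNV subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmir)
```

## The analysis

Copy number variants (CNVs) found in patients with neurodevelopmental
phenotypes fall into clinically distinct classes: *de novo* variants absent
from both parents, *familial* variants inherited from a parent, and
*common* variants that coincide with polymorphisms catalogued in
population-variant databases such as DGV.  A long-standing question is
whether the non-coding content of these classes differs — in particular
whether pathogenic-leaning CNVs carry more microRNAs (miRNAs) and more
miRNA-regulated protein-coding genes (PCGs) than benign common CNVs.

`cnvmir` implements that comparison as a reproducible pipeline:

1. **Classification.** Each case-cohort CNV is compared against a
   known-variant table.  A CNV is *common* when the union of overlapping
   known variants covers 100% of its bases and those variants come from at
   least two distinct studies; it is *rare* when less than 50% of its bases
   are covered, and rare CNVs split into *de novo* or *familial* by the
   recorded inheritance.  Control-cohort CNVs form their own common group,
   and a pathogenic reference set (e.g. syndromic regions from DECIPHER)
   bypasses classification.
2. **CNVR merging.** Within each subgroup, CNVs sharing at least one base
   are merged transitively into CNV regions (CNVRs), the unit of all
   downstream statistics.
3. **Content annotation.** miRNAs (from a miRBase-style GFF3) and PCGs
   (from BED) overlapping each CNVR by at least one base are counted;
   densities are counts per megabase of exact CNVR length.
4. **Group statistics.** Subgroups are compared by the size-weighted
   median of per-CNVR densities and the two-sided Wilcoxon rank-sum test;
   count fractions (targeted genes, brain-related miRNAs) are compared
   with two-sided Fisher's exact tests; multiplicity uses
   Benjamini-Hochberg.
5. **Coverage null.** Whether a subgroup's regions cover more (or fewer)
   of the genome's miRNAs or genes than expected is tested against a
   resampled null: random region sets with the same length list, redrawn
   1000 times by default, with an empirical two-tailed p-value.
6. **Target enrichment.** The fraction of subgroup genes appearing in a
   miRNA→target map, hypergeometric over-representation of gene sets
   (GMT), and the reverse lookup of which miRNAs target the subgroup's
   genes.

## Statistical details and conventions

**Coordinates.** All internal arithmetic is 0-based half-open; readers
normalise (CNV tables and known-variant tables default to 1-based
inclusive, the clinical convention; GFF3 is 1-based inclusive; BED is
native).  A single convention avoids off-by-one drift between formats.
Book-ended intervals share no base and never merge; "overlap" always means
at least one shared base pair.  Strand is ignored throughout: the
intersections are strandless region overlaps.

**Classification edge cases.** The published rules decide only full
coverage (common) and sub-50% coverage (rare).  Coverage in `[50%, 100%)`
— and full coverage supported by a single study — is undecided; such CNVs
are classed `ambiguous` and excluded by default, with
`classification_config(ambiguous_policy = "treat_as_rare")` as the
alternative.  We read "completely overlapping with variants reported in at
least two studies" as union coverage plus a distinct-study count, the
weakest reading consistent with the rule; requiring each study to cover
the CNV fully would be stricter and can be emulated by raising
`min_studies` after filtering the variant table.  Internal controls can be
appended to the known-variant list under a reserved study id
(`partition_cohort(..., controls_as_known = TRUE)`).

**Weighted median.** The group-level density statistic is the *lower*
weighted median of per-CNVR densities with CNVR sizes (Mb) as weights: the
smallest value whose cumulative weight reaches half the total.  No
interpolation is performed, so a subgroup in which most CNVRs contain no
miRNA reports exactly 0.  The unweighted median is emitted alongside,
since "weighted by size" admits both readings.

**Rank-sum, not signed-rank.** Subgroups are unpaired samples, so the
two-sided Wilcoxon rank-sum (Mann-Whitney) test is used: exact enumeration
when both samples have at most 10 observations and no ties, otherwise the
normal approximation with tie and continuity correction; the result's
method note records which path ran.

**Coverage null.** Each replicate redraws one region per observed CNVR
length: a chromosome is chosen with probability proportional to its number
of valid start positions (length − region length + 1, reduced by an
optional exclusion mask), then a uniform valid start.  Sampled regions may
overlap each other and are not re-merged — the null preserves the observed
length distribution and total coverage, and re-merging would shrink it;
`null_config(allow_overlap = FALSE)` switches to rejection sampling of
disjoint sets.  No assembly-gap mask is applied by default, but any
interval set can be supplied as a mask.  The empirical p-value is
`min(1, 2 * (1 + min(#{null ≥ obs}, #{null ≤ obs})) / (R + 1))`: doubling
the smaller tail makes it two-tailed, and the add-one correction keeps it
positive under finite resampling.  Replicate substreams are derived from
one named seed, so results do not depend on evaluation order.

**Enrichment.** The raw p-value of a gene set is the upper-tail
hypergeometric probability of at least the observed overlap, with the set
intersected with the universe first (overlap 0 gives p = 1, since
P(X ≥ 0) = 1).  The universe defaults to all genes in the PCG track and is
configurable to the union of set members.  The two-stage procedure used by
web enrichment tools — first select over-represented miRNA-target groups
at adjP < 0.05, then test pathways over the genes of the passing groups —
is reproduced by two sequential calls of `hypergeometric_enrichment()`,
first with the target map's per-miRNA gene sets and then with the pathway
collection.  Results are ranked by adjP with ties broken by raw p then set
name, filtered at adjP < 0.05 and truncated to the top 10 by default.
Gene identity is by symbol, upper-cased on read.

**Reporting.** Densities print with two decimals, per-CNVR averages and
sizes with one, percentages of brain-related miRNAs as whole percent, all
rounded half away from zero; the machine-readable companions
(`group_summary_full.tsv`) keep full precision, and density denominators
always use exact base-pair length / 10^6, never a rounded megabase figure.

## The synthetic cohort generator

Because the original coordinates, the variant-database freeze and the
curated expression annotations are not distributable inputs, every stage
is validated against synthetic cohorts with recorded ground truth
(`generate_cohort()`).  The default `simulation_spec()` mirrors the study
design the pipeline targets:

* a human-scale 24-chromosome genome (~3.1 Gb);
* 2042 miRNA loci, 35% of them placed in 60 clusters (s.d. 50 kb) to
  mimic genomic miRNA clustering — this is what lets a small CNV carry
  many miRNAs, the edge case that decouples per-Mb density from total
  content;
* 19,905 protein-coding genes with log-normal widths (median 30 kb);
* five subgroups with CNV counts 24 / 46 / 216 / 67 / 35 and log-normal
  sizes with medians 3.0 / 0.64 / 0.50 / 0.56 / 3.3 Mb (dispersion
  `sdlog = 0.6`), reproducing the large-rare versus small-common size
  contrast;
* a known-variant database of 300 loci, each reported by at least two of
  five studies; common CNVs are placed exactly on these loci and rare
  CNVs are rejection-placed to overlap none, so planted classes are
  unambiguous by construction;
* a miRNA→target map of 300 miRNAs × 40 targets with one planted pathway
  whose genes are drawn with weight 5 (the same magnitude used for the
  placement bias), and per-subgroup expression/brain-annotation fractions
  matching the published range (≈20–30% of rare-CNV miRNAs with
  expression data versus ≈10% for common ones).

A subgroup's `mirna_bias` m places a `1 − 1/m` share of its CNVs centred
on miRNA loci (m = 1 is uniform placement), which plants a coverage
enrichment of tunable strength.  Inheritance labels are assigned directly
(no trio simulation), and array-level artefacts (probe noise,
segmentation) are *not* emulated — passing tests therefore demonstrate
correctness of the analysis given CNV calls, not robustness to calling
error.

## Test problem sizes

The suite checks the interval algebra, coverage arithmetic and enrichment
p-values against per-base and exhaustive-enumeration oracles on toy
instances (hundreds of random cases on 10 kb chromosomes; universes ≤ 20
for full enumeration).  Calibration properties use sizes chosen to keep
granularity fine enough for a meaningful check while remaining quick: the
resampling-null calibration redraws 25 observed regions on a 20 Mb
two-chromosome genome with a 1000-feature track, 199 replicates and 200
runs (the discreteness of count fractions makes the empirical p slightly
conservative, which the accepted band reflects); the planted-effect power
check uses 50 seeded cohorts of 15 de-novo-like CNVs with `mirna_bias = 5`
and 99 replicates.  Classification recovery and planted-pathway ranking
run on the full-scale default cohort.

## Known limitations

* The classifier cannot reproduce a historical cohort partition without
  the same variant-database freeze and internal-control set; only the
  rules, not the published counts, are testable.
* The brain/expression annotation is an input table replacing manual
  literature curation; the pipeline tests its arithmetic, not its quality.
* The miRNA→target map is taken as given; no target prediction is
  performed.
* Published average-CNVR-size figures that are inconsistent with their own
  totals are not reproduced: the pipeline always reports
  totals / counts computed from its inputs.
* With very few informative CNVRs the rank-sum and Fisher tests have
  little power; the report emits them regardless, with the method note
  and counts needed to judge them.
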