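Package: cnvmir
Title: miRNA and Gene Content Analysis of Copy Number Variant Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies copy number variants (CNVs) from case/control
    cohorts into de novo, familial and common subgroups using
    known-variant (DGV-style) overlap rules, merges overlapping CNVs of
    the same subgroup into CNV regions (CNVRs), quantifies integral
    microRNAs and protein-coding genes per region, and compares
    subgroups with size-weighted density statistics, a random-interval
    resampling null for genome-wide coverage, Fisher tests on
    brain-annotation fractions, and hypergeometric pathway
    over-representation of miRNA target genes.  Includes a synthetic
    cohort simulator with recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
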