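test_that("feature membership counts any >=1 bp overlap, boundary straddlers included", {
  track <- data.frame(feature_id = sprintf("m%d", 1:5), chrom = "chr1",
                      start = c(0, 100, 200, 300, 400),
                      end = c(50, 150, 250, 350, 450),
                      stringsAsFactors = FALSE)
  region <- list(chrom = "chr1", start = 100, end = 350)
  expect_setequal(features_in_region(region, track), c("m2", "m3", "m4"))
  # a feature straddling the region boundary is inside
  straddle <- list(chrom = "chr1", start = 120, end = 220)
  expect_setequal(features_in_region(straddle, track), c("m2", "m3"))
  expect_equal(features_in_region(list(chrom = "chr2", start = 0, end = 500),
                                  track), character())
})

test_that("feature membership matches a per-base oracle and is monotone", {
  g <- toy_genome()
  set.seed(31)
  track <- random_toy_track(g, 40)
  for (i in 1:100) {
    region <- random_toy_interval(g, 100, 3000)
    expect_setequal(features_in_region(region, track),
                    oracle_features_in(region, track))
    # enlarging the region never loses features
    bigger <- list(chrom = region$chrom,
                   start = max(0, region$start - 200),
                   end = min(g$length[g$chrom == region$chrom], region$end + 200))
    expect_true(all(features_in_region(region, track) %in%
                      features_in_region(bigger, track)))
  }
})

test_that("CNVR summaries compute densities over exact Mb sizes", {
  track <- data.frame(feature_id = sprintf("m%d", 1:4), chrom = "chr1",
                      start = c(10, 20, 30, 40) * 1e4,
                      end = c(10, 20, 30, 40) * 1e4 + 22,
                      stringsAsFactors = FALSE)
  cnvr <- data.frame(cnvr_id = "r1", chrom = "chr1", start = 0, end = 2e6)
  s <- summarize_cnvr(cnvr, track, track[0, ])
  expect_equal(s$n_mirna, 4)
  expect_equal(s$mirna_density, 2)   # 4 miRNAs / 2 Mb
  expect_equal(s$n_gene, 0)
  expect_equal(s$gene_density, 0)
})

test_that("group summaries satisfy the identity constraints at Table-scale totals", {
  # construct a group whose totals are decipher-like: 90 miRNAs, 100.1 Mb,
  # 30 CNVRs -> 0.90 /Mb and 3.0 /CNVR after report rounding
  set.seed(32)
  n <- 30
  sizes <- rep(100.1e6 / n, n)
  starts <- cumsum(c(0, head(sizes, -1) + 1e5))
  cnvrs <- data.frame(cnvr_id = sprintf("r%02d", 1:n), chrom = "chrBig",
                      start = starts, end = starts + sizes)
  mir_pos <- sort(sample(unlist(lapply(1:n, function(i)
    seq(starts[i] + 50, starts[i] + sizes[i] - 50, length.out = 3))), 90))
  track <- data.frame(feature_id = sprintf("m%03d", 1:90), chrom = "chrBig",
                      start = mir_pos, end = mir_pos + 22,
                      stringsAsFactors = FALSE)
  summ <- summarize_cnvrs(cnvrs, track, track[0, ])
  gs <- summarize_group("decipher", cnvrs, cnvrs, summ)
  expect_equal(gs$total_mirna, 90)
  expect_equal(gs$total_mb, 100.1, tolerance = 1e-9)
  expect_equal(gs$mirna_per_mb, gs$total_mirna / gs$total_mb)
  expect_equal(gs$mirna_per_cnvr, gs$total_mirna / gs$n_cnvrs)
  fm <- format_group_summary(gs)
  expect_equal(fm$mirna_per_mb, 0.90)
  expect_equal(fm$mirna_per_cnvr, 3.0)
  # single-CNVR group: averages equal that CNVR's own values
  g1 <- summarize_group("one", cnvrs[1, ], cnvrs[1, ], summ[1, ])
  expect_equal(g1$mirna_per_mb, summ$mirna_density[1])
  expect_equal(g1$mirna_per_cnvr, summ$n_mirna[1])
})

test_that("group totals count distinct miRNAs and ignore CNVR order", {
  g <- toy_genome()
  set.seed(33)
  track <- random_toy_track(g, 30)
  cnvs <- do.call(rbind, lapply(1:10, function(i) random_toy_interval(g, 200, 2000)))
  cnvs$cnv_id <- sprintf("c%02d", 1:10)
  cnvrs <- merge_to_cnvrs(cnvs, "g")
  summ <- summarize_cnvrs(cnvrs, track, track[0, ])
  gs <- summarize_group("g", cnvs, cnvrs, summ)
  expect_equal(gs$total_mirna, length(unique(unlist(summ$mirna_ids))))
  # per-CNVR sum can only exceed or equal the distinct total
  expect_gte(sum(summ$n_mirna), gs$total_mirna)
  perm <- sample.int(nrow(cnvrs))
  gs2 <- summarize_group("g", cnvs, cnvrs[perm, ], summ[perm, ])
  expect_equal(gs2$total_mirna, gs$total_mirna)
  expect_equal(gs2$total_mb, gs$total_mb)
  expect_equal(gs2$wmedian_mirna_per_mb, gs$wmedian_mirna_per_mb)
})

test_that("report rounding is half away from zero at printed precision", {
  expect_equal(round_half_up(0.645, 2), 0.65)
  expect_equal(round_half_up(3.818181, 1), 3.8)
  expect_equal(round_half_up(45.833, 0), 46)
  expect_equal(round_half_up(-0.645, 2), -0.65)
})
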