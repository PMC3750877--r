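kv <- function(chrom, start, end, study, id = sprintf("v_%s", study)) {
  data.frame(chrom = chrom, start = start, end = end, study = study,
             variant_id = id, stringsAsFactors = FALSE)
}
cnv <- function(chrom, start, end, inheritance = "unknown", id = "c1") {
  list(cnv_id = id, chrom = chrom, start = start, end = end,
       inheritance = inheritance)
}

test_that("covered fraction uses the union of known variants and counts studies", {
  known <- rbind(kv("chr1", 100, 200, "S1"), kv("chr1", 100, 200, "S2"))
  cf <- covered_fraction(cnv("chr1", 100, 200), known)
  expect_equal(unname(cf["fraction"]), 1)
  expect_equal(unname(cf["studies"]), 2)

  cf <- covered_fraction(cnv("chr1", 0, 1000), kv("chr1", 0, 400, "S1"))
  expect_equal(unname(cf["fraction"]), 0.4)
  expect_equal(unname(cf["studies"]), 1)

  # two half-covering variants from different studies jointly cover
  known <- rbind(kv("chr1", 0, 600, "S1"), kv("chr1", 400, 1000, "S2"))
  cf <- covered_fraction(cnv("chr1", 0, 1000), known)
  expect_equal(unname(cf["fraction"]), 1)
  expect_equal(unname(cf["studies"]), 2)
})

test_that("covered fraction matches a per-base oracle on random configurations", {
  g <- toy_genome()
  set.seed(21)
  for (i in 1:100) {
    target <- random_toy_interval(g, 50, 2000)
    n <- sample(0:6, 1)
    known <- if (n == 0) kv(character(), numeric(), numeric(), character())
    else do.call(rbind, lapply(seq_len(n), function(j) {
      iv <- random_toy_interval(g, 50, 2000)
      kv(iv$chrom, iv$start, iv$end, sample(c("S1", "S2", "S3"), 1))
    }))
    cf <- covered_fraction(target, known)
    expect_equal(unname(cf["fraction"]),
                 oracle_covered_bp(target, known) / (target$end - target$start))
  }
})

test_that("classification rules map coverage and inheritance to classes", {
  cfg <- classification_config()
  known2 <- rbind(kv("chr1", 100, 200, "S1"), kv("chr1", 100, 200, "S2"))

  expect_equal(classify_cnv(cnv("chr1", 100, 200, "unknown"), known2, cfg)$class,
               "common")
  expect_equal(classify_cnv(cnv("chr1", 5000, 6000, "de_novo"), known2, cfg)$class,
               "de_novo")
  # 40% covered, inherited -> familial (rare)
  expect_equal(classify_cnv(cnv("chr1", 100, 1100, "maternal"),
                            kv("chr1", 100, 500, "S1"), cfg)$class,
               "familial")
  # full coverage but a single study is not decided by the rules
  expect_equal(classify_cnv(cnv("chr1", 100, 200, "maternal"),
                            kv("chr1", 100, 200, "S1"), cfg)$class,
               "ambiguous")
  # 60% coverage falls between the rare ceiling and common floor
  expect_equal(classify_cnv(cnv("chr1", 100, 1100, "maternal"),
                            kv("chr1", 100, 700, "S1"), cfg)$class,
               "ambiguous")
  cfg2 <- classification_config(ambiguous_policy = "treat_as_rare")
  expect_equal(classify_cnv(cnv("chr1", 100, 1100, "maternal"),
                            kv("chr1", 100, 700, "S1"), cfg2)$class,
               "familial")
  expect_error(classify_cnv(cnv("chr1", 5000, 6000, "unknown"), known2, cfg),
               "unknown inheritance")
})

test_that("classification is deterministic and monotone in min_studies", {
  g <- toy_genome()
  set.seed(22)
  for (i in 1:40) {
    target <- cnv("chr1", 1000, 3000,
                  sample(c("de_novo", "maternal", "paternal"), 1))
    known <- do.call(rbind, lapply(1:4, function(j) {
      iv <- random_toy_interval(g, 500, 4000)
      kv("chr1", iv$start, iv$end, sprintf("S%d", sample.int(4, 1)))
    }))
    r1 <- classify_cnv(target, known, classification_config(min_studies = 2))
    expect_identical(r1,
                     classify_cnv(target, known, classification_config(min_studies = 2)))
    r2 <- classify_cnv(target, known, classification_config(min_studies = 3))
    # raising the study threshold can never create a common call
    if (r2$class == "common") expect_equal(r1$class, "common")
  }
})

test_that("cohort partition routes cohorts to the five subgroups", {
  cnvs <- data.frame(
    cnv_id = sprintf("c%d", 1:6),
    chrom = "chr1",
    start = c(100, 5000, 8000, 100, 5000, 2000),
    end = c(200, 6000, 9000, 200, 6000, 3000),
    sample = "s",
    state = "gain",
    inheritance = c("unknown", "de_novo", "maternal", "unknown", "unknown",
                    "unknown"),
    cohort = c("case", "case", "case", "control", "control", "decipher"),
    stringsAsFactors = FALSE)
  known <- rbind(kv("chr1", 100, 200, "S1"), kv("chr1", 100, 200, "S2"))
  expect_warning(part <- partition_cohort(cnvs, known), "not common")
  expect_equal(part$subgroups$common_case$cnv_id, "c1")
  expect_equal(part$subgroups$de_novo$cnv_id, "c2")
  expect_equal(part$subgroups$familial$cnv_id, "c3")
  expect_equal(part$subgroups$common_control$cnv_id, "c4")
  expect_equal(part$subgroups$decipher$cnv_id, "c6")
  expect_equal(part$control_rare$cnv_id, "c5")
  # every CNV lands in exactly one class
  expect_false(anyNA(part$classification$class))
})

test_that("control CNVs can back the known-variant list as internal controls", {
  cnvs <- data.frame(
    cnv_id = c("case1", "ctrl1", "ctrl2"),
    chrom = "chr1", start = c(1000, 1000, 1000), end = c(2000, 2000, 2000),
    sample = "s", state = "gain",
    inheritance = c("maternal", "unknown", "unknown"),
    cohort = c("case", "control", "control"), stringsAsFactors = FALSE)
  known <- kv("chr1", 1000, 2000, "S_dgv")
  suppressWarnings({
    no_ctrl <- partition_cohort(cnvs, known)
    with_ctrl <- partition_cohort(cnvs, known, controls_as_known = TRUE)
  })
  # one external study alone cannot make the case CNV common...
  expect_equal(no_ctrl$classification$class[1], "ambiguous")
  # ...but the internal-control study tips it over the two-study floor
  expect_equal(with_ctrl$classification$class[1], "common")
})
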