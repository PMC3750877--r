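test_that("targeted-gene reports compute percentages at Table scale", {
  map <- list(mirX = sprintf("T%03d", 1:87))
  genes <- c(sprintf("T%03d", 1:87), sprintf("U%03d", 1:751))  # 838 genes
  r <- targeted_genes(genes, map, "decipher")
  expect_equal(r$n_genes, 838)
  expect_equal(r$n_targeted, 87)
  expect_equal(r$pct_targeted, 10.4)

  r2 <- targeted_genes(c(sprintf("T%03d", 1:3), sprintf("U%03d", 1:263)),
                       list(mirY = sprintf("T%03d", 1:3)), "common_control")
  expect_equal(r2$n_genes, 266)
  expect_equal(r2$pct_targeted, 1.1)

  r3 <- targeted_genes(sprintf("U%03d", 1:10), list(), "empty")
  expect_equal(r3$n_targeted, 0)
})

test_that("reverse miRNA lookup is consistent with forward targeting", {
  expect_equal(mirnas_targeting("G1", list(`miR-A` = "G1")), "miR-A")
  expect_equal(mirnas_targeting(character(), list(`miR-A` = "G1")), character())

  set.seed(61)
  universe <- sprintf("G%03d", 1:100)
  map <- lapply(setNames(seq_len(50), sprintf("miR-%02d", 1:50)), function(i)
    sample(universe, sample(1:8, 1)))
  for (i in 1:20) {
    genes <- sample(universe, sample(1:20, 1))
    got <- mirnas_targeting(genes, map)
    brute <- character()
    for (m in names(map)) {
      for (t in map[[m]]) if (t %in% genes) brute <- c(brute, m)
    }
    expect_setequal(got, unique(brute))
    # round trip: every reported miRNA targets at least one queried gene
    for (m in got) expect_true(any(map[[m]] %in% genes))
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- sprintf("G%02d", 1:20)
  sets <- list(S = universe[1:5])
  res <- attr(hypergeometric_enrichment(universe[c(1:4, 10)], sets, universe,
                                        adjp_threshold = 1.1), "all_sets")
  expect_equal(res$overlap, 4)
  expect_equal(res$p_raw, oracle_hyper_upper(4, 20, 5, 5), tolerance = 1e-9)

  set.seed(62)
  for (i in 1:15) {
    un <- sample(10:20, 1)
    universe <- sprintf("G%02d", seq_len(un))
    sn <- sample(2:(un - 2), 1)
    qn <- sample(2:min(7, un - 1), 1)
    sets <- list(S = universe[seq_len(sn)])
    query <- sample(universe, qn)
    res <- attr(hypergeometric_enrichment(query, sets, universe,
                                          adjp_threshold = 1.1), "all_sets")
    expect_equal(res$p_raw,
                 oracle_hyper_upper(res$overlap, un, sn, qn), tolerance = 1e-9)
  }

  # forced overlap: a set equal to the universe has raw p 1
  res <- attr(hypergeometric_enrichment(universe[1:3], list(ALL = universe),
                                        universe), "all_sets")
  expect_equal(res$p_raw, 1)
  # zero overlap: P(X >= 0) = 1
  res <- attr(hypergeometric_enrichment("G01", list(S = c("G05", "G06")),
                                        universe), "all_sets")
  expect_equal(res$p_raw, 1)
  expect_error(hypergeometric_enrichment("NOT_THERE", list(S = "G01"), universe),
               "outside the universe")
})

test_that("enrichment ranking, thresholding and monotonicity behave", {
  universe <- sprintf("G%03d", 1:200)
  sets <- list(HIT = universe[1:20], MISS = universe[101:120])
  query <- universe[1:25]
  res <- hypergeometric_enrichment(query, sets, universe)
  expect_equal(res$set_name[1], "HIT")
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(all(res$adj_p < 0.05))
  expect_true(all(res$adj_p >= res$p_raw))
  # adding a query gene never decreases any overlap
  res_all <- attr(hypergeometric_enrichment(query, sets, universe,
                                            adjp_threshold = 1.1), "all_sets")
  res_more <- attr(hypergeometric_enrichment(c(query, "G121"), sets, universe,
                                             adjp_threshold = 1.1), "all_sets")
  expect_true(all(res_more$overlap >= res_all$overlap))
})

test_that("raw enrichment p is super-uniform for random queries", {
  set.seed(63)
  universe <- sprintf("G%03d", 1:150)
  sets <- list(S = universe[1:30])
  ps <- vapply(1:400, function(i) {
    attr(hypergeometric_enrichment(sample(universe, 15), sets, universe,
                                   adjp_threshold = 1.1), "all_sets")$p_raw
  }, 0)
  expect_lte(mean(ps < 0.05), 0.07)
  expect_lte(mean(ps < 0.2), 0.25)
})

test_that("brain fraction reports use the with-data denominator", {
  ann <- data.frame(mirna = sprintf("m%02d", 1:90),
                    has_expression = rep(c(TRUE, FALSE), c(24, 66)),
                    brain_related = rep(c(TRUE, FALSE), c(11, 79)),
                    note = "", stringsAsFactors = FALSE)
  r <- brain_fraction_report(sprintf("m%02d", 1:90), ann, "decipher")
  expect_equal(r$n_mirna, 90)
  expect_equal(r$n_with_data, 24)
  expect_equal(r$n_brain, 11)
  expect_equal(r$pct_brain, 46)

  ann2 <- data.frame(mirna = sprintf("m%02d", 1:14),
                     has_expression = rep(c(TRUE, FALSE), c(4, 10)),
                     brain_related = rep(c(TRUE, FALSE), c(2, 12)),
                     note = "", stringsAsFactors = FALSE)
  r2 <- brain_fraction_report(sprintf("m%02d", 1:14), ann2, "familial")
  expect_equal(r2$pct_brain, 50)

  ann3 <- data.frame(mirna = sprintf("m%02d", 1:30),
                     has_expression = rep(c(TRUE, FALSE), c(3, 27)),
                     brain_related = FALSE, note = "", stringsAsFactors = FALSE)
  r3 <- brain_fraction_report(sprintf("m%02d", 1:30), ann3, "common_control")
  expect_equal(r3$n_with_data, 3)
  expect_equal(r3$n_brain, 0)
  expect_equal(r3$pct_brain, 0)

  # ids absent from the annotation count as no-data
  expect_message(r4 <- brain_fraction_report(c("m01", "zz"), ann, "x"),
                 "missing from the annotation")
  expect_equal(r4$n_mirna, 2)
  expect_equal(r4$n_with_data, 1)

  cmp <- compare_brain_fractions(r, r3)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
})
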