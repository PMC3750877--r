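test_that("coverage fraction counts distinct covered features", {
  g <- toy_genome()
  track <- data.frame(feature_id = sprintf("m%d", 1:10), chrom = "chr1",
                      start = seq(0, 9000, 1000), end = seq(100, 9100, 1000),
                      stringsAsFactors = FALSE)
  whole <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                      end = c(1e4, 5e3))
  expect_equal(coverage_fraction(whole, track), 1)
  none <- whole[0, ]
  expect_equal(coverage_fraction(none, track), 0)
  expect_error(coverage_fraction(whole, track, total = 0), "positive")

  set.seed(51)
  rtrack <- random_toy_track(g, 30)
  for (i in 1:100) {
    regions <- do.call(rbind, lapply(seq_len(sample(1:5, 1)), function(j)
      random_toy_interval(g, 100, 3000)))
    expected <- length(unique(unlist(lapply(seq_len(nrow(regions)), function(j)
      oracle_features_in(regions[j, ], rtrack))))) / nrow(rtrack)
    expect_equal(coverage_fraction(regions, rtrack), expected)
    # monotone under region supersets
    expect_gte(coverage_fraction(rbind(regions, random_toy_interval(g)), rtrack),
               coverage_fraction(regions, rtrack))
  }
})

test_that("random regions are uniform within and proportional across chromosomes", {
  one <- genome_build("chr1", 1000)
  set.seed(52)
  starts <- vapply(1:10000, function(i)
    sample_random_regions(100, one)$start, 0)
  expect_true(all(starts >= 0 & starts <= 900))
  # mean of Uniform{0..900} is 450, sd ~ 260; 3 standard errors
  expect_equal(mean(starts), 450, tolerance = 3 * 260 / sqrt(10000) / 450)

  # forced placement: a length equal to the longest chromosome
  two <- genome_build(c("a", "b"), c(900 + 99, 100 + 99))
  full <- sample_random_regions(999, two)
  expect_equal(full$chrom, "a")
  expect_equal(full$start, 0)
  expect_equal(full$end, 999)

  # 900 vs 100 placeable starts -> chromosome 'a' drawn ~90% of the time
  set.seed(53)
  chroms <- vapply(1:5000, function(i)
    sample_random_regions(100, two)$chrom, "")
  expect_equal(mean(chroms == "a"), 0.9,
               tolerance = 3 * sqrt(0.9 * 0.1 / 5000) / 0.9)

  expect_error(sample_random_regions(1e6, two), "no chromosome")
})

test_that("exclusion masks remove blocked start positions", {
  g <- genome_build("chr1", 1000)
  mask <- data.frame(chrom = "chr1", start = 400, end = 600)
  set.seed(54)
  for (i in 1:300) {
    r <- sample_random_regions(50, g, mask = mask)
    expect_equal(interval_overlap_bp(r[1, ], list(chrom = "chr1", start = 400,
                                                  end = 600)), 0)
  }
})

test_that("empirical two-tailed p follows the add-one doubling formula", {
  null <- seq_len(1000) / 1000
  expect_equal(empirical_two_tailed_p(2, null), 2 / 1001)
  expect_equal(empirical_two_tailed_p(-1, null), 2 / 1001)
  expect_equal(empirical_two_tailed_p(0.5, rep(0.5, 1000)), 1)
  # observed at the null median: both tails large, capped at 1
  expect_equal(empirical_two_tailed_p(0.5005, null), 1)
  expect_error(empirical_two_tailed_p(1, numeric()), "empty")
})

test_that("the resampling null is reproducible and detects planted structure", {
  g <- genome_build(c("c1", "c2"), c(8e6, 4e6))
  set.seed(55)
  track <- data.frame(feature_id = sprintf("m%03d", 1:200),
                      chrom = sample(c("c1", "c2"), 200, TRUE, c(2, 1) / 3),
                      stringsAsFactors = FALSE)
  track$start <- floor(runif(200, 0, c(c1 = 8e6, c2 = 4e6)[track$chrom] - 25))
  track$end <- track$start + 22
  cnvrs <- data.frame(cnvr_id = "r1", chrom = "c1",
                      start = track$start[1], end = track$start[1] + 2e5)

  r1 <- run_coverage_null(cnvrs, track, g, null_config(replicates = 200, seed = 9))
  r2 <- run_coverage_null(cnvrs, track, g, null_config(replicates = 200, seed = 9))
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$null >= 0 & r1$null <= 1))

  # regions planted directly on 30 features must look enriched
  planted <- data.frame(cnvr_id = sprintf("p%d", 1:30), chrom = track$chrom[1:30],
                        start = pmax(0, track$start[1:30] - 100),
                        end = track$end[1:30] + 100)
  rp <- run_coverage_null(planted, track, g, null_config(replicates = 199, seed = 10))
  expect_gt(rp$observed, max(rp$null))
  expect_lt(rp$p_value, 0.05)

  # disallowing overlap yields pairwise-disjoint samples
  set.seed(56)
  regs <- cnvmir:::sample_disjoint_regions(rep(2e5, 10), g)
  o <- order(regs$chrom, regs$start)
  s <- regs[o, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  expect_false(any(same & s$start[-1] < s$end[-nrow(s)]))
})
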