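# Independent brute-force oracles and small fixture builders.  The oracles
# operate per base (or by exhaustive enumeration) and share no code with
# the implementation they check.

# Per-base overlap between two intervals on toy coordinates.
oracle_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1)))
}

# Per-base count of region bases covered by the union of intervals.
oracle_covered_bp <- function(region, intervals) {
  bases <- seq(region$start, region$end - 1)
  covered <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] != region$chrom) next
    covered <- covered | (bases >= intervals$start[i] & bases < intervals$end[i])
  }
  sum(covered)
}

# Per-base union size of a set of intervals (single toy chromosome scale).
oracle_union_bp <- function(intervals) {
  if (nrow(intervals) == 0) return(0L)
  total <- 0L
  for (ch in unique(intervals$chrom)) {
    sel <- intervals[intervals$chrom == ch, ]
    bases <- unique(unlist(lapply(seq_len(nrow(sel)),
                                  function(i) seq(sel$start[i], sel$end[i] - 1))))
    total <- total + length(bases)
  }
  total
}

# Feature membership by per-base scan.
oracle_features_in <- function(region, track) {
  hits <- character()
  for (i in seq_len(nrow(track))) {
    if (oracle_overlap_bp(region, track[i, ]) > 0) {
      hits <- c(hits, track$feature_id[i])
    }
  }
  unique(hits)
}

# Connected components of the interval overlap graph by repeated pairwise
# union (quadratic, order-free).
oracle_merge <- function(intervals) {
  comp <- as.list(seq_len(nrow(intervals)))
  iv <- intervals
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(iv))) {
      for (j in seq_len(nrow(iv))) {
        if (i >= j || nrow(iv) < 2) next
        if (iv$chrom[i] == iv$chrom[j] &&
            min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j]) > 0) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          comp[[i]] <- c(comp[[i]], comp[[j]])
          iv <- iv[-j, , drop = FALSE]
          comp <- comp[-j]
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  iv$members <- comp
  iv[order(iv$chrom, iv$start), , drop = FALSE]
}

# Exhaustive two-sided Fisher p from hypergeometric enumeration with fixed
# margins, summing tables no more probable than the observed one.
oracle_fisher_p <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  probs <- vapply(max(0, K - n2):min(K, n1), function(k) {
    choose(n1, k) * choose(n2, K - k) / choose(n1 + n2, K)
  }, 0)
  obs <- probs[k1 - max(0, K - n2) + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by enumerating every possible query draw.
oracle_hyper_upper <- function(overlap, universe_n, set_n, query_n) {
  draws <- utils::combn(universe_n, query_n)
  # the set occupies elements 1..set_n of the universe
  mean(apply(draws, 2, function(d) sum(d <= set_n) >= overlap))
}

# Exact two-sided rank-sum p by enumerating all group labelings.
oracle_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_along(a)])
  all_sums <- apply(utils::combn(n, length(a)), 2, function(ix) sum(r[ix]))
  mu <- length(a) * (n + 1) / 2
  min(1, mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-9))
}

# Lower weighted median by integer-weight replication.
oracle_weighted_median <- function(values, weights) {
  k <- round(weights * 1000)
  x <- sort(rep(values, k))
  x[ceiling(length(x) / 2)]
}

# Toy fixtures ---------------------------------------------------------

toy_genome <- function() genome_build(c("chr1", "chr2"), c(1e4, 5e3))

random_toy_interval <- function(genome, min_len = 1, max_len = 2000) {
  ci <- sample.int(nrow(genome), 1)
  len <- sample(min_len:max_len, 1)
  s <- sample.int(genome$length[ci] - len + 1, 1) - 1
  data.frame(chrom = genome$chrom[ci], start = s, end = s + len,
             stringsAsFactors = FALSE)
}

random_toy_track <- function(genome, n, prefix = "f") {
  rows <- lapply(seq_len(n), function(i) random_toy_interval(genome, 10, 500))
  df <- do.call(rbind, rows)
  df$feature_id <- sprintf("%s%03d", prefix, seq_len(n))
  df$strand <- "+"
  df$type <- "miRNA"
  df$feature_class <- "mirna"
  df
}

# Small simulation spec for fast end-to-end tests.
small_sim_spec <- function(seed = 1, ...) {
  simulation_spec(
    seed = seed,
    chromosomes = c(chrA = 3e7, chrB = 3e7, chrC = 3e7),
    n_mirna = 200, n_pcg = 800, n_hotspots = 10, hotspot_fraction = 0.4,
    subgroups = data.frame(
      label = c("de_novo", "familial", "common_case", "common_control",
                "decipher"),
      n_cnv = c(8, 8, 20, 10, 6),
      size_median_bp = c(1e6, 4e5, 3e5, 3e5, 1e6),
      size_sdlog = 0.5, mirna_bias = 1, stringsAsFactors = FALSE),
    n_studies = 4, n_common_loci = 40, map_mirnas = 50,
    targets_per_mirna = 15, n_pathways = 8, pathway_size = 15, ...)
}
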