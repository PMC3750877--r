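# Random-interval resampling null for genome-wide feature coverage.
#
# For a CNV subgroup, the observed statistic is the fraction of all
# annotated features (miRNAs or protein-coding genes) overlapped by the
# subgroup's regions.  The null redraws region sets with the same length
# list at random genomic positions; the empirical two-tailed p compares
# the observed fraction with the resampled ones.

#' Resampling-null configuration
#'
#' @param replicates number of random region sets drawn.
#' @param seed integer seed; per-replicate substreams are derived from it
#'   deterministically so results do not depend on execution order.
#' @param mask optional exclusion mask: data.frame of intervals (`chrom`,
#'   `start`, `end`, 0-based half-open) no sampled region may overlap.
#' @param allow_overlap may sampled regions overlap each other (default
#'   yes, preserving the requested total coverage); when `FALSE`,
#'   rejection sampling forces pairwise-disjoint regions.
#' @return a `null_config` list.
#' @export
null_config <- function(replicates = 1000, seed = 1, mask = NULL,
                        allow_overlap = TRUE) {
  stopifnot(replicates >= 1)
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 mask = mask, allow_overlap = isTRUE(allow_overlap)),
            class = "null_config")
}

#' Fraction of all features covered by a region set
#'
#' @param regions data.frame of intervals (`chrom`, `start`, `end`).
#' @param track annotation feature data.frame.
#' @param total total number of features of that class in the genome
#'   (defaults to the track size).
#' @return distinct features overlapping any region, divided by `total`.
#' @export
coverage_fraction <- function(regions, track, total = nrow(track)) {
  if (total <= 0) stop("total feature count must be positive", call. = FALSE)
  if (nrow(regions) == 0) return(0)
  length(unique(unlist(features_in_regions(regions, track)))) / total
}

# Allowed 0-based start positions for a region of length `len` on one
# chromosome, as a set of inclusive windows after removing mask-blocked
# starts.  Returns list(start=, end=) vectors, possibly empty.
allowed_start_windows <- function(chrom_len, len, mask_s = numeric(),
                                  mask_e = numeric()) {
  hi <- chrom_len - len
  if (hi < 0) return(list(start = numeric(), end = numeric()))
  ws <- 0; we <- hi
  if (length(mask_s)) {
    # a start s is blocked iff [s, s+len) intersects a mask interval
    bs <- pmax(0, mask_s - len + 1)
    be <- pmin(hi, mask_e - 1)
    keep <- bs <= be
    bs <- bs[keep]; be <- be[keep]
    if (length(bs)) {
      ord <- order(bs)
      bs <- bs[ord]; be <- be[ord]
      # merge blocked windows, then complement within [0, hi]
      ms <- bs[1]; me <- be[1]
      merged_s <- numeric(); merged_e <- numeric()
      for (i in seq_along(bs)[-1]) {
        if (bs[i] <= me + 1) me <- max(me, be[i]) else {
          merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
          ms <- bs[i]; me <- be[i]
        }
      }
      merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
      ws <- c(0, merged_e + 1)
      we <- c(merged_s - 1, hi)
      keep <- ws <= we
      ws <- ws[keep]; we <- we[keep]
    }
  }
  list(start = ws, end = we)
}

#' Draw random regions with a prescribed length list
#'
#' Each requested length is placed independently: a chromosome is chosen
#' with probability proportional to its number of valid start positions
#' (`chromosome length - region length + 1`, mask-adjusted), then a start
#' is drawn uniformly among the valid positions.  This reproduces a
#' "shuffle" preserving the length distribution and total coverage of an
#' observed region set.
#'
#' @param lengths numeric vector of region lengths in base pairs.
#' @param genome a [genome_build()].
#' @param mask optional exclusion mask (see [null_config()]).
#' @return data.frame of intervals (`chrom`, `start`, `end`), one per
#'   requested length, in request order.  Errors if some length fits on no
#'   chromosome.
#' @export
sample_random_regions <- function(lengths, genome, mask = NULL) {
  lens <- chrom_lengths(genome)
  if (is.null(mask) || nrow(mask) == 0) {
    # fast path: valid starts per chromosome are [0, L - len]
    out_chrom <- character(length(lengths))
    out_start <- numeric(length(lengths))
    for (i in seq_along(lengths)) {
      counts <- pmax(0, lens - lengths[i] + 1)
      if (sum(counts) == 0) {
        stop(sprintf("no chromosome can host a region of %s bp",
                     format(lengths[i], scientific = FALSE)), call. = FALSE)
      }
      ci <- sample.int(length(lens), 1, prob = counts)
      out_chrom[i] <- names(lens)[ci]
      out_start[i] <- sample.int(counts[[ci]], 1) - 1
    }
    return(data.frame(chrom = out_chrom, start = out_start,
                      end = out_start + lengths, stringsAsFactors = FALSE))
  }
  mask_by_chrom <- split(mask, mask$chrom)
  out_chrom <- character(length(lengths))
  out_start <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    wins <- lapply(names(lens), function(ch) {
      mk <- mask_by_chrom[[ch]]
      allowed_start_windows(lens[[ch]], len,
                            mk$start %||% numeric(), mk$end %||% numeric())
    })
    counts <- vapply(wins, function(w) sum(w$end - w$start + 1), 0)
    if (sum(counts) == 0) {
      stop(sprintf("no chromosome can host a region of %s bp",
                   format(len, scientific = FALSE)), call. = FALSE)
    }
    ci <- sample.int(length(lens), 1, prob = counts)
    w <- wins[[ci]]
    # uniform draw over the union of allowed windows
    r <- sample.int(counts[ci], 1) - 1
    cum <- cumsum(w$end - w$start + 1)
    wi <- which(r < cum)[1]
    offset <- r - c(0, cum)[wi]
    s <- w$start[wi] + offset
    out_chrom[i] <- names(lens)[ci]
    out_start[i] <- s
  }
  data.frame(chrom = out_chrom, start = out_start,
             end = out_start + lengths, stringsAsFactors = FALSE)
}

# Sorted per-chromosome track index for the tight resampling loop, where
# building a GRanges per replicate would dominate the run time.
build_track_index <- function(track) {
  by <- split(seq_len(nrow(track)), track$chrom)
  lapply(by, function(ii) {
    o <- ii[order(track$start[ii])]
    list(start = track$start[o], end = track$end[o], row = o,
         maxw = max(track$end[o] - track$start[o]))
  })
}

# Number of distinct track features overlapped by a region set, using the
# index above.  A feature with start <= s - maxw ends at or before s and
# cannot overlap [s, e), which bounds the candidate slice.
count_covered_features <- function(regions, index, n_track) {
  hit <- logical(n_track)
  for (i in seq_len(nrow(regions))) {
    ch <- index[[regions$chrom[i]]]
    if (is.null(ch)) next
    s <- regions$start[i]; e <- regions$end[i]
    lo <- findInterval(s - ch$maxw, ch$start)
    hi <- findInterval(e - 0.5, ch$start)
    if (hi > lo) {
      cand <- (lo + 1):hi
      hit[ch$row[cand][ch$end[cand] > s]] <- TRUE
    }
  }
  sum(hit)
}

# Rejection-sample a set of pairwise-disjoint regions.
sample_disjoint_regions <- function(lengths, genome, mask = NULL,
                                    max_tries = 1000) {
  for (try in seq_len(max_tries)) {
    regs <- sample_random_regions(lengths, genome, mask)
    ord <- order(regs$chrom, regs$start)
    s <- regs[ord, ]
    same <- s$chrom[-1] == s$chrom[-nrow(s)]
    if (nrow(s) < 2 || !any(same & s$start[-1] < s$end[-nrow(s)])) return(regs)
  }
  stop("could not place pairwise-disjoint regions after ", max_tries,
       " attempts", call. = FALSE)
}

#' Empirical two-tailed p-value from a resampled null
#'
#' `p = min(1, 2 * (1 + min(#{null >= obs}, #{null <= obs})) / (R + 1))`:
#' the smaller tail count is doubled and the +1 add-one correction keeps p
#' away from zero under finite resampling.
#'
#' @param observed observed statistic.
#' @param null numeric vector of resampled statistics.
#' @return p-value in (0, 1].
#' @export
empirical_two_tailed_p <- function(observed, null) {
  if (length(null) == 0) stop("empty null distribution", call. = FALSE)
  lo <- sum(null <= observed)
  hi <- sum(null >= observed)
  min(1, 2 * (1 + min(lo, hi)) / (length(null) + 1))
}

#' Coverage enrichment of a CNV subgroup against a random-interval null
#'
#' Computes the observed coverage fraction of the subgroup's CNVRs, draws
#' `replicates` random region sets with the same length list, and returns
#' the empirical two-tailed p.  Fully reproducible from the config seed:
#' each replicate uses a substream seed derived once from it, so the
#' result is independent of evaluation order.
#'
#' @param cnvrs the subgroup's CNVR data.frame.
#' @param track annotation feature data.frame (miRNA or gene).
#' @param genome a [genome_build()].
#' @param config a [null_config()].
#' @param label subgroup label carried into the result.
#' @param track_class `"mirna"` or `"pcg"`, carried into the result.
#' @param total genome-wide feature total (defaults to the track size).
#' @return a `coverage_null` list: `subgroup`, `track_class`, `observed`,
#'   `null` (length `replicates`), `p_value`, `seed`.
#' @export
run_coverage_null <- function(cnvrs, track, genome, config = null_config(),
                              label = "all", track_class = "mirna",
                              total = nrow(track)) {
  lengths <- cnvrs$end - cnvrs$start
  observed <- coverage_fraction(cnvrs, track, total)
  index <- build_track_index(track)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$replicates)
  null <- vapply(seq_len(config$replicates), function(i) {
    set.seed(sub_seeds[i])
    regs <- if (config$allow_overlap) {
      sample_random_regions(lengths, genome, config$mask)
    } else {
      sample_disjoint_regions(lengths, genome, config$mask)
    }
    count_covered_features(regs, index, nrow(track)) / total
  }, 0)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(subgroup = label, track_class = track_class,
                 observed = observed, null = null,
                 p_value = empirical_two_tailed_p(observed, null),
                 seed = config$seed),
            class = "coverage_null")
}

#' @export
print.coverage_null <- function(x, ...) {
  cat(sprintf(paste0("coverage null [%s, %s]: observed %.4f, ",
                     "null mean %.4f (%d replicates), p = %.4g\n"),
              x$subgroup, x$track_class, x$observed, mean(x$null),
              length(x$null), x$p_value))
  invisible(x)
}
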