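# Interval algebra and CNVR merging.
#
# All coordinates are 0-based half-open internally; readers normalise on
# input and writers denormalise per output format.  Interval set operations
# are delegated to GenomicRanges/IRanges behind this surface.

# Internal: data.frame (chrom/start/end, 0-based half-open) -> GRanges
# (1-based closed).  An explicit seqlevel set lets two objects on partly
# disjoint chromosome subsets be compared without seqinfo warnings.
as_gr <- function(df, seqlevels = NULL) {
  chrom <- if (is.null(seqlevels)) df$chrom else factor(df$chrom, seqlevels)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Overlap between two genomic intervals in base pairs
#'
#' @param a,b intervals: lists or one-row data.frames with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return shared base pairs: `max(0, min(ends) - max(starts))` when the
#'   chromosomes match, 0 otherwise.  Symmetric in its arguments.
#' @export
#' @examples
#' interval_overlap_bp(list(chrom = "chr1", start = 0, end = 100),
#'                     list(chrom = "chr1", start = 50, end = 150)) # 50
interval_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Merge overlapping CNV calls into CNV regions (CNVRs)
#'
#' CNVs sharing at least one base are merged transitively: the output
#' intervals are the connected components of the overlap graph.  Merging is
#' always within one subgroup; book-ended calls (end of one equal to start
#' of the next) share no base and are not merged.
#'
#' @param cnvs data.frame of CNV calls with at least `chrom`, `start`,
#'   `end`, `cnv_id` (0-based half-open coordinates).
#' @param subgroup label attached to the resulting regions.
#' @return data.frame of CNVRs sorted by chromosome then start, with
#'   columns `cnvr_id`, `chrom`, `start`, `end`, `subgroup`, `n_cnvs` and a
#'   list-column `members` of member CNV ids.  Empty input gives an empty
#'   frame.
#' @export
merge_to_cnvrs <- function(cnvs, subgroup = "all") {
  empty <- data.frame(cnvr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      subgroup = character(), n_cnvs = integer(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (is.null(cnvs) || nrow(cnvs) == 0) return(empty)
  if (is.null(cnvs$cnv_id)) cnvs$cnv_id <- sprintf("cnv_%04d", seq_len(nrow(cnvs)))

  gr <- as_gr(cnvs)
  # min.gapwidth = 0: merge only ranges that truly share bases; adjacent
  # (gap-0) ranges stay separate.
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, red)
  members <- split(cnvs$cnv_id[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits))

  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = as.numeric(GenomicRanges::end(red)),
                    subgroup = subgroup, stringsAsFactors = FALSE)
  out$members <- unname(members[as.character(seq_len(nrow(out)))])
  out$n_cnvs <- lengths(out$members)
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  out$cnvr_id <- sprintf("%s_cnvr_%04d", subgroup, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cnvr_id", "chrom", "start", "end", "subgroup", "n_cnvs", "members")]
}

#' Total genomic span of non-overlapping regions, in megabases
#'
#' @param cnvrs data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); regions must be pairwise non-overlapping (i.e. already
#'   merged) or an error is raised.
#' @return sum of region lengths / 1e6.
#' @export
total_span_mb <- function(cnvrs) {
  if (is.null(cnvrs) || nrow(cnvrs) == 0) return(0)
  ord <- order(cnvrs$chrom, cnvrs$start)
  s <- cnvrs[ord, , drop = FALSE]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (any(same & s$start[-1] < s$end[-nrow(s)])) {
    stop("regions overlap; merge them into CNVRs first", call. = FALSE)
  }
  sum(s$end - s$start) / 1e6
}
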