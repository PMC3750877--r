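# miRNA / protein-coding-gene content of CNVRs and Table-1-style group
# summaries.
#
# A feature belongs to a region when they share at least one base — genes
# "within or covering" a CNV both count.  Densities divide by the exact
# base-pair length / 1e6, never by a rounded megabase figure; rounding
# happens only in the reporting layer (format_group_summary).

#' Feature ids overlapping a region
#'
#' @param region list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param track annotation feature data.frame ([read_gff3_mirnas()] /
#'   [read_bed_genes()]).
#' @return character vector of ids of features overlapping the region by
#'   at least one base (each id once).
#' @export
features_in_region <- function(region, track) {
  if (is.null(track) || nrow(track) == 0) return(character())
  sel <- track$chrom == region$chrom & track$start < region$end &
    track$end > region$start
  unique(track$feature_id[sel])
}

# Feature ids per region for many regions at once (list parallel to rows).
features_in_regions <- function(regions, track) {
  if (nrow(regions) == 0) return(list())
  if (is.null(track) || nrow(track) == 0) {
    return(rep(list(character()), nrow(regions)))
  }
  lv <- union(unique(regions$chrom), unique(track$chrom))
  hits <- GenomicRanges::findOverlaps(as_gr(regions, lv), as_gr(track, lv))
  ids <- split(track$feature_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  lapply(unname(ids), unique)
}

#' Content summary of one CNVR
#'
#' @param cnvr one-row CNVR data.frame (see [merge_to_cnvrs()]).
#' @param mirna_track miRNA feature data.frame.
#' @param gene_track protein-coding-gene feature data.frame.
#' @return one-row data.frame with counts, size in Mb and per-Mb densities,
#'   plus list-columns `mirna_ids`, `gene_ids`.
#' @export
summarize_cnvr <- function(cnvr, mirna_track, gene_track) {
  mir <- features_in_region(cnvr, mirna_track)
  gen <- features_in_region(cnvr, gene_track)
  size_mb <- (cnvr$end - cnvr$start) / 1e6
  out <- data.frame(cnvr_id = cnvr$cnvr_id %||% NA_character_,
                    chrom = cnvr$chrom, start = cnvr$start, end = cnvr$end,
                    size_mb = size_mb,
                    n_mirna = length(mir), n_gene = length(gen),
                    mirna_density = length(mir) / size_mb,
                    gene_density = length(gen) / size_mb,
                    stringsAsFactors = FALSE)
  out$mirna_ids <- list(mir)
  out$gene_ids <- list(gen)
  out
}

#' Content summaries for a set of CNVRs
#'
#' Vectorised [summarize_cnvr()].
#'
#' @param cnvrs CNVR data.frame.
#' @inheritParams summarize_cnvr
#' @return data.frame with one row per CNVR, in input order.
#' @export
summarize_cnvrs <- function(cnvrs, mirna_track, gene_track) {
  if (nrow(cnvrs) == 0) {
    out <- data.frame(cnvr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), size_mb = numeric(),
                      n_mirna = integer(), n_gene = integer(),
                      mirna_density = numeric(), gene_density = numeric(),
                      stringsAsFactors = FALSE)
    out$mirna_ids <- list(); out$gene_ids <- list()
    return(out)
  }
  mir <- features_in_regions(cnvrs, mirna_track)
  gen <- features_in_regions(cnvrs, gene_track)
  size_mb <- (cnvrs$end - cnvrs$start) / 1e6
  out <- data.frame(cnvr_id = cnvrs$cnvr_id, chrom = cnvrs$chrom,
                    start = cnvrs$start, end = cnvrs$end, size_mb = size_mb,
                    n_mirna = lengths(mir), n_gene = lengths(gen),
                    mirna_density = lengths(mir) / size_mb,
                    gene_density = lengths(gen) / size_mb,
                    stringsAsFactors = FALSE)
  out$mirna_ids <- mir
  out$gene_ids <- gen
  out
}

#' Group-level summary (one Table-1-style row), full precision
#'
#' Totals count distinct feature ids across the group's CNVRs; per-CNVR
#' summaries keep duplicates (only distinguishable for malformed,
#' unmerged input, since merged CNVRs are disjoint).  The weighted median
#' density uses CNVR sizes in Mb as weights; the unweighted median is also
#' reported.
#'
#' @param label subgroup label.
#' @param cnvs the group's CNV calls.
#' @param cnvrs the group's merged CNVRs.
#' @param summaries output of [summarize_cnvrs()] for exactly `cnvrs`.
#' @return one-row data.frame of unrounded group statistics.
#' @export
summarize_group <- function(label, cnvs, cnvrs, summaries) {
  stopifnot(nrow(summaries) == nrow(cnvrs))
  total_mb <- total_span_mb(cnvrs)
  n_cnvrs <- nrow(cnvrs)
  tot_mir <- length(unique(unlist(summaries$mirna_ids)))
  tot_gen <- length(unique(unlist(summaries$gene_ids)))
  wm <- function(v) {
    if (n_cnvrs == 0) return(NA_real_)
    weighted_median(v, summaries$size_mb)
  }
  data.frame(subgroup = label,
             n_cnvs = nrow(cnvs), n_cnvrs = n_cnvrs,
             total_mb = total_mb,
             mean_cnvr_mb = if (n_cnvrs) total_mb / n_cnvrs else NA_real_,
             total_mirna = tot_mir,
             mirna_per_mb = if (total_mb > 0) tot_mir / total_mb else NA_real_,
             mirna_per_cnvr = if (n_cnvrs) tot_mir / n_cnvrs else NA_real_,
             wmedian_mirna_per_mb = wm(summaries$mirna_density),
             median_mirna_per_mb = if (n_cnvrs) stats::median(summaries$mirna_density) else NA_real_,
             total_gene = tot_gen,
             gene_per_mb = if (total_mb > 0) tot_gen / total_mb else NA_real_,
             gene_per_cnvr = if (n_cnvrs) tot_gen / n_cnvrs else NA_real_,
             wmedian_gene_per_mb = wm(summaries$gene_density),
             median_gene_per_mb = if (n_cnvrs) stats::median(summaries$gene_density) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Reporting layer: round a group summary to printed precision
#'
#' Densities (per-Mb figures) are printed with two decimals, per-CNVR
#' averages and sizes with one, using half-away-from-zero rounding
#' ([round_half_up()]).
#'
#' @param gs data.frame from [summarize_group()] (any number of rows).
#' @return data.frame with rounded columns.
#' @export
format_group_summary <- function(gs) {
  out <- gs
  for (col in intersect(c("mirna_per_mb", "gene_per_mb"), names(gs))) {
    out[[col]] <- round_half_up(gs[[col]], 2)
  }
  one_dec <- c("total_mb", "mean_cnvr_mb", "mirna_per_cnvr", "gene_per_cnvr",
               "wmedian_mirna_per_mb", "median_mirna_per_mb",
               "wmedian_gene_per_mb", "median_gene_per_mb")
  for (col in intersect(one_dec, names(gs))) {
    out[[col]] <- round_half_up(gs[[col]], 1)
  }
  out
}
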