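# miRNA-target fractions, hypergeometric pathway over-representation and
# the brain-annotation fraction report.

#' Genes of a subgroup targeted by any miRNA
#'
#' @param genes character vector of gene symbols found in a subgroup's
#'   CNVs.
#' @param target_map named list mapping miRNA id -> target gene symbols
#'   (see [read_target_map()]).
#' @param label subgroup label carried into the report.
#' @return one-row data.frame (`n_genes`, `n_targeted`, `pct_targeted` —
#'   rounded to one decimal — and list-column `targeted`); the unrounded
#'   percentage is in `pct_targeted_raw`.
#' @export
targeted_genes <- function(genes, target_map, label = "all") {
  genes <- unique(toupper(genes))
  all_targets <- unique(toupper(unlist(target_map, use.names = FALSE)))
  hit <- intersect(genes, all_targets)
  pct <- if (length(genes)) 100 * length(hit) / length(genes) else NA_real_
  out <- data.frame(subgroup = label, n_genes = length(genes),
                    n_targeted = length(hit),
                    pct_targeted = round_half_up(pct, 1),
                    pct_targeted_raw = pct, stringsAsFactors = FALSE)
  out$targeted <- list(sort(hit))
  out
}

#' miRNAs targeting any gene of a set (reverse lookup)
#'
#' @param genes character vector of gene symbols.
#' @param target_map named list mapping miRNA id -> target gene symbols.
#' @return character vector of miRNA ids whose target set intersects
#'   `genes`.
#' @export
mirnas_targeting <- function(genes, target_map) {
  genes <- unique(toupper(genes))
  if (length(genes) == 0 || length(target_map) == 0) return(character())
  hit <- vapply(target_map, function(t) any(toupper(t) %in% genes), TRUE)
  names(target_map)[hit]
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, the raw p is the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when `|query|` genes are sampled
#' without replacement from the universe (each set is intersected with the
#' universe before testing; an overlap of 0 gives p = 1 since
#' P(X >= 0) = 1).  Benjamini-Hochberg adjustment runs across all tested
#' sets; results are filtered to `adjP < adjp_threshold`, ranked by adjP
#' (ties broken by raw p, then set name) and truncated to the top `k`.
#'
#' @param query character vector of query gene symbols; must lie within
#'   the universe.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector of all eligible gene symbols.
#' @param adjp_threshold report sets with adjP strictly below this.
#' @param top_k maximum number of sets reported.
#' @return data.frame, one row per reported set: `set_name`, `set_size`,
#'   `overlap`, `p_raw`, `adj_p`, `rank` and list-column `overlap_genes`.
#'   The unfiltered table is attached as attribute `"all_sets"`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe,
                                      adjp_threshold = 0.05, top_k = 10) {
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(set_name = character(), set_size = integer(),
                      overlap = integer(), p_raw = numeric(),
                      adj_p = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  empty$overlap_genes <- list()
  if (length(sets) == 0) {
    attr(empty, "all_sets") <- empty
    return(empty)
  }
  inset <- lapply(sets, function(s) intersect(unique(toupper(s)), universe))
  ov <- lapply(inset, intersect, query)
  k <- lengths(ov)
  m <- lengths(inset)
  p_raw <- stats::phyper(k - 1, m, length(universe) - m, length(query),
                         lower.tail = FALSE)
  all_sets <- data.frame(set_name = names(sets), set_size = m,
                         overlap = k, p_raw = p_raw,
                         adj_p = bh_adjust(p_raw),
                         stringsAsFactors = FALSE)
  all_sets$overlap_genes <- lapply(ov, sort)
  rownames(all_sets) <- NULL
  keep <- all_sets[all_sets$adj_p < adjp_threshold, , drop = FALSE]
  ord <- order(keep$adj_p, keep$p_raw, keep$set_name)
  keep <- keep[ord, , drop = FALSE]
  keep <- utils::head(keep, top_k)
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep <- keep[, c("set_name", "set_size", "overlap", "p_raw", "adj_p", "rank",
                   "overlap_genes")]
  attr(keep, "all_sets") <- all_sets
  keep
}

#' Brain-annotation fractions of a subgroup's miRNAs
#'
#' The percentage of brain-related miRNAs is computed over the miRNAs
#' *with expression data* only, rounded to integer percent in the report;
#' miRNAs missing from the annotation count as "no data" (a message logs
#' how many).
#'
#' @param mirna_ids character vector of the subgroup's miRNA ids.
#' @param annotations annotation data.frame (see
#'   [read_mirna_annotation()]).
#' @param label subgroup label carried into the report.
#' @return one-row data.frame: `n_mirna`, `n_with_data`, `n_brain`,
#'   `pct_brain` (integer percent, NA when no miRNA has data) and the
#'   unrounded `pct_brain_raw`.
#' @export
brain_fraction_report <- function(mirna_ids, annotations, label = "all") {
  mirna_ids <- unique(mirna_ids)
  idx <- match(mirna_ids, annotations$mirna)
  if (anyNA(idx) && length(mirna_ids)) {
    message(sum(is.na(idx)), " miRNA id(s) missing from the annotation; ",
            "counted as having no expression data")
  }
  has <- !is.na(idx) & annotations$has_expression[replace(idx, is.na(idx), 1)]
  brain <- has & annotations$brain_related[replace(idx, is.na(idx), 1)]
  n_with <- sum(has)
  n_brain <- sum(brain)
  pct <- if (n_with > 0) 100 * n_brain / n_with else NA_real_
  data.frame(subgroup = label, n_mirna = length(mirna_ids),
             n_with_data = n_with, n_brain = n_brain,
             pct_brain = round_half_up(pct, 0), pct_brain_raw = pct,
             stringsAsFactors = FALSE)
}

#' Compare the brain-related fractions of two subgroups
#'
#' Two-sided Fisher's exact test on brain-related counts among miRNAs
#' with expression data, via [fisher_fraction_test()].
#'
#' @param report_a,report_b one-row data.frames from
#'   [brain_fraction_report()].
#' @return one-row comparison data.frame.
#' @export
compare_brain_fractions <- function(report_a, report_b) {
  fisher_fraction_test(report_a$n_brain, report_a$n_with_data,
                       report_b$n_brain, report_b$n_with_data,
                       label_a = report_a$subgroup,
                       label_b = report_b$subgroup)
}
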