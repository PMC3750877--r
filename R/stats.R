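# Between-group statistics: size-weighted median density, Wilcoxon rank-sum
# comparison, Fisher's exact fraction test, Benjamini-Hochberg adjustment.

#' Lower weighted median
#'
#' The smallest value (over values sorted increasingly) whose cumulative
#' weight reaches half the total weight.  With equal weights this is the
#' ordinary lower median; no interpolation is performed, so a
#' majority-zero sample yields exactly 0.
#'
#' @param values numeric vector (e.g. per-CNVR densities).
#' @param weights positive weights aligned with `values` (e.g. CNVR sizes
#'   in Mb).
#' @return the weighted median value.
#' @export
#' @examples
#' weighted_median(c(0, 0, 5), c(1, 1, 10)) # 5
weighted_median <- function(values, weights) {
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (any(is.na(values)) || any(is.na(weights)) || any(weights <= 0)) {
    stop("weights must be positive and values/weights non-missing", call. = FALSE)
  }
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord])
  v[which(cw >= sum(weights) / 2)[1]]
}

comparison_result <- function(a, b, statistic, value, p, method) {
  data.frame(group_a = a, group_b = b, statistic = statistic,
             value = value, p_value = p, method = method,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two unpaired samples
#'
#' Two-sided; the exact null distribution is enumerated when both samples
#' have at most 10 observations and there are no ties, otherwise the
#' normal approximation with tie and continuity correction is used.  The
#' `method` note records which path ran.
#'
#' @param a,b numeric vectors (e.g. per-CNVR densities of two subgroups).
#' @param label_a,label_b group labels carried into the result.
#' @return one-row data.frame: groups, W statistic, two-sided p, method.
#' @export
rank_sum_test <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  comparison_result(label_a, label_b, "W", unname(ht$statistic),
                    min(1, ht$p.value),
                    if (exact) "wilcoxon rank-sum, exact enumeration"
                    else "wilcoxon rank-sum, normal approximation with tie correction")
}

#' Two-sided Fisher's exact test on two fractions
#'
#' Tests `k1/n1` against `k2/n2` on the 2x2 table
#' `[[k1, n1-k1], [k2, n2-k2]]`; two-sided by summing the probabilities of
#' all tables no more likely than the observed one.
#'
#' @param k1,n1 successes and total in group one.
#' @param k2,n2 successes and total in group two.
#' @param label_a,label_b group labels carried into the result.
#' @return one-row data.frame: groups, odds ratio estimate, p, method.
#' @export
fisher_fraction_test <- function(k1, n1, k2, n2, label_a = "a", label_b = "b") {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  comparison_result(label_a, label_b, "odds_ratio", unname(ht$estimate),
                    ht$p.value, "fisher exact, two-sided")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values (each >= its raw p, capped at 1, ranking
#'   preserved).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
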