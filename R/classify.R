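# CNV classification: common vs rare (de novo / familial) by overlap with a
# known-variant database.
#
# A CNV is common when the union of known variants covers all of its bases
# and the overlapping variants come from at least two distinct studies; it
# is rare when less than half of its bases are covered.  Coverage in
# between — or full coverage backed by a single study — is not decided by
# those rules and is classed "ambiguous" (excluded by default, optionally
# treated as rare).

#' Classification thresholds
#'
#' @param min_studies distinct studies required for a common call.
#' @param rare_ceiling covered-fraction ceiling below which a CNV is rare.
#' @param common_floor covered fraction required for a common call.
#' @param ambiguous_policy what to do with CNVs the rules leave undecided:
#'   drop them (`"exclude"`) or split them by inheritance like rare CNVs
#'   (`"treat_as_rare"`).
#' @return a `classification_config` list.
#' @export
classification_config <- function(min_studies = 2, rare_ceiling = 0.5,
                                  common_floor = 1.0,
                                  ambiguous_policy = c("exclude", "treat_as_rare")) {
  stopifnot(rare_ceiling >= 0, rare_ceiling <= common_floor, common_floor <= 1,
            min_studies >= 1)
  structure(list(min_studies = min_studies, rare_ceiling = rare_ceiling,
                 common_floor = common_floor,
                 ambiguous_policy = match.arg(ambiguous_policy)),
            class = "classification_config")
}

#' Fraction of a CNV covered by known variants
#'
#' Coverage is computed against the union of all overlapping known-variant
#' intervals (so two half-covering variants from different studies can
#' jointly cover a CNV); the supporting-study count is the number of
#' distinct study ids among the overlapping records.
#'
#' @param cnv one CNV: list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param known known-variant data.frame (see [read_known_variants()]).
#' @return named numeric: `fraction` in \[0, 1\] and `studies` count.
#' @export
covered_fraction <- function(cnv, known) {
  sel <- known$chrom == cnv$chrom & known$start < cnv$end & known$end > cnv$start
  if (!any(sel)) return(c(fraction = 0, studies = 0))
  s <- pmax(known$start[sel], cnv$start)
  e <- pmin(known$end[sel], cnv$end)
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  covered <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  covered <- covered + (cur_e - cur_s)
  c(fraction = covered / (cnv$end - cnv$start),
    studies = length(unique(known$study[sel])))
}

classify_one <- function(frac, studies, inheritance, config, strict) {
  if (frac >= config$common_floor && studies >= config$min_studies) {
    return("common")
  }
  if (frac >= config$rare_ceiling &&
      config$ambiguous_policy != "treat_as_rare") {
    return("ambiguous")
  }
  switch(inheritance,
         de_novo = "de_novo",
         maternal = ,
         paternal = "familial",
         unknown = if (strict) {
           stop("rare CNV with unknown inheritance cannot be split into de novo/familial",
                call. = FALSE)
         } else "rare_unsplit")
}

#' Classify one CNV
#'
#' @param cnv one CNV call (see [read_cnv_table()]).
#' @param known known-variant data.frame.
#' @param config a [classification_config()].
#' @param strict error on a rare CNV whose inheritance is unknown (the
#'   default for case cohorts); when `FALSE` such CNVs are classed
#'   `rare_unsplit`.
#' @return one-row data.frame: `cnv_id`, `class`, `covered_fraction`,
#'   `supporting_studies`.
#' @export
classify_cnv <- function(cnv, known, config = classification_config(),
                         strict = TRUE) {
  cf <- covered_fraction(cnv, known)
  data.frame(cnv_id = cnv$cnv_id %||% NA_character_,
             class = classify_one(cf[["fraction"]], cf[["studies"]],
                                  cnv$inheritance, config, strict),
             covered_fraction = cf[["fraction"]],
             supporting_studies = as.integer(cf[["studies"]]),
             stringsAsFactors = FALSE)
}

#' Classify every CNV in a table
#'
#' @param cnvs CNV call data.frame.
#' @inheritParams classify_cnv
#' @return data.frame with one row per CNV, in input order.
#' @export
classify_cnvs <- function(cnvs, known, config = classification_config(),
                          strict = TRUE) {
  out <- lapply(seq_len(nrow(cnvs)), function(i) {
    classify_cnv(cnvs[i, ], known, config, strict)
  })
  do.call(rbind, out)
}

#' Partition a cohort into the five standard CNV subgroups
#'
#' Case-cohort CNVs are classified into `de_novo`, `familial` and
#' `common_case`; control-cohort CNVs into `common_control` (their rare
#' CNVs are reported separately with a warning, since controls carry no
#' trio inheritance information); `decipher`-cohort CNVs bypass
#' classification and map directly to the `decipher` subgroup.  Optionally
#' the control cohort's own CNVs are appended to the known-variant list
#' under a reserved study id before classification, mirroring the use of
#' internal controls alongside a public variant database.
#'
#' @param cnvs CNV call data.frame (mixed cohorts).
#' @param known known-variant data.frame.
#' @param config a [classification_config()].
#' @param controls_as_known append control-cohort CNVs to the known-variant
#'   list under study id `"internal_controls"` before classifying cases.
#' @return list with `subgroups` (named list of the five CNV data.frames),
#'   `control_rare`, `excluded` (ambiguous CNVs under the exclude policy)
#'   and `classification` (per-CNV report incl. subgroup).
#' @export
partition_cohort <- function(cnvs, known, config = classification_config(),
                             controls_as_known = FALSE) {
  is_case <- cnvs$cohort == "case"
  is_ctrl <- cnvs$cohort == "control"
  is_dec <- cnvs$cohort == "decipher"

  known_eff <- known
  if (controls_as_known && any(is_ctrl)) {
    ctrl <- cnvs[is_ctrl, ]
    known_eff <- rbind(known,
                       data.frame(chrom = ctrl$chrom, start = ctrl$start,
                                  end = ctrl$end, study = "internal_controls",
                                  variant_id = ctrl$cnv_id,
                                  stringsAsFactors = FALSE))
  }

  cls <- rep(NA_character_, nrow(cnvs))
  frac <- rep(NA_real_, nrow(cnvs))
  studies <- rep(NA_integer_, nrow(cnvs))
  if (any(is_case)) {
    r <- classify_cnvs(cnvs[is_case, ], known_eff, config, strict = TRUE)
    cls[is_case] <- r$class
    frac[is_case] <- r$covered_fraction
    studies[is_case] <- r$supporting_studies
  }
  if (any(is_ctrl)) {
    r <- classify_cnvs(cnvs[is_ctrl, ], known, config, strict = FALSE)
    cls[is_ctrl] <- r$class
    frac[is_ctrl] <- r$covered_fraction
    studies[is_ctrl] <- r$supporting_studies
  }
  cls[is_dec] <- "decipher"

  subgroup <- rep(NA_character_, nrow(cnvs))
  subgroup[is_case & cls == "de_novo"] <- "de_novo"
  subgroup[is_case & cls == "familial"] <- "familial"
  subgroup[is_case & cls == "common"] <- "common_case"
  subgroup[is_ctrl & cls == "common"] <- "common_control"
  subgroup[is_dec] <- "decipher"

  ctrl_rare <- is_ctrl & cls != "common"
  if (any(ctrl_rare)) {
    warning(sum(ctrl_rare),
            " control-cohort CNV(s) are not common; reported separately, ",
            "not assigned to a subgroup", call. = FALSE)
  }
  excluded <- is_case & cls == "ambiguous"
  if (any(excluded)) {
    message(sum(excluded), " ambiguous case CNV(s) excluded by policy")
  }

  labels <- c("de_novo", "familial", "common_case", "common_control", "decipher")
  subgroups <- lapply(stats::setNames(labels, labels), function(l) {
    out <- cnvs[!is.na(subgroup) & subgroup == l, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  message("subgroup counts: ",
          paste(sprintf("%s=%d", labels, vapply(subgroups, nrow, 0L)),
                collapse = ", "))
  list(subgroups = subgroups,
       control_rare = cnvs[ctrl_rare, , drop = FALSE],
       excluded = cnvs[excluded, , drop = FALSE],
       classification = data.frame(cnv_id = cnvs$cnv_id, cohort = cnvs$cohort,
                                   class = cls, subgroup = subgroup,
                                   covered_fraction = frac,
                                   supporting_studies = studies,
                                   stringsAsFactors = FALSE))
}
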