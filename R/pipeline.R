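# Pipeline orchestration: one declarative config, ordered stages, TSV/JSON
# reports and a run manifest sufficient to re-run bit-identically.

PIPELINE_STAGES <- c("classify", "merge", "annotate", "compare",
                     "coverage_null", "enrich")

#' Pipeline configuration
#'
#' Collects every input path and threshold in one auditable object.  Any
#' subset of stages can be run; later stages depend on `classify` and
#' `merge` having run in the same call.
#'
#' @param cnvs,genome,mirna_gff3,genes_bed,known_variants paths to the
#'   required inputs.
#' @param target_map,gene_sets,mirna_annotation optional input paths;
#'   stages needing a missing one are skipped with a message.
#' @param outdir output directory (created if missing).
#' @param seed integer seed for the resampling stage.
#' @param classification a [classification_config()].
#' @param null a [null_config()]; its seed defaults to `seed`.
#' @param adjp_threshold,top_k enrichment reporting thresholds.
#' @param cnv_coords coordinate convention of the CNV table.
#' @param mirna_type optional GFF3 type filter for the miRNA track.
#' @param stages stages to run, in fixed order.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cnvs, genome, mirna_gff3, genes_bed,
                            known_variants, target_map = NULL,
                            gene_sets = NULL, mirna_annotation = NULL,
                            outdir = tempfile("cnvmir_run"), seed = 1,
                            classification = classification_config(),
                            null = NULL, adjp_threshold = 0.05, top_k = 10,
                            cnv_coords = "one_based", mirna_type = NULL,
                            stages = PIPELINE_STAGES) {
  stopifnot(adjp_threshold > 0, adjp_threshold <= 1, top_k >= 1,
            all(stages %in% PIPELINE_STAGES))
  paths <- c(cnvs = cnvs, genome = genome, mirna_gff3 = mirna_gff3,
             genes_bed = genes_bed, known_variants = known_variants,
             target_map = target_map, gene_sets = gene_sets,
             mirna_annotation = mirna_annotation)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(paths = as.list(paths), outdir = outdir,
                 seed = as.integer(seed), classification = classification,
                 null = null %||% null_config(seed = seed),
                 adjp_threshold = adjp_threshold, top_k = top_k,
                 cnv_coords = cnv_coords, mirna_type = mirna_type,
                 stages = stages),
            class = "pipeline_config")
}

# Serialise list-columns for TSV output.
flatten_listcols <- function(df) {
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
    }
  }
  df
}

#' Run the pipeline
#'
#' Stages run in the fixed order classify -> merge -> annotate -> compare
#' -> coverage null -> enrich; each writes its reports under the output
#' directory, and a `manifest.json` records the config, input checksums,
#' seed and per-stage row counts.  Identical config + inputs give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; `manifest$outputs` names every
#'   file written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$paths
  genome <- read_genome(p$genome)
  cnvs <- read_cnv_table(p$cnvs, genome, coords = config$cnv_coords)
  mirna <- read_gff3_mirnas(p$mirna_gff3, genome, type = config$mirna_type)
  genes <- read_bed_genes(p$genes_bed, genome)
  known <- read_known_variants(p$known_variants, genome)
  tmap <- if (!is.null(p$target_map)) read_target_map(p$target_map)
  gsets <- if (!is.null(p$gene_sets)) read_gmt(p$gene_sets)
  ann <- if (!is.null(p$mirna_annotation)) read_mirna_annotation(p$mirna_annotation)

  outputs <- character()
  counts <- list()
  out <- function(name) file.path(config$outdir, name)
  emit <- function(df, name) {
    path <- write_tsv_prov(flatten_listcols(df), out(name), seed = config$seed)
    outputs[[name]] <<- path
    counts[[name]] <<- nrow(df)
  }
  labels <- SUBGROUP_LABELS

  part <- cnvrs_by <- summaries_by <- groups <- NULL
  if ("classify" %in% config$stages) {
    part <- partition_cohort(cnvs, known, config$classification)
    emit(part$classification, "classification.tsv")
  }
  if ("merge" %in% config$stages) {
    if (is.null(part)) stop("stage 'merge' requires stage 'classify'", call. = FALSE)
    cnvrs_by <- lapply(stats::setNames(labels, labels), function(l) {
      merge_to_cnvrs(part$subgroups[[l]], l)
    })
    emit(do.call(rbind, cnvrs_by), "cnvrs.tsv")
  }
  if ("annotate" %in% config$stages) {
    if (is.null(cnvrs_by)) stop("stage 'annotate' requires stage 'merge'", call. = FALSE)
    summaries_by <- lapply(cnvrs_by, summarize_cnvrs, mirna_track = mirna,
                           gene_track = genes)
    emit(do.call(rbind, summaries_by), "cnvr_content.tsv")
    groups <- do.call(rbind, lapply(labels, function(l) {
      summarize_group(l, part$subgroups[[l]], cnvrs_by[[l]], summaries_by[[l]])
    }))
    emit(groups, "group_summary_full.tsv")
    emit(format_group_summary(groups), "group_summary.tsv")
  }
  if ("compare" %in% config$stages) {
    if (is.null(summaries_by)) stop("stage 'compare' requires stage 'annotate'", call. = FALSE)
    pairs <- utils::combn(labels, 2)
    cmp <- list()
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      sa <- summaries_by[[a]]; sb <- summaries_by[[b]]
      if (nrow(sa) == 0 || nrow(sb) == 0) next
      r1 <- rank_sum_test(sa$mirna_density, sb$mirna_density, a, b)
      r1$quantity <- "mirna_per_mb"
      r2 <- rank_sum_test(sa$gene_density, sb$gene_density, a, b)
      r2$quantity <- "gene_per_mb"
      cmp[[length(cmp) + 1]] <- rbind(r1, r2)
    }
    cmp <- do.call(rbind, cmp)
    if (!is.null(cmp)) cmp$adj_p <- bh_adjust(cmp$p_value)
    emit(cmp %||% data.frame(), "comparisons.tsv")
  }
  if ("coverage_null" %in% config$stages) {
    if (is.null(cnvrs_by)) stop("stage 'coverage_null' requires stage 'merge'", call. = FALSE)
    res <- list()
    dump <- list()
    for (l in labels) {
      if (nrow(cnvrs_by[[l]]) == 0) next
      for (tc in c("mirna", "pcg")) {
        track <- if (tc == "mirna") mirna else genes
        cn <- run_coverage_null(cnvrs_by[[l]], track, genome, config$null,
                                label = l, track_class = tc)
        res[[length(res) + 1]] <- data.frame(subgroup = l, track_class = tc,
                                             observed = cn$observed,
                                             null_mean = mean(cn$null),
                                             p_value = cn$p_value,
                                             replicates = length(cn$null),
                                             seed = cn$seed,
                                             stringsAsFactors = FALSE)
        dump[[length(dump) + 1]] <- data.frame(subgroup = l, track_class = tc,
                                               replicate = seq_along(cn$null),
                                               fraction = cn$null,
                                               stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, res) %||% data.frame(), "coverage_null.tsv")
    emit(do.call(rbind, dump) %||% data.frame(), "null_distributions.tsv")
  }
  if ("enrich" %in% config$stages) {
    if (is.null(summaries_by)) stop("stage 'enrich' requires stage 'annotate'", call. = FALSE)
    universe <- unique(genes$feature_id)
    if (!is.null(tmap)) {
      tg <- do.call(rbind, lapply(labels, function(l) {
        targeted_genes(unique(unlist(summaries_by[[l]]$gene_ids)), tmap, l)
      }))
      tg$mirnas_targeting <- vapply(labels, function(l) {
        paste(mirnas_targeting(unique(unlist(summaries_by[[l]]$gene_ids)), tmap),
              collapse = ",")
      }, "")
      emit(tg, "targeted_genes.tsv")
      if (!is.null(gsets)) {
        enr <- list()
        for (l in labels) {
          sub_genes <- intersect(unique(unlist(summaries_by[[l]]$gene_ids)),
                                 universe)
          if (length(sub_genes) == 0) next
          # stage 1: which miRNA target-gene groups are over-represented
          # in this subgroup's genes
          s1 <- hypergeometric_enrichment(sub_genes, tmap, universe,
                                          config$adjp_threshold, config$top_k)
          stage2_query <- unique(unlist(s1$overlap_genes))
          if (length(stage2_query) == 0) next
          # stage 2: pathway over-representation of those target genes
          s2 <- hypergeometric_enrichment(stage2_query, gsets, universe,
                                          config$adjp_threshold, config$top_k)
          if (nrow(s2)) {
            s2$subgroup <- l
            enr[[length(enr) + 1]] <- s2
          }
        }
        emit(do.call(rbind, enr) %||% data.frame(), "enrichment.tsv")
      }
    }
    if (!is.null(ann)) {
      reports <- lapply(stats::setNames(labels, labels), function(l) {
        brain_fraction_report(unique(unlist(summaries_by[[l]]$mirna_ids)),
                              ann, l)
      })
      emit(do.call(rbind, reports), "brain_report.tsv")
      pairs <- utils::combn(labels, 2)
      bc <- list()
      for (j in seq_len(ncol(pairs))) {
        ra <- reports[[pairs[1, j]]]; rb <- reports[[pairs[2, j]]]
        if (ra$n_with_data == 0 || rb$n_with_data == 0) next
        bc[[length(bc) + 1]] <- compare_brain_fractions(ra, rb)
      }
      emit(do.call(rbind, bc) %||% data.frame(), "brain_comparisons.tsv")
    }
  }

  cfg_repr <- deparse(config[setdiff(names(config), "outdir")])
  cfg_file <- tempfile()
  writeLines(cfg_repr, cfg_file)
  manifest <- list(tool = "cnvmir",
                   version = as.character(utils::packageVersion("cnvmir")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   config = list(adjp_threshold = config$adjp_threshold,
                                 top_k = config$top_k,
                                 min_studies = config$classification$min_studies,
                                 rare_ceiling = config$classification$rare_ceiling,
                                 common_floor = config$classification$common_floor,
                                 replicates = config$null$replicates,
                                 stages = config$stages),
                   inputs = lapply(config$paths, function(f) {
                     list(path = f, md5 = unname(tools::md5sum(f)))
                   }),
                   row_counts = counts,
                   outputs = as.list(outputs))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$outputs$manifest <- file.path(config$outdir, "manifest.json")
  invisible(manifest)
}
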