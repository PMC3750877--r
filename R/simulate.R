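# Synthetic cohort simulator: emits every input file the pipeline reads,
# plus a ground-truth side-car, from one seeded specification.
#
# The default spec emulates the study design the package targets: a
# human-scale genome, ~2000 mature miRNA loci with clustering, ~20000
# protein-coding genes, five CNV subgroups whose counts and size
# distributions follow the published cohort (large ~3 Mb rare/pathogenic
# CNVs, small ~0.5-0.6 Mb common CNVs), a multi-study common-variant
# database, a miRNA-to-target map with one planted pathway, and a
# brain-annotation table with subgroup-specific fractions.

# Approximate hg18-scale chromosome lengths (autosomes + X/Y).
default_chromosomes <- function() {
  c(chr1 = 247249719, chr2 = 242951149, chr3 = 199501827, chr4 = 191273063,
    chr5 = 180857866, chr6 = 170899992, chr7 = 158821424, chr8 = 146274826,
    chr9 = 140273252, chr10 = 135374737, chr11 = 134452384, chr12 = 132349534,
    chr13 = 114142980, chr14 = 106368585, chr15 = 100338915, chr16 = 88827254,
    chr17 = 78774742, chr18 = 76117153, chr19 = 63811651, chr20 = 62435964,
    chr21 = 46944323, chr22 = 49691432, chrX = 154913754, chrY = 57772954)
}

SUBGROUP_LABELS <- c("de_novo", "familial", "common_case", "common_control",
                     "decipher")

#' Simulation specification
#'
#' Defaults mirror the cohort design the package analyses: subgroup CNV
#' counts 24/46/216/67/35, median sizes ~3 Mb for de novo and pathogenic
#' regions versus ~0.5-0.6 Mb for common ones (log-normal within group),
#' >2000 miRNA loci of which a fraction sits in genomic clusters, and
#' ~20000 protein-coding genes.
#'
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param n_mirna,n_pcg genome-wide miRNA / protein-coding-gene counts.
#' @param hotspot_fraction fraction of miRNAs placed inside clusters.
#' @param n_hotspots number of miRNA cluster centres.
#' @param hotspot_sd spread (bp, normal s.d.) of miRNAs around a centre.
#' @param subgroups data.frame with one row per subgroup: `label`,
#'   `n_cnv`, `size_median_bp`, `size_sdlog`, `mirna_bias` (placement bias
#'   multiplier towards miRNA loci; 1 = uniform placement).
#' @param n_studies number of studies in the known-variant database.
#' @param n_common_loci number of distinct common-variant loci.
#' @param map_mirnas,targets_per_mirna size of the miRNA-target map.
#' @param n_pathways,pathway_size gene-set collection shape.
#' @param planted_pathway name of the pathway whose genes miRNA targeting
#'   is biased towards.
#' @param planted_effect weight multiplier for planted-pathway genes when
#'   drawing targets (1 = no planted effect).
#' @param expression_fraction,brain_fraction per-subgroup fractions of
#'   subgroup miRNAs with expression data / brain relation (named by
#'   subgroup label).
#' @return a validated `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1,
                            chromosomes = default_chromosomes(),
                            n_mirna = 2042, n_pcg = 19905,
                            hotspot_fraction = 0.35, n_hotspots = 60,
                            hotspot_sd = 5e4,
                            subgroups = data.frame(
                              label = SUBGROUP_LABELS,
                              n_cnv = c(24, 46, 216, 67, 35),
                              size_median_bp = c(3.0e6, 6.4e5, 5.0e5, 5.6e5, 3.3e6),
                              size_sdlog = 0.6,
                              mirna_bias = 1,
                              stringsAsFactors = FALSE),
                            n_studies = 5, n_common_loci = 300,
                            map_mirnas = 300, targets_per_mirna = 40,
                            n_pathways = 20, pathway_size = 25,
                            planted_pathway = "SYNTH_PATHWAY_PLANTED",
                            planted_effect = 5,
                            expression_fraction = c(de_novo = 0.21,
                                                    familial = 0.29,
                                                    common_case = 0.06,
                                                    common_control = 0.10,
                                                    decipher = 0.27),
                            brain_fraction = c(de_novo = 0.55,
                                               familial = 0.50,
                                               common_case = 0.25,
                                               common_control = 0,
                                               decipher = 0.46)) {
  stopifnot(all(chromosomes > 0), n_mirna >= 0, n_pcg >= 0,
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            all(subgroups$n_cnv >= 0), all(subgroups$size_median_bp > 0),
            all(subgroups$mirna_bias > 0), planted_effect > 0,
            all(subgroups$label %in% SUBGROUP_LABELS))
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 n_mirna = n_mirna, n_pcg = n_pcg,
                 hotspot_fraction = hotspot_fraction,
                 n_hotspots = n_hotspots, hotspot_sd = hotspot_sd,
                 subgroups = subgroups, n_studies = n_studies,
                 n_common_loci = n_common_loci, map_mirnas = map_mirnas,
                 targets_per_mirna = targets_per_mirna,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 planted_pathway = planted_pathway,
                 planted_effect = planted_effect,
                 expression_fraction = expression_fraction,
                 brain_fraction = brain_fraction),
            class = "simulation_spec")
}

# Uniform genomic position for a region of `len` bp: chromosome chosen
# proportionally to its placeable starts, start uniform.
sim_place_uniform <- function(len, lens) {
  counts <- pmax(0, lens - len + 1)
  if (sum(counts) == 0) {
    stop(sprintf("no chromosome can host a region of %s bp",
                 format(len, scientific = FALSE)), call. = FALSE)
  }
  ci <- sample.int(length(lens), 1, prob = counts)
  s <- sample.int(counts[ci], 1) - 1
  list(chrom = names(lens)[ci], start = s, end = s + len)
}

#' Generate a complete synthetic cohort
#'
#' Writes every input file the pipeline reads — chromosome sizes, miRNA
#' GFF3, gene BED, CNV table, known-variant table, target map, GMT gene
#' sets, miRNA annotation — plus a `ground_truth.json` side-car, into
#' `dir`.  Construction guarantees: common CNVs coincide exactly with
#' multi-study known-variant loci (covered fraction 1, >= 2 studies);
#' rare/pathogenic CNVs are rejection-placed to overlap no known variant
#' (unambiguously rare); subgroups with `mirna_bias` m > 1 centre a
#' `1 - 1/m` share of their CNVs on miRNA loci (m = 1 places uniformly);
#' miRNA targeting is biased towards the planted pathway's genes by
#' `planted_effect`.  Byte-identical output for a given seed.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if missing).
#' @return list with `files` (named paths), `truth` (ground-truth list)
#'   and the in-memory `genome`.
#' @export
generate_cohort <- function(spec = simulation_spec(), dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  lens <- spec$chromosomes
  genome <- genome_build(names(lens), lens)

  ## miRNA track: clustered + uniform placement
  n_hot <- round(spec$n_mirna * spec$hotspot_fraction)
  centres <- if (spec$n_hotspots > 0) {
    t(vapply(seq_len(spec$n_hotspots),
             function(i) { p <- sim_place_uniform(1, lens); c(match(p$chrom, names(lens)), p$start) },
             c(0, 0)))
  }
  mir_chrom <- character(spec$n_mirna)
  mir_start <- numeric(spec$n_mirna)
  for (i in seq_len(spec$n_mirna)) {
    if (i <= n_hot && spec$n_hotspots > 0) {
      ci <- centres[sample.int(nrow(centres), 1), ]
      L <- lens[[ci[1]]]
      s <- round(ci[2] + stats::rnorm(1, 0, spec$hotspot_sd))
      s <- min(max(0, s), L - 22)
      mir_chrom[i] <- names(lens)[ci[1]]
      mir_start[i] <- s
    } else {
      p <- sim_place_uniform(22, lens)
      mir_chrom[i] <- p$chrom
      mir_start[i] <- p$start
    }
  }
  mirna <- data.frame(feature_id = sprintf("sim-mir-%04d", seq_len(spec$n_mirna)),
                      chrom = mir_chrom, start = mir_start,
                      end = mir_start + 22, strand = "+", type = "miRNA",
                      feature_class = "mirna", stringsAsFactors = FALSE)

  ## protein-coding gene track
  gene_w <- pmin(pmax(round(stats::rlnorm(spec$n_pcg, log(3e4), 1)), 200), 2e6)
  genes <- data.frame(feature_id = sprintf("SIMG%05d", seq_len(spec$n_pcg)),
                      chrom = character(spec$n_pcg), start = numeric(spec$n_pcg),
                      end = numeric(spec$n_pcg), strand = ".", type = "gene",
                      feature_class = "pcg", stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_pcg)) {
    p <- sim_place_uniform(gene_w[i], lens)
    genes$chrom[i] <- p$chrom; genes$start[i] <- p$start; genes$end[i] <- p$end
  }

  ## known-variant database: each locus reported by >= 2 distinct studies
  loci_w <- pmax(round(stats::rlnorm(spec$n_common_loci, log(5e5), 0.4)), 1e4)
  loci <- vector("list", spec$n_common_loci)
  kv <- vector("list", spec$n_common_loci)
  for (i in seq_len(spec$n_common_loci)) {
    p <- sim_place_uniform(loci_w[i], lens)
    loci[[i]] <- p
    n_rep <- min(spec$n_studies, 2 + stats::rbinom(1, spec$n_studies - 2, 0.3))
    st <- sample(sprintf("study_%02d", seq_len(spec$n_studies)), n_rep)
    kv[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                          study = st,
                          variant_id = sprintf("dgv_%04d_%s", i, st),
                          stringsAsFactors = FALSE)
  }
  known <- do.call(rbind, kv)

  ## CNVs per subgroup
  cohort_of <- c(de_novo = "case", familial = "case", common_case = "case",
                 common_control = "control", decipher = "decipher")
  inherit_of <- c(de_novo = "de_novo", common_case = "unknown",
                  common_control = "unknown", decipher = "unknown")
  cnv_rows <- list()
  true_class <- character()
  for (g in seq_len(nrow(spec$subgroups))) {
    lab <- spec$subgroups$label[g]
    n <- spec$subgroups$n_cnv[g]
    if (n == 0) next
    sizes <- pmin(pmax(round(stats::rlnorm(n, log(spec$subgroups$size_median_bp[g]),
                                           spec$subgroups$size_sdlog[g])), 2e3), 2e7)
    bias <- spec$subgroups$mirna_bias[g]
    common_like <- lab %in% c("common_case", "common_control")
    for (i in seq_len(n)) {
      if (common_like) {
        p <- loci[[sample.int(length(loci), 1)]]
      } else {
        # rejection-place until the CNV overlaps no known variant
        for (try in seq_len(1000)) {
          if (bias > 1 && stats::runif(1) < 1 - 1 / bias) {
            mi <- sample.int(nrow(mirna), 1)
            L <- lens[[mirna$chrom[mi]]]
            s <- max(0, min(round(mirna$start[mi] - sizes[i] * stats::runif(1)),
                            L - sizes[i]))
            p <- list(chrom = mirna$chrom[mi], start = s, end = s + sizes[i])
          } else {
            p <- sim_place_uniform(sizes[i], lens)
          }
          cf <- covered_fraction(p, known)
          if (cf[["fraction"]] == 0) break
          if (try == 1000) stop("infeasible placement of a rare CNV", call. = FALSE)
        }
      }
      inh <- if (lab == "familial") sample(c("maternal", "paternal"), 1) else
        inherit_of[[lab]]
      samp <- switch(cohort_of[[lab]],
                     case = sprintf("case_%03d", sample.int(213, 1)),
                     control = sprintf("control_%02d", sample.int(32, 1)),
                     decipher = sprintf("decipher_%02d", sample.int(40, 1)))
      cnv_rows[[length(cnv_rows) + 1]] <-
        data.frame(cnv_id = sprintf("%s_%03d", lab, i), chrom = p$chrom,
                   start = p$start, end = p$end, sample = samp,
                   state = sample(c("gain", "loss"), 1), inheritance = inh,
                   cohort = cohort_of[[lab]], stringsAsFactors = FALSE)
      true_class[sprintf("%s_%03d", lab, i)] <- lab
    }
  }
  cnvs <- do.call(rbind, cnv_rows)

  ## pathway collection; first set is the planted one
  sets <- lapply(seq_len(spec$n_pathways), function(i) {
    sample(genes$feature_id, min(spec$pathway_size, nrow(genes)))
  })
  names(sets) <- c(spec$planted_pathway,
                   sprintf("SYNTH_PATHWAY_%02d", seq_len(spec$n_pathways - 1) + 1))
  attr(sets, "description") <- stats::setNames(rep("synthetic", length(sets)),
                                               names(sets))

  ## target map biased towards the planted pathway
  planted_genes <- sets[[spec$planted_pathway]]
  w <- rep(1, nrow(genes))
  w[genes$feature_id %in% planted_genes] <- spec$planted_effect
  map_ids <- sample(mirna$feature_id, min(spec$map_mirnas, nrow(mirna)))
  target_map <- lapply(stats::setNames(map_ids, map_ids), function(m) {
    sort(sample(genes$feature_id, min(spec$targets_per_mirna, nrow(genes)),
                prob = w))
  })

  ## brain annotation, per-subgroup fractions over subgroup miRNA members
  ann <- data.frame(mirna = mirna$feature_id, has_expression = FALSE,
                    brain_related = FALSE, note = "synthetic",
                    stringsAsFactors = FALSE)
  assigned <- rep(FALSE, nrow(mirna))
  for (lab in SUBGROUP_LABELS) {
    sub_cnvs <- cnvs[cnvs$cnv_id %in% names(true_class)[true_class == lab], ,
                     drop = FALSE]
    if (nrow(sub_cnvs) == 0) next
    cnvrs <- merge_to_cnvrs(sub_cnvs, lab)
    ids <- unique(unlist(features_in_regions(cnvrs, mirna)))
    idx <- which(mirna$feature_id %in% ids & !assigned)
    assigned[idx] <- TRUE
    if (length(idx)) {
      has <- stats::runif(length(idx)) < spec$expression_fraction[[lab]]
      brain <- has & (stats::runif(length(idx)) < spec$brain_fraction[[lab]])
      ann$has_expression[idx] <- has
      ann$brain_related[idx] <- brain
    }
  }
  idx <- which(!assigned)
  has <- stats::runif(length(idx)) < 0.15
  ann$has_expression[idx] <- has
  ann$brain_related[idx] <- has & (stats::runif(length(idx)) < 0.25)

  ## emit files
  files <- c(genome = file.path(dir, "genome.tsv"),
             mirna = file.path(dir, "mirna.gff3"),
             genes = file.path(dir, "genes.bed"),
             cnvs = file.path(dir, "cnvs.tsv"),
             known = file.path(dir, "known_variants.tsv"),
             target_map = file.path(dir, "target_map.tsv"),
             gene_sets = file.path(dir, "pathways.gmt"),
             annotation = file.path(dir, "mirna_annotation.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_genome(genome, files[["genome"]])
  write_gff3_mirnas(mirna, files[["mirna"]], seed = spec$seed)
  write_bed_genes(genes, files[["genes"]], seed = spec$seed)
  write_cnv_table(cnvs, files[["cnvs"]], seed = spec$seed)
  write_known_variants(known, files[["known"]], seed = spec$seed)
  write_target_map(target_map, files[["target_map"]], seed = spec$seed)
  write_gmt(sets, files[["gene_sets"]])
  write_mirna_annotation(ann, files[["annotation"]], seed = spec$seed)

  truth <- list(seed = spec$seed,
                classes = as.list(true_class),
                mirna_bias = as.list(stats::setNames(spec$subgroups$mirna_bias,
                                                     spec$subgroups$label)),
                planted_pathway = spec$planted_pathway,
                planted_effect = spec$planted_effect,
                planted_genes = sort(planted_genes))
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  list(files = files, truth = truth, genome = genome)
}

#' Miniature hand-checkable worked-example fixture
#'
#' Writes a deterministic toy data set whose miRNA loci sit at real
#' mature-miRNA coordinates on full-length chromosomes, together with a
#' handful of CNVs chosen so every intersection count can be verified by
#' hand: one de novo CNV spanning chr1:1,100,000-1,110,000 contains
#' hsa-miR-200a/b and hsa-miR-429; another spans no miRNA at all; one
#' common CNV coincides with a two-study known variant.
#'
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
spike_worked_example <- function(dir = tempfile("spike")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- genome_build(
    c("chr1", "chr2", "chr5", "chr7", "chr15", "chr19", "chr20"),
    c(247249719, 242951149, 180857866, 158821424, 100338915, 63811651, 62435964))
  # 1-based inclusive loci of brain-annotated mature miRNAs
  loci <- data.frame(
    chrom = c("chr1", "chr1", "chr5", "chr5", "chr7", "chr7", "chr7",
              "chr19", "chr20", "chr20", "chr1", "chr15", "chr2"),
    start1 = c(1103258, 1104435, 87962684, 179442361, 99691233, 99691438,
               99691625, 4770712, 61151558, 61809866, 94312436, 45725296,
               32757280),
    end1 = c(1103279, 1104456, 87962705, 179442382, 99691253, 99691460,
             99691646, 4770734, 61151579, 61809887, 94312455, 45725317,
             32757298),
    id = c("hsa-miR-200a/b", "hsa-miR-429", "hsa-miR-9", "hsa-miR-340",
           "hsa-miR-25", "hsa-miR-93", "hsa-miR-106b", "hsa-miR-7",
           "hsa-miR-1", "hsa-miR-124", "hsa-miR-760", "hsa-miR-147b",
           "hsa-miR-558"),
    stringsAsFactors = FALSE)
  mirna <- data.frame(feature_id = loci$id, chrom = loci$chrom,
                      start = loci$start1 - 1, end = loci$end1,
                      strand = "+", type = "miRNA", feature_class = "mirna",
                      stringsAsFactors = FALSE)
  cnvs <- data.frame(
    cnv_id = c("dn_001", "dn_002", "dn_003", "fam_001", "common_001", "dn_empty"),
    chrom = c("chr1", "chr7", "chr20", "chr15", "chr2", "chr19"),
    start = c(1100000, 99690000, 61150000, 45720000, 32750000, 10000000) - 1,
    end = c(1110000, 99700000, 61815000, 45730000, 32760000, 10050000),
    sample = c("case_001", "case_002", "case_003", "case_004", "case_005",
               "case_006"),
    state = c("loss", "gain", "loss", "gain", "gain", "loss"),
    inheritance = c("de_novo", "de_novo", "de_novo", "maternal", "unknown",
                    "de_novo"),
    cohort = "case", stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr2", start = 32750000 - 1, end = 32760000,
                      study = c("study_01", "study_02"),
                      variant_id = c("dgv_spike_a", "dgv_spike_b"),
                      stringsAsFactors = FALSE)
  genes <- data.frame(feature_id = c("SPIKEG1", "SPIKEG2", "SPIKEG3"),
                      chrom = c("chr1", "chr7", "chr2"),
                      start = c(1101000, 99692000, 32752000),
                      end = c(1105000, 99695000, 32755000),
                      strand = ".", type = "gene", feature_class = "pcg",
                      stringsAsFactors = FALSE)
  target_map <- list(`hsa-miR-429` = c("SPIKEG1", "SPIKEG2"),
                     `hsa-miR-558` = "SPIKEG3")
  sets <- list(SPIKE_PATHWAY = c("SPIKEG1", "SPIKEG2"))
  attr(sets, "description") <- c(SPIKE_PATHWAY = "toy")
  ann <- data.frame(mirna = mirna$feature_id,
                    has_expression = TRUE,
                    brain_related = mirna$feature_id %in%
                      c("hsa-miR-200a/b", "hsa-miR-9", "hsa-miR-124"),
                    note = "toy", stringsAsFactors = FALSE)

  files <- c(genome = file.path(dir, "genome.tsv"),
             mirna = file.path(dir, "mirna.gff3"),
             genes = file.path(dir, "genes.bed"),
             cnvs = file.path(dir, "cnvs.tsv"),
             known = file.path(dir, "known_variants.tsv"),
             target_map = file.path(dir, "target_map.tsv"),
             gene_sets = file.path(dir, "pathways.gmt"),
             annotation = file.path(dir, "mirna_annotation.tsv"))
  write_genome(genome, files[["genome"]])
  write_gff3_mirnas(mirna, files[["mirna"]])
  write_bed_genes(genes, files[["genes"]])
  write_cnv_table(cnvs, files[["cnvs"]])
  write_known_variants(known, files[["known"]])
  write_target_map(target_map, files[["target_map"]])
  write_gmt(sets, files[["gene_sets"]])
  write_mirna_annotation(ann, files[["annotation"]])
  invisible(files)
}
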