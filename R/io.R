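# Readers and writers for every external file the pipeline touches.
#
# Readers validate aggressively and report the offending file line; they
# never reorder rows (sorting is an explicit downstream step).  Each reader
# round-trips through the matching writer.

CNV_STATES <- c("gain", "loss")
CNV_INHERITANCE <- c("de_novo", "maternal", "paternal", "unknown")
CNV_COHORTS <- c("case", "control", "decipher")

# Parse header + rows of a simple TSV, returning a list of character
# matrices plus original line numbers.
parse_tsv <- function(path, required, optional = character()) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(list(rows = NULL, header = character(), lineno = integer()))
  }
  header <- strsplit(dat$lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(miss, collapse = ", ")), call. = FALSE)
  }
  body <- dat$lines[-1]
  lineno <- dat$lineno[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < length(header))
  if (length(short)) {
    stop_at_line(path, lineno[short[1]], "fewer fields than header columns")
  }
  rows <- lapply(stats::setNames(seq_along(header), header),
                 function(j) vapply(fields, `[[`, "", j))
  list(rows = rows, header = header, lineno = lineno)
}

num_col <- function(x, path, lineno, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad)) stop_at_line(path, lineno[bad[1]], paste("non-numeric", what))
  out
}

# Convert declared input coordinates to the internal 0-based half-open
# convention, validating start/end order at the input convention.
normalize_coords <- function(start, end, coords, path, lineno) {
  if (coords == "one_based") {
    bad <- which(end < start)
    if (length(bad)) {
      stop_at_line(path, lineno[bad[1]],
                   sprintf("end (%s) < start (%s)",
                           format(end[bad[1]], scientific = FALSE),
                           format(start[bad[1]], scientific = FALSE)))
    }
    list(start = start - 1, end = end)
  } else {
    bad <- which(end <= start)
    if (length(bad)) {
      stop_at_line(path, lineno[bad[1]], "end <= start in 0-based half-open input")
    }
    list(start = start, end = end)
  }
}

# Drop rows on chromosomes absent from the build, with a logged count.
drop_unknown_chroms <- function(df, genome, path) {
  known <- df$chrom %in% genome$chrom
  if (!all(known)) {
    warning(sprintf("%s: dropped %d row(s) on chromosome(s) not in the genome build (%s)",
                    basename(path), sum(!known),
                    paste(unique(df$chrom[!known]), collapse = ", ")),
            call. = FALSE)
    df <- df[known, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a CNV call table
#'
#' TSV with header columns `chrom`, `start`, `end`, `sample`, `state`
#' (`gain`/`loss`), `inheritance` (`de_novo`/`maternal`/`paternal`/
#' `unknown`) and `cohort` (`case`/`control`/`decipher`); an optional
#' `cnv_id` column is kept, otherwise stable ids are generated.  Clinical
#' CNV tables are conventionally 1-based inclusive, the default; the
#' declared convention is converted to the internal 0-based half-open one
#' on read.  Rows on chromosomes missing from the build are dropped with a
#' warning; malformed rows raise an error naming the file line.
#'
#' @param path file path.
#' @param genome a [genome_build()].
#' @param coords coordinate convention of the file.
#' @return data.frame of CNV calls (`cnv_id`, `chrom`, `start`, `end`,
#'   `sample`, `state`, `inheritance`, `cohort`), in input order.
#' @export
read_cnv_table <- function(path, genome, coords = c("one_based", "zero_based")) {
  coords <- match.arg(coords)
  p <- parse_tsv(path, c("chrom", "start", "end", "sample", "state",
                         "inheritance", "cohort"))
  if (is.null(p$rows)) stop("empty CNV table: ", path, call. = FALSE)
  r <- p$rows
  start <- num_col(r$start, path, p$lineno, "start")
  end <- num_col(r$end, path, p$lineno, "end")
  for (col in c("state", "inheritance", "cohort")) {
    vocab <- switch(col, state = CNV_STATES, inheritance = CNV_INHERITANCE,
                    cohort = CNV_COHORTS)
    bad <- which(!r[[col]] %in% vocab)
    if (length(bad)) {
      stop_at_line(path, p$lineno[bad[1]],
                   sprintf("unknown %s token '%s'", col, r[[col]][bad[1]]))
    }
  }
  cc <- normalize_coords(start, end, coords, path, p$lineno)
  df <- data.frame(cnv_id = if ("cnv_id" %in% p$header) r$cnv_id else
                     sprintf("cnv_%04d", seq_along(start)),
                   chrom = r$chrom, start = cc$start, end = cc$end,
                   sample = r$sample, state = r$state,
                   inheritance = r$inheritance, cohort = r$cohort,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$cnv_id)) {
    stop(basename(path), ": duplicate cnv_id '",
         df$cnv_id[duplicated(df$cnv_id)][1], "'", call. = FALSE)
  }
  df <- drop_unknown_chroms(df, genome, path)
  validate_intervals(df, genome, "CNV")
  df
}

#' Write a CNV call table
#'
#' Inverse of [read_cnv_table()]; coordinates are denormalised to the
#' declared convention (default 1-based inclusive).
#'
#' @param cnvs CNV call data.frame.
#' @param path output path.
#' @param coords coordinate convention to write.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(cnvs, path, coords = c("one_based", "zero_based"),
                            seed = NULL) {
  coords <- match.arg(coords)
  out <- cnvs[, c("cnv_id", "chrom", "start", "end", "sample", "state",
                  "inheritance", "cohort")]
  if (coords == "one_based") out$start <- out$start + 1
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write_tsv_prov(out, path, seed = seed)
}

#' Read miRNA loci from a miRBase-dialect GFF3 file
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention.  The feature identifier is taken from the
#' attributes column (key configurable, default `Name`).  Records can be
#' restricted to one GFF3 `type` (e.g. `miRNA` for mature loci versus
#' `miRNA_primary_transcript` for hairpins); the default keeps all.
#'
#' @param path file path.
#' @param genome a [genome_build()].
#' @param id_key attribute key holding the feature id.
#' @param type optional GFF3 type filter.
#' @return data.frame of annotation features (`feature_id`, `chrom`,
#'   `start`, `end`, `strand`, `type`, `feature_class = "mirna"`).
#' @export
read_gff3_mirnas <- function(path, genome, id_key = "Name", type = NULL) {
  dat <- read_data_lines(path)
  empty <- data.frame(feature_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), type = character(),
                      feature_class = character(), stringsAsFactors = FALSE)
  if (length(dat$lines) == 0) return(empty)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad)) stop_at_line(path, dat$lineno[bad[1]], "expected 9 GFF3 columns")
  m <- do.call(rbind, fields)
  keep <- rep(TRUE, nrow(m))
  if (!is.null(type)) keep <- m[, 3] %in% type
  m <- m[keep, , drop = FALSE]
  lineno <- dat$lineno[keep]
  if (nrow(m) == 0) return(empty)

  ids <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    toks <- strsplit(m[i, 9], ";", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0 || any(!grepl("=", toks, fixed = TRUE))) {
      stop_at_line(path, lineno[i], "malformed attribute column")
    }
    kv <- regmatches(toks, regexpr("=", toks, fixed = TRUE), invert = TRUE)
    keys <- vapply(kv, `[[`, "", 1)
    hit <- match(id_key, keys)
    if (is.na(hit)) {
      stop_at_line(path, lineno[i],
                   sprintf("attribute key '%s' not found", id_key))
    }
    ids[i] <- vapply(kv, `[[`, "", 2)[hit]
  }
  start <- num_col(m[, 4], path, lineno, "start")
  end <- num_col(m[, 5], path, lineno, "end")
  cc <- normalize_coords(start, end, "one_based", path, lineno)
  df <- data.frame(feature_id = ids, chrom = m[, 1], start = cc$start,
                   end = cc$end, strand = m[, 7], type = m[, 3],
                   feature_class = "mirna", stringsAsFactors = FALSE)
  df <- drop_unknown_chroms(df, genome, path)
  if (anyDuplicated(df$feature_id)) {
    stop(basename(path), ": duplicate feature id '",
         df$feature_id[duplicated(df$feature_id)][1],
         "' (choose a unique id_key, e.g. the accession)", call. = FALSE)
  }
  validate_intervals(df, genome, "miRNA feature")
  df
}

#' Write miRNA loci as GFF3
#'
#' @param features miRNA feature data.frame (see [read_gff3_mirnas()]).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_gff3_mirnas <- function(features, path, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##gff-version 3", provenance_lines(seed)), con)
  if (nrow(features)) {
    lines <- sprintf("%s\tcnvmir\t%s\t%s\t%s\t.\t%s\t.\tName=%s",
                     features$chrom,
                     features$type %||% "miRNA",
                     format(features$start + 1, scientific = FALSE, trim = TRUE),
                     format(features$end, scientific = FALSE, trim = TRUE),
                     features$strand %||% ".",
                     features$feature_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read protein-coding gene loci from a BED file
#'
#' BED is 0-based half-open; the name column is the gene symbol,
#' case-normalised to upper case.  Duplicate symbols are an error.
#'
#' @param path file path.
#' @param genome a [genome_build()].
#' @return data.frame of annotation features (`feature_class = "pcg"`).
#' @export
read_bed_genes <- function(path, genome) {
  dat <- read_data_lines(path)
  dat$keep <- !grepl("^(track|browser)\\b", dat$lines)
  lines <- dat$lines[dat$keep]
  lineno <- dat$lineno[dat$keep]
  empty <- data.frame(feature_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), type = character(),
                      feature_class = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  if (length(bad)) stop_at_line(path, lineno[bad[1]], "expected at least 4 BED columns")
  m <- t(vapply(fields, function(f) f[1:4], character(4)))
  start <- num_col(m[, 2], path, lineno, "start")
  end <- num_col(m[, 3], path, lineno, "end")
  cc <- normalize_coords(start, end, "zero_based", path, lineno)
  df <- data.frame(feature_id = toupper(m[, 4]), chrom = m[, 1],
                   start = cc$start, end = cc$end, strand = ".",
                   type = "gene", feature_class = "pcg",
                   stringsAsFactors = FALSE)
  df <- drop_unknown_chroms(df, genome, path)
  if (anyDuplicated(df$feature_id)) {
    stop(basename(path), ": duplicate gene symbol '",
         df$feature_id[duplicated(df$feature_id)][1], "'", call. = FALSE)
  }
  validate_intervals(df, genome, "gene")
  df
}

#' Write gene loci as BED
#'
#' @param features gene feature data.frame (see [read_bed_genes()]).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_bed_genes <- function(features, path, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  if (nrow(features)) {
    writeLines(sprintf("%s\t%s\t%s\t%s", features$chrom,
                       format(features$start, scientific = FALSE, trim = TRUE),
                       format(features$end, scientific = FALSE, trim = TRUE),
                       features$feature_id), con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Symbols are upper-cased; empty sets and duplicate set names are errors.
#'
#' @param path file path.
#' @return named list of character vectors (gene ids), with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) {
    out <- list()
    attr(out, "description") <- character()
    return(out)
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop_at_line(path, dat$lineno[bad[1]], "gene set with no member genes")
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    stop(basename(path), ": duplicate gene-set name '",
         nm[duplicated(nm)][1], "'", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2), nm)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[names(sets)[i]]] %||% "na", sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-to-target-gene map
#'
#' TSV with header columns `mirna` and `gene`; one pair per row.  Pairs are
#' aggregated into a named list mapping each miRNA to its set of target
#' gene symbols (upper-cased); no empty target sets are stored.
#'
#' @param path file path.
#' @return named list: miRNA id -> character vector of target genes.
#' @export
read_target_map <- function(path) {
  p <- parse_tsv(path, c("mirna", "gene"))
  if (is.null(p$rows)) return(list())
  lapply(split(toupper(p$rows$gene), p$rows$mirna), unique)
}

#' Write a miRNA-to-target-gene map
#'
#' @param map named list (see [read_target_map()]).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(map, path, seed = NULL) {
  df <- data.frame(mirna = rep(names(map), lengths(map)),
                   gene = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, seed = seed)
}

#' Read a known-variant (DGV-style) table
#'
#' TSV needing only `chrom`, `start`, `end`, `study`, `variant_id` columns;
#' extra columns are ignored (DGV dialects vary across releases).  The
#' default coordinate convention is 1-based inclusive.
#'
#' @param path file path.
#' @param genome a [genome_build()].
#' @param coords coordinate convention of the file.
#' @return data.frame of known-variant records.
#' @export
read_known_variants <- function(path, genome,
                                coords = c("one_based", "zero_based")) {
  coords <- match.arg(coords)
  p <- parse_tsv(path, c("chrom", "start", "end", "study", "variant_id"))
  if (is.null(p$rows)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      study = character(), variant_id = character(),
                      stringsAsFactors = FALSE))
  }
  bad <- which(!nzchar(p$rows$study))
  if (length(bad)) stop_at_line(path, p$lineno[bad[1]], "empty study id")
  start <- num_col(p$rows$start, path, p$lineno, "start")
  end <- num_col(p$rows$end, path, p$lineno, "end")
  cc <- normalize_coords(start, end, coords, path, p$lineno)
  df <- data.frame(chrom = p$rows$chrom, start = cc$start, end = cc$end,
                   study = p$rows$study, variant_id = p$rows$variant_id,
                   stringsAsFactors = FALSE)
  df <- drop_unknown_chroms(df, genome, path)
  validate_intervals(df, genome, "known variant")
  df
}

#' Write a known-variant table
#'
#' @param known known-variant data.frame (see [read_known_variants()]).
#' @param path output path.
#' @param coords coordinate convention to write.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_known_variants <- function(known, path,
                                 coords = c("one_based", "zero_based"),
                                 seed = NULL) {
  coords <- match.arg(coords)
  out <- known[, c("chrom", "start", "end", "study", "variant_id")]
  if (coords == "one_based") out$start <- out$start + 1
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write_tsv_prov(out, path, seed = seed)
}

#' Read a miRNA expression/brain annotation table
#'
#' TSV with header columns `mirna`, `has_expression`, `brain_related` and
#' optionally `note`.  Flags accept `TRUE`/`FALSE` or `1`/`0`.  A
#' brain-related flag without expression data violates the annotation's
#' own definition and is an error.  This table replaces manual literature
#' curation: it is an input, not a computation.
#'
#' @param path file path.
#' @return data.frame with logical `has_expression`, `brain_related`.
#' @export
read_mirna_annotation <- function(path) {
  p <- parse_tsv(path, c("mirna", "has_expression", "brain_related"))
  if (is.null(p$rows)) {
    return(data.frame(mirna = character(), has_expression = logical(),
                      brain_related = logical(), note = character(),
                      stringsAsFactors = FALSE))
  }
  flag <- function(x, what) {
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "1")] <- TRUE
    out[x %in% c("FALSE", "false", "0")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad)) {
      stop_at_line(path, p$lineno[bad[1]],
                   sprintf("unparseable %s flag '%s'", what, x[bad[1]]))
    }
    out
  }
  df <- data.frame(mirna = p$rows$mirna,
                   has_expression = flag(p$rows$has_expression, "has_expression"),
                   brain_related = flag(p$rows$brain_related, "brain_related"),
                   note = if ("note" %in% p$header) p$rows$note else "",
                   stringsAsFactors = FALSE)
  bad <- which(df$brain_related & !df$has_expression)
  if (length(bad)) {
    stop_at_line(path, p$lineno[bad[1]],
                 sprintf("miRNA '%s' flagged brain-related without expression data",
                         df$mirna[bad[1]]))
  }
  if (anyDuplicated(df$mirna)) {
    stop(basename(path), ": duplicate miRNA id '",
         df$mirna[duplicated(df$mirna)][1], "'", call. = FALSE)
  }
  df
}

#' Write a miRNA annotation table
#'
#' @param ann annotation data.frame (see [read_mirna_annotation()]).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_mirna_annotation <- function(ann, path, seed = NULL) {
  out <- ann[, c("mirna", "has_expression", "brain_related")]
  out$note <- ann$note %||% ""
  write_tsv_prov(out, path, seed = seed)
}
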