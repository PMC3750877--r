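# Genome model: a chromosome-sizes table every interval is validated against.

#' Construct a genome build
#'
#' A genome build is the set of chromosome names and lengths that all
#' genomic intervals in an analysis are validated against.  Any assembly
#' can be supplied as a chromosome-sizes table.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-ish vector of chromosome lengths in base pairs.
#' @return a `genome_build` data.frame with columns `chrom`, `length`.
#' @export
#' @examples
#' genome_build(c("chr1", "chr2"), c(1e6, 5e5))
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("chrom and length must have equal length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0)) {
    stop("every chromosome length must be a positive number", call. = FALSE)
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_build", "data.frame"))
}

#' Read a chromosome-sizes file
#'
#' Two-column headerless TSV (`name<TAB>length`), the format emitted by
#' standard genome tooling.  Comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return a [genome_build()].
#' @export
read_genome <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) stop("empty chromosome-sizes file: ", path, call. = FALSE)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    stop_at_line(path, dat$lineno[bad[1]], "expected two tab-separated columns")
  }
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  bad <- which(is.na(len))
  if (length(bad)) stop_at_line(path, dat$lineno[bad[1]], "non-numeric chromosome length")
  genome_build(vapply(fields, `[[`, "", 1), len)
}

#' Write a chromosome-sizes file
#'
#' @param genome a [genome_build()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  df <- data.frame(chrom = genome$chrom,
                   length = format(genome$length, scientific = FALSE, trim = TRUE))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_lines(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_lengths <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome build: %d chromosome(s), %.1f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  NextMethod()
}

# Validate an interval data.frame (chrom/start/end, 0-based half-open)
# against a genome build.  Returns the data.frame invisibly.
validate_intervals <- function(df, genome, what = "interval") {
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(df$chrom), names(lens))
  if (length(unknown)) {
    stop(what, " on chromosome(s) not in the genome build: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- df$start < 0 | df$end <= df$start | df$end > lens[df$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid %s %s:%s-%s (need 0 <= start < end <= chromosome length)",
                 what, df$chrom[i], format(df$start[i], scientific = FALSE),
                 format(df$end[i], scientific = FALSE)), call. = FALSE)
  }
  invisible(df)
}
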