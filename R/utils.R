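# Shared helpers: reporting-layer rounding, provenance headers, TSV plumbing.

#' Round half away from zero
#'
#' Reporting-layer rounding used for all printed densities and percentages:
#' ties are rounded away from zero (so 0.645 -> 0.65, -0.645 -> -0.65),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(67 / 105.2, 2) # 0.64
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Comment lines stamped at the top of every emitted file so a report can be
# traced back to a package version and seed.  Deliberately time-free: the
# same inputs + seed must give byte-identical files.
provenance_lines <- function(seed = NULL) {
  out <- sprintf("# cnvmir %s", as.character(utils::packageVersion("cnvmir")))
  if (!is.null(seed)) {
    out <- c(out, sprintf("# seed: %s", format(seed, scientific = FALSE)))
  }
  out
}

# Write a data.frame as TSV with a provenance comment block.
write_tsv_prov <- function(df, path, seed = NULL, col.names = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

# Read the non-comment, non-empty lines of a text file, keeping the original
# file line number of each so parse errors can name it.
read_data_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

stop_at_line <- function(path, lineno, msg) {
  stop(sprintf("%s, line %d: %s", basename(path), lineno, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
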