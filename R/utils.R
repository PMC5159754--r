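# Shared helpers: provenance-aware table IO used by every module's file
# interface. Output tables carry "#key=value" comment lines so that results
# are self-describing; readers must therefore skip leading comment lines.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited table, skipping leading '#' comment lines
#'
#' @param path file path.
#' @param ... passed to [data.table::fread()].
#' @return a `data.table`.
#' @keywords internal
read_table_skip_comments <- function(path, ...) {
  con <- file(path, "r")
  on.exit(close(con))
  n_skip <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    n_skip <- n_skip + 1L
  }
  data.table::fread(path, skip = n_skip, header = TRUE, ...)
}

#' Write a table with a provenance header
#'
#' Prepends `#key=value` comment lines (package version always included) so
#' that seeds and parameters travel with every output file.
#'
#' @param x data.frame/data.table.
#' @param path output path.
#' @param provenance named list; values are collapsed with `format()`.
#' @keywords internal
write_table_with_header <- function(x, path, provenance = list()) {
  provenance <- c(list(gwamaqc = as.character(packageVersion("gwamaqc"))),
                  provenance)
  hdr <- vapply(seq_along(provenance), function(i) {
    sprintf("#%s=%s", names(provenance)[i],
            paste(format(provenance[[i]], trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(hdr, path)
  data.table::fwrite(x, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

# Complement of a nucleotide vector; used for strand-flip resolution.
dna_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# A/T and C/G SNPs cannot be strand-resolved from allele letters.
is_palindromic <- function(a1, a2) {
  dna_complement(a1) == a2
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
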