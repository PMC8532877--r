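# Small shared helpers. Coordinates are 0-based half-open internally; GTF is
# written 1-based inclusive and BED12 0-based half-open, matching each format.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# interval overlap length for 0-based half-open intervals
.ov_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

# deterministic local RNG scope: run `expr` under `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# write a data.frame as TSV (no quotes, no row names) -- shared output idiom
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Access a bundled reference table
#'
#' Small published summary tables from a goat skeletal-muscle
#' hybrid-sequencing study, shipped as TSV under `inst/extdata/`:
#' `"meat_quality_traits"`, `"ccs_library_summary"`, `"flnc_mapping_summary"`,
#' `"loci_length_bins"`, `"de_partition_counts"`, plus the frozen
#' `"coding_model_synthetic"` weights.
#'
#' @param name table name (without extension).
#' @return data.frame.
#' @export
reference_table <- function(name) {
  path <- system.file("extdata", paste0(name, ".tsv"), package = "isoforge")
  if (!nzchar(path)) .stopf("no bundled table named '%s'", name)
  utils::read.delim(path, check.names = FALSE)
}
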