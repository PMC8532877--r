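# CCS read classification: primer/polyA detection, the full-length /
# full-length non-chimeric (FLNC) rules, and the short-read QC filters.

#' Primer and read-length configuration for CCS classification
#'
#' @param primer5,primer3 cDNA primer sequences (length >= 8, distinct).
#'   `primer3` is given in its synthesis orientation; reads are scanned for
#'   its reverse complement at their 3' end.
#' @param max_mismatches Hamming mismatches tolerated per primer occurrence.
#' @param polya_min_length minimum polyA window length (bases).
#' @param polya_min_purity minimum A fraction within the window, in (0, 1].
#' @param min_read_length,max_read_length length bounds defining filtered
#'   short reads (defaults 50 and 15,000).
#' @return a list of class `primer_config`.
#' @export
primer_config <- function(primer5, primer3, max_mismatches = 2L,
                          polya_min_length = 20L, polya_min_purity = 0.9,
                          min_read_length = 50L, max_read_length = 15000L) {
  if (nchar(primer5) < 8L || nchar(primer3) < 8L)
    .stopf("primers must be at least 8 bases")
  if (identical(primer5, primer3)) .stopf("primers must be distinct")
  if (min_read_length >= max_read_length) .stopf("min_read_length must be < max")
  if (polya_min_purity <= 0 || polya_min_purity > 1)
    .stopf("polya_min_purity must lie in (0, 1]")
  structure(list(primer5 = primer5, primer3 = primer3,
                 max_mismatches = as.integer(max_mismatches),
                 polya_min_length = as.integer(polya_min_length),
                 polya_min_purity = polya_min_purity,
                 min_read_length = as.integer(min_read_length),
                 max_read_length = as.integer(max_read_length)),
            class = "primer_config")
}

# occurrences of `pattern` (Hamming <= mm) in a DNAStringSet; returns a list
# of integer start vectors (1-based)
.scan_primer <- function(seqs, pattern, mm) {
  hits <- Biostrings::vmatchPattern(pattern, seqs, max.mismatch = mm,
                                    fixed = TRUE)
  lapply(hits, IRanges::start)
}

#' Detect cDNA primers at read ends and internally
#'
#' The terminal windows (twice the primer length at each read end) are
#' scanned for the 5' primer and the reverse complement of the 3' primer
#' with up to `max_mismatches` Hamming mismatches; occurrences outside a
#' primer's own terminal window count as internal hits (the chimera signal).
#'
#' @param seqs character vector of read sequences.
#' @param primers a [primer_config()].
#' @return data.frame with `has_primer5`, `has_primer3`,
#'   `internal_primer_hits` and `primer3_pos` (1-based start of the terminal
#'   3'-primer occurrence, NA when absent).
#' @export
detect_primers <- function(seqs, primers) {
  stopifnot(inherits(primers, "primer_config"))
  if (any(!nzchar(seqs))) .stopf("empty read sequence")
  p5 <- primers$primer5
  p3rc <- revcomp(primers$primer3)
  w5 <- 2L * nchar(p5)
  w3 <- 2L * nchar(p3rc)
  ss <- Biostrings::DNAStringSet(seqs)
  len <- nchar(seqs)
  h5 <- .scan_primer(ss, p5, primers$max_mismatches)
  h3 <- .scan_primer(ss, p3rc, primers$max_mismatches)
  out <- data.frame(has_primer5 = logical(length(seqs)),
                    has_primer3 = logical(length(seqs)),
                    internal_primer_hits = integer(length(seqs)),
                    primer3_pos = NA_integer_)
  for (i in seq_along(seqs)) {
    s5 <- h5[[i]]; s3 <- h3[[i]]
    in5 <- s5 + nchar(p5) - 1L <= min(w5, len[i])      # within 5' window
    in3 <- s3 >= max(1L, len[i] - w3 + 1L)             # within 3' window
    out$has_primer5[i] <- any(in5)
    out$has_primer3[i] <- any(in3)
    out$internal_primer_hits[i] <- sum(!in5) + sum(!in3)
    if (any(in3)) out$primer3_pos[i] <- max(s3[in3])
  }
  out
}

#' Detect a polyA tail near the 3' primer
#'
#' TRUE when a window of `polya_min_length` bases with A fraction at least
#' `polya_min_purity` ends within 50 bases upstream of the 3' primer start
#' (or of the read end when the primer is absent), and the scanned tail
#' region holds at least `polya_min_length` A bases in total (so a 19-base
#' A run never passes a 20-base minimum, whatever the purity allowance).
#'
#' @param seqs character vector of read sequences.
#' @param primers a [primer_config()].
#' @param primer3_pos optional 1-based 3'-primer start per read (as returned
#'   by [detect_primers()]); detected when omitted.
#' @return logical vector.
#' @export
detect_polya <- function(seqs, primers, primer3_pos = NULL) {
  stopifnot(inherits(primers, "primer_config"))
  if (is.null(primer3_pos)) primer3_pos <- detect_primers(seqs, primers)$primer3_pos
  L <- primers$polya_min_length
  pur <- primers$polya_min_purity
  vapply(seq_along(seqs), function(i) {
    anchor <- if (is.na(primer3_pos[i])) nchar(seqs[i]) else primer3_pos[i] - 1L
    if (anchor < L) return(FALSE)
    lo <- max(1L, anchor - 50L - L + 1L)
    region <- substring(seqs[i], lo, anchor)
    v <- strsplit(region, "", fixed = TRUE)[[1]] == "A"
    if (length(v) < L || sum(v) < L) return(FALSE)
    cs <- c(0L, cumsum(v))
    n <- length(v)
    frac <- (cs[(L + 1L):(n + 1L)] - cs[1L:(n - L + 1L)]) / L
    any(frac >= pur)
  }, logical(1))
}

#' Classify CCS reads into the full-length categories
#'
#' Reads outside the `[min_read_length, max_read_length]` window are
#' `filtered_short`; otherwise a read is `full_length` when it carries the 5'
#' primer, the 3' primer and a polyA tail, else `non_full_length`. Full-length
#' reads without internal primer copies are additionally flagged FLNC
#' (full-length non-chimeric). The three categories partition the input.
#'
#' @param reads data.frame with columns `length`, `has_primer5`,
#'   `has_primer3`, `has_polya`, `internal_primer_hits` (see
#'   [classify_reads()] for the one-call pipeline).
#' @param primers a [primer_config()].
#' @return `reads` with `category` (factor: `filtered_short`,
#'   `non_full_length`, `full_length`) and logical `is_flnc` appended.
#' @export
classify_ccs <- function(reads, primers) {
  stopifnot(inherits(primers, "primer_config"))
  need <- c("length", "has_primer5", "has_primer3", "has_polya",
            "internal_primer_hits")
  if (!all(need %in% names(reads)))
    .stopf("reads must have columns: %s", paste(need, collapse = ", "))
  flags <- reads[c("has_primer5", "has_primer3", "has_polya")]
  if (any(is.na(unlist(flags))))
    .stopf("primer/polyA detection flags must be set before classification")
  short <- reads$length < primers$min_read_length |
    reads$length > primers$max_read_length
  fl <- reads$has_primer5 & reads$has_primer3 & reads$has_polya
  category <- ifelse(short, "filtered_short",
                     ifelse(fl, "full_length", "non_full_length"))
  reads$category <- factor(category, levels = c("filtered_short",
                                                "non_full_length",
                                                "full_length"))
  reads$is_flnc <- !short & fl & reads$internal_primer_hits == 0L
  reads
}

#' Classify read sequences end-to-end
#'
#' Runs [detect_primers()], [detect_polya()] and [classify_ccs()] on raw
#' sequences.
#'
#' @param seqs named character vector of read sequences.
#' @param primers a [primer_config()].
#' @return per-read data.frame: `read_id`, `length`, detection flags,
#'   `category`, `is_flnc`.
#' @export
classify_reads <- function(seqs, primers) {
  det <- detect_primers(seqs, primers)
  det$has_polya <- detect_polya(seqs, primers, det$primer3_pos)
  det$read_id <- names(seqs) %||% sprintf("read%06d", seq_along(seqs))
  det$length <- nchar(seqs)
  out <- classify_ccs(det, primers)
  out[c("read_id", "length", "has_primer5", "has_primer3", "has_polya",
        "internal_primer_hits", "category", "is_flnc")]
}

#' Library-level summary of CCS classification
#'
#' One row shaped like the per-library CCS classification tables of Iso-Seq
#' studies. Primer/polyA tallies are counted over all CCS, before length
#' filtering.
#'
#' @param per_read output of [classify_reads()].
#' @return one-row data.frame: `ccs`, `five_prime_reads`, `three_prime_reads`,
#'   `polya_reads`, `filtered_short`, `non_full_length`, `full_length`,
#'   `flnc`, `mean_flnc_length`.
#' @export
summarize_read_classes <- function(per_read) {
  tab <- table(per_read$category)
  data.frame(
    ccs = nrow(per_read),
    five_prime_reads = sum(per_read$has_primer5),
    three_prime_reads = sum(per_read$has_primer3),
    polya_reads = sum(per_read$has_polya),
    filtered_short = as.integer(tab[["filtered_short"]]),
    non_full_length = as.integer(tab[["non_full_length"]]),
    full_length = as.integer(tab[["full_length"]]),
    flnc = sum(per_read$is_flnc),
    mean_flnc_length = if (any(per_read$is_flnc))
      round(mean(per_read$length[per_read$is_flnc]), 1) else NA_real_)
}

#' Short-read quality filter
#'
#' Discards a read when an adaptor occurrence is found, when unknown bases
#' (N) exceed 10% of its length, or when more than 50% of bases fall below
#' the Phred quality floor.
#'
#' @param seqs character vector of read sequences.
#' @param quals qualities, either Phred+33 strings or a list of numeric
#'   vectors, same lengths as `seqs`.
#' @param adapters optional character vector of adaptor sequences (exact
#'   match).
#' @param quality_floor Phred score below which a base is low-quality
#'   (default 20).
#' @param max_n_frac maximum tolerated N fraction (default 0.10, exclusive).
#' @param max_lowq_frac maximum tolerated low-quality fraction (default
#'   0.50, exclusive).
#' @return logical keep flags.
#' @export
filter_short_reads <- function(seqs, quals, adapters = NULL,
                               quality_floor = 20L, max_n_frac = 0.10,
                               max_lowq_frac = 0.50) {
  qnum <- if (is.character(quals)) {
    lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
  } else quals
  if (any(lengths(qnum) != nchar(seqs)))
    .stopf("qualities must match sequence lengths")
  vapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    n <- nchar(s)
    if (!is.null(adapters) &&
        any(vapply(adapters, function(a) grepl(a, s, fixed = TRUE),
                   logical(1))))
      return(FALSE)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    if (sum(v %in% c("N", "n")) / n > max_n_frac) return(FALSE)
    if (sum(qnum[[i]] < quality_floor) / n > max_lowq_frac) return(FALSE)
    TRUE
  }, logical(1))
}
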