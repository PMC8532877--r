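# Transcript models: the atom of loci clustering, isoform collapse and AS
# analysis. A transcript_set is a data.frame with one row per transcript and a
# list-column `exons` of 2-column integer matrices (start, end), 0-based
# half-open, sorted, non-overlapping.

#' Construct a set of transcript models
#'
#' The central container of the catalogue stages: a stranded exon chain per
#' transcript. Internally all coordinates are 0-based half-open; [write_gtf()]
#' and [write_bed12()] convert to the conventions of each format.
#'
#' @param transcript_id character vector of unique ids.
#' @param chrom chromosome name per transcript.
#' @param strand `"+"` or `"-"` per transcript.
#' @param exons list of integer matrices with columns `start`, `end`
#'   (0-based half-open), rows sorted by `start` and non-overlapping.
#' @param gene_id optional gene assignment (NA when not yet clustered).
#' @param support_count number of supporting FLNC reads (default 1).
#' @param support_pid best local percent identity among supporting reads
#'   (NA when unknown).
#' @return a `data.frame` of class `transcript_set` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (list),
#'   `support_count`, `support_pid`.
#' @export
transcript_set <- function(transcript_id, chrom, strand, exons,
                           gene_id = NA_character_,
                           support_count = 1L, support_pid = NA_real_) {
  n <- length(transcript_id)
  if (anyDuplicated(transcript_id)) .stopf("transcript ids must be unique")
  if (!all(strand %in% c("+", "-"))) .stopf("strand must be '+' or '-'")
  if (length(exons) != n) .stopf("one exon matrix per transcript required")
  exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    if (nrow(e) == 0L) .stopf("empty exon chain")
    if (any(e[, 2L] <= e[, 1L])) .stopf("zero or negative length exon")
    e <- e[order(e[, 1L]), , drop = FALSE]
    if (nrow(e) > 1L && any(e[-1L, 1L] < e[-nrow(e), 2L]))
      .stopf("overlapping exons in one transcript")
    e
  })
  out <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = rep_len(as.character(gene_id), n),
    chrom = rep_len(as.character(chrom), n),
    strand = rep_len(as.character(strand), n),
    support_count = rep_len(as.integer(support_count), n),
    support_pid = rep_len(as.numeric(support_pid), n),
    stringsAsFactors = FALSE
  )
  out$exons <- exons
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  ne <- vapply(x$exons, nrow, integer(1))
  cat(sprintf("  multi-exon: %d  mono-exon: %d\n", sum(ne > 1), sum(ne == 1)))
  invisible(x)
}

# spliced length = sum of exon widths
spliced_length <- function(exons) sum(exons[, 2L] - exons[, 1L])

# genomic span (start of first exon, end of last), 0-based half-open
tx_span <- function(exons) c(exons[1L, 1L], exons[nrow(exons), 2L])

# introns as a 2-col matrix (0-based half-open); 0 rows for mono-exon
tx_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
}

# canonical string key of an intron chain (isoform identity after collapse)
chain_key <- function(chrom, strand, exons) {
  intr <- tx_introns(exons)
  if (nrow(intr) == 0L)
    return(sprintf("%s:%s:mono", chrom, strand))
  sprintf("%s:%s:%s", chrom, strand,
          paste(intr[, 1L], intr[, 2L], sep = "-", collapse = ","))
}

# splice donors/acceptors in genome coordinates, strand aware:
# '+' donor = intron start, acceptor = intron end;
# '-' donor = intron end,  acceptor = intron start.
splice_sites <- function(strand, exons) {
  intr <- tx_introns(exons)
  if (nrow(intr) == 0L)
    return(data.frame(pos = integer(0), kind = character(0)))
  if (strand == "+") {
    data.frame(pos = c(intr[, 1L], intr[, 2L]),
               kind = rep(c("donor", "acceptor"), each = nrow(intr)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = c(intr[, 2L], intr[, 1L]),
               kind = rep(c("donor", "acceptor"), each = nrow(intr)),
               stringsAsFactors = FALSE)
  }
}

# 5'-most splice donor of a multi-exon transcript (genome coordinate)
first_donor <- function(strand, exons) {
  intr <- tx_introns(exons)
  if (nrow(intr) == 0L) return(NA_integer_)
  if (strand == "+") intr[1L, 1L] else intr[nrow(intr), 2L]
}

# ---- interchange with GenomicRanges / standard formats ---------------------

#' Convert a transcript_set to a GRangesList of exons
#'
#' @param ts a [transcript_set()].
#' @return a [GenomicRanges::GRangesList] named by transcript id, 1-based.
#' @export
as_grangeslist <- function(ts) {
  grl <- lapply(seq_len(nrow(ts)), function(i) {
    e <- ts$exons[[i]]
    GenomicRanges::GRanges(ts$chrom[i],
                           IRanges::IRanges(e[, 1L] + 1L, e[, 2L]),
                           strand = ts$strand[i])
  })
  names(grl) <- ts$transcript_id
  GenomicRanges::GRangesList(grl)
}

#' Write transcript models as GTF
#'
#' One `exon` feature per exon with `gene_id`/`transcript_id` attributes,
#' 1-based inclusive coordinates (via rtracklayer).
#'
#' @param ts a [transcript_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path) {
  rows <- lapply(seq_len(nrow(ts)), function(i) {
    e <- ts$exons[[i]]
    GenomicRanges::GRanges(
      ts$chrom[i], IRanges::IRanges(e[, 1L] + 1L, e[, 2L]),
      strand = ts$strand[i], type = "exon",
      gene_id = if (is.na(ts$gene_id[i])) ts$transcript_id[i] else ts$gene_id[i],
      transcript_id = ts$transcript_id[i])
  })
  gr <- do.call(c, rows)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Keeps `exon` features and assembles one exon chain per `transcript_id`.
#'
#' @param path GTF file.
#' @return a [transcript_set()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[is.na(gr$type) | tolower(as.character(gr$type)) == "exon"]
  txid <- as.character(gr$transcript_id)
  ord <- order(txid, GenomicRanges::start(gr))
  gr <- gr[ord]; txid <- txid[ord]
  idx <- split(seq_along(gr), txid)
  exons <- lapply(idx, function(i)
    cbind(start = GenomicRanges::start(gr)[i] - 1L,
          end = GenomicRanges::end(gr)[i]))
  firsts <- vapply(idx, `[`, integer(1), 1L)
  transcript_set(
    transcript_id = names(idx),
    chrom = as.character(GenomicRanges::seqnames(gr))[firsts],
    strand = as.character(GenomicRanges::strand(gr))[firsts],
    exons = exons,
    gene_id = as.character(gr$gene_id)[firsts])
}

#' Write transcript models (or read placements) as BED12
#'
#' @param ts a [transcript_set()]; `transcript_id` becomes the BED name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(ts, path) {
  bed <- rtracklayer::asBED(as_grangeslist(ts))
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Read BED12 into a transcript_set
#'
#' @param path BED12 file; block fields define the exon chain.
#' @return a [transcript_set()].
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  exons <- lapply(seq_along(gr), function(i) {
    b <- gr$blocks[[i]]
    off <- GenomicRanges::start(gr)[i] - 1L  # 0-based chrom start
    cbind(start = off + IRanges::start(b) - 1L, end = off + IRanges::end(b))
  })
  transcript_set(
    transcript_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exons = exons)
}

#' Spliced (mature) sequence of each transcript
#'
#' Concatenates exon sequence in genome order and reverse-complements for
#' minus-strand transcripts, returning the 5'->3' transcript sequence.
#'
#' @param ts a [transcript_set()].
#' @param genome named character vector (or [Biostrings::DNAStringSet]) of
#'   chromosome sequences.
#' @return named character vector of transcript sequences.
#' @export
transcript_sequences <- function(ts, genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  out <- vapply(seq_len(nrow(ts)), function(i) {
    chr <- genome[[ts$chrom[i]]]
    e <- ts$exons[[i]]
    s <- paste(substring(chr, e[, 1L] + 1L, e[, 2L]), collapse = "")
    if (ts$strand[i] == "-") revcomp(s) else s
  }, character(1))
  names(out) <- ts$transcript_id
  out
}
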