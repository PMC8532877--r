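# Alignment quality triage: percent identity (global/local), the four
# mapping categories, merging of pre-/post-error-correction rounds, and
# per-exon read coverage.

#' Global and local percent identity of an alignment
#'
#' Local PID uses the aligned columns as denominator, global PID the full
#' read length, so `global_pid <= local_pid` always.
#'
#' @param matches matching columns per alignment.
#' @param aligned_columns aligned columns (matches + mismatches + gaps).
#' @param read_length full read length (bases).
#' @return data.frame with `global_pid` and `local_pid` (percent).
#' @export
compute_pid <- function(matches, aligned_columns, read_length) {
  if (any(aligned_columns <= 0)) .stopf("aligned_columns must be positive")
  if (any(matches > aligned_columns))
    .stopf("matches cannot exceed aligned columns")
  if (any(matches > read_length))
    .stopf("matches cannot exceed read length")
  data.frame(global_pid = 100 * matches / read_length,
             local_pid = 100 * matches / aligned_columns)
}

.aln_levels <- c("unmapped", "multiple_best", "low_pid", "high_quality")

#' Classify reads by their genome placements
#'
#' A read with no placement is `unmapped`; with two or more placements tied
#' for the best score (within `tie_frac`) it is `multiple_best`; a unique
#' best placement below the local-PID threshold is `low_pid`, otherwise
#' `high_quality`. The four categories partition the read universe.
#'
#' @param alignments data.frame of placements with columns `read_id`,
#'   `score` and `local_pid` (zero rows allowed).
#' @param reads character vector: the read universe (ids without placements
#'   become `unmapped`).
#' @param pid_threshold local PID below which a unique best placement is
#'   `low_pid` (percent, default 90).
#' @param tie_frac scores within this fraction of the best are ties
#'   (default 0.01).
#' @return data.frame `read_id`, `category` (factor), `local_pid` of the
#'   best placement (NA when unmapped).
#' @export
classify_alignments <- function(alignments, reads, pid_threshold = 90,
                                tie_frac = 0.01) {
  if (pid_threshold <= 0 || pid_threshold >= 100)
    .stopf("pid_threshold must lie in (0, 100)")
  out <- data.frame(read_id = reads,
                    category = factor("unmapped", levels = .aln_levels),
                    local_pid = NA_real_, stringsAsFactors = FALSE)
  if (nrow(alignments)) {
    sp <- split(alignments[c("score", "local_pid")], alignments$read_id)
    for (rid in names(sp)) {
      i <- match(rid, out$read_id)
      if (is.na(i)) next
      a <- sp[[rid]]
      best <- max(a$score)
      ties <- a$score >= (1 - tie_frac) * best
      if (sum(ties) >= 2L) {
        out$category[i] <- "multiple_best"
        out$local_pid[i] <- max(a$local_pid[ties])
      } else {
        bp <- a$local_pid[which.max(a$score)]
        out$local_pid[i] <- bp
        out$category[i] <- if (bp < pid_threshold) "low_pid" else "high_quality"
      }
    }
  }
  out
}

#' Merge pre- and post-correction alignment rounds
#'
#' Per read, the round with the better category wins under the ranking
#' `high_quality > low_pid > multiple_best > unmapped`; ties go to the higher
#' local PID. Reads present in only one round count as `unmapped` in the
#' other, so merging never decreases the high-quality count.
#'
#' @param pre,post data.frames as returned by [classify_alignments()].
#' @return merged data.frame of the same shape over the union of reads.
#' @export
merge_rounds <- function(pre, post) {
  ids <- union(pre$read_id, post$read_id)
  rank_of <- function(df) {
    i <- match(ids, df$read_id)
    list(rank = ifelse(is.na(i), 1L,
                       match(as.character(df$category[i]), .aln_levels)),
         pid = ifelse(is.na(i), -Inf,
                      ifelse(is.na(df$local_pid[i]), -Inf, df$local_pid[i])),
         cat = ifelse(is.na(i), "unmapped", as.character(df$category[i])))
  }
  a <- rank_of(pre); b <- rank_of(post)
  take_post <- b$rank > a$rank | (b$rank == a$rank & b$pid > a$pid)
  data.frame(
    read_id = ids,
    category = factor(ifelse(take_post, b$cat, a$cat), levels = .aln_levels),
    local_pid = {
      p <- ifelse(take_post, b$pid, a$pid)
      ifelse(is.finite(p), p, NA_real_)
    },
    stringsAsFactors = FALSE)
}

#' Tabulate alignment categories with percentages
#'
#' @param x factor of categories (from [classify_alignments()] /
#'   [merge_rounds()]) or a named integer vector of counts.
#' @param digits decimal places for percentages (default 2).
#' @return data.frame `category`, `count`, `percent` in the fixed order
#'   unmapped, multiple_best, low_pid, high_quality.
#' @export
summarize_alignment_classes <- function(x, digits = 2) {
  counts <- if (is.factor(x) || is.character(x)) {
    table(factor(as.character(x), levels = .aln_levels))
  } else {
    if (is.null(names(x)) || !all(names(x) %in% .aln_levels))
      .stopf("counts must be named by alignment category")
    y <- setNames(rep(0L, length(.aln_levels)), .aln_levels)
    y[names(x)] <- x
    y
  }
  counts <- as.integer(counts)
  data.frame(category = .aln_levels, count = counts,
             percent = round(100 * counts / sum(counts), digits))
}

#' Per-exon read coverage and its histogram
#'
#' Coverage of an exon is the percentage of its bases overlapped by at least
#' one aligned block (strand-agnostic), histogrammed in ten-percent bins
#' `[0,10) ... [90,100]`.
#'
#' @param alignments a [transcript_set()] of read placements.
#' @param annotation a [transcript_set()] of reference transcripts.
#' @return list with `per_exon` (chrom, start, end, transcript_id, coverage
#'   percent) and `histogram` (named counts over the ten bins).
#' @export
exon_coverage <- function(alignments, annotation) {
  if (nrow(annotation) == 0L) .stopf("annotation must be non-empty")
  blocks <- function(ts) {
    n_ex <- vapply(ts$exons, nrow, integer(1))
    GenomicRanges::GRanges(
      rep(ts$chrom, n_ex),
      IRanges::IRanges(unlist(lapply(ts$exons, `[`, , 1L)) + 1L,
                       unlist(lapply(ts$exons, `[`, , 2L))))
  }
  cov <- GenomicRanges::reduce(blocks(alignments))
  ex <- blocks(annotation)
  hits <- GenomicRanges::findOverlaps(ex, cov)
  ovw <- GenomicRanges::width(GenomicRanges::pintersect(
    ex[S4Vectors::queryHits(hits)], cov[S4Vectors::subjectHits(hits)]))
  covered <- numeric(length(ex))
  agg <- tapply(ovw, S4Vectors::queryHits(hits), sum)
  covered[as.integer(names(agg))] <- agg
  pct <- 100 * covered / GenomicRanges::width(ex)
  n_ex <- vapply(annotation$exons, nrow, integer(1))
  per_exon <- data.frame(
    chrom = rep(annotation$chrom, n_ex),
    start = unlist(lapply(annotation$exons, `[`, , 1L)),
    end = unlist(lapply(annotation$exons, `[`, , 2L)),
    transcript_id = rep(annotation$transcript_id, n_ex),
    coverage = pct, stringsAsFactors = FALSE)
  histogram <- table(cut(pct, breaks = seq(0, 100, 10), right = FALSE,
                         include.lowest = TRUE))
  list(per_exon = per_exon, histogram = histogram)
}
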