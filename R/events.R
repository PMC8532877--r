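# Alternative splicing events between isoforms of one locus, alternative
# polyadenylation sites from FLNC 3' ends, and fusion candidates from split
# read placements.

# events between one ordered pair of exon chains (genome coordinates);
# returns a data.frame of (type, start, end)
.pair_events <- function(ex_a, ex_b, strand) {
  ia <- tx_introns(ex_a); ib <- tx_introns(ex_b)
  ev <- list()
  add <- function(type, s, e)
    ev[[length(ev) + 1L]] <<- data.frame(type = type, start = s, end = e,
                                         stringsAsFactors = FALSE)
  # ES: an internal exon of one chain absent from the other while the outer
  # boundaries of its flanking introns match (the other chain has the single
  # "skip" intron spanning the exon)
  es_pairs <- matrix(integer(0), ncol = 4L)  # skip-intron coords per side
  es_scan <- function(exq, iq, it) {
    nq <- nrow(exq)
    if (nq < 3L || nrow(it) == 0L) return()
    for (k in 2L:(nq - 1L)) {
      d1 <- iq[k - 1L, 1L]; a2 <- iq[k, 2L]
      if (any(it[, 1L] == d1 & it[, 2L] == a2)) {
        add("ES", exq[k, 1L], exq[k, 2L])
        es_pairs <<- rbind(es_pairs,
                           c(d1, iq[k - 1L, 2L], iq[k, 1L], a2))
      }
    }
  }
  es_scan(ex_a, ia, ib)
  es_scan(ex_b, ib, ia)
  # AA/AD: intron pairs sharing one boundary; skip pairs explained by an ES
  # (the skip intron vs either flanking intron of the skipped exon)
  is_es_pair <- function(s1, e1, s2, e2) {
    if (nrow(es_pairs) == 0L) return(FALSE)
    any((es_pairs[, 1L] == s1 | es_pairs[, 1L] == s2) &
          (es_pairs[, 4L] == e1 | es_pairs[, 4L] == e2) &
          (s1 == s2 | e1 == e2))
  }
  if (nrow(ia) && nrow(ib)) {
    for (p in seq_len(nrow(ia))) for (q in seq_len(nrow(ib))) {
      s1 <- ia[p, 1L]; e1 <- ia[p, 2L]; s2 <- ib[q, 1L]; e2 <- ib[q, 2L]
      if (s1 == s2 && e1 != e2 && !is_es_pair(s1, e1, s2, e2)) {
        # shared low boundary: donor on '+', acceptor on '-'
        add(if (strand == "+") "AA" else "AD", min(e1, e2), max(e1, e2))
      } else if (e1 == e2 && s1 != s2 && !is_es_pair(s1, e1, s2, e2)) {
        add(if (strand == "+") "AD" else "AA", min(s1, s2), max(s1, s2))
      }
    }
  }
  # IR: an intron of one chain fully inside an exon of the other
  ir_scan <- function(intr, exo) {
    if (nrow(intr) == 0L) return()
    for (p in seq_len(nrow(intr)))
      if (any(exo[, 1L] <= intr[p, 1L] & exo[, 2L] >= intr[p, 2L]))
        add("IR", intr[p, 1L], intr[p, 2L])
  }
  ir_scan(ia, ex_b)
  ir_scan(ib, ex_a)
  if (length(ev) == 0L)
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0)))
  do.call(rbind, ev)
}

#' Enumerate alternative-splicing events within loci
#'
#' Compares every isoform pair of each locus and reports exon skipping (ES),
#' alternative acceptor (AA), alternative donor (AD) and intron retention
#' (IR) events, deduplicated by (type, coordinates). Event coordinates are
#' the skipped exon (ES), the interval between the alternative boundaries
#' (AA/AD) or the retained intron (IR). `n_pairs` counts how many isoform
#' pairs exhibit each deduplicated event.
#'
#' @param isoforms output of [collapse_isoforms()] (or any data.frame with
#'   `isoform_id`, `locus_id`, `chrom`, `strand` and an `exons` list-column).
#' @return data.frame: `locus_id`, `type`, `start`, `end`, `isoform_a`,
#'   `isoform_b` (first pair observed), `n_pairs`.
#' @export
enumerate_as_events <- function(isoforms) {
  empty <- data.frame(locus_id = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      isoform_a = character(0), isoform_b = character(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE)
  out <- list()
  for (ii in split(seq_len(nrow(isoforms)), isoforms$locus_id)) {
    if (length(ii) < 2L) next
    seen <- new.env(parent = emptyenv())
    for (a in seq_along(ii)) for (b in seq_along(ii)[-seq_len(a)]) {
      i <- ii[a]; j <- ii[b]
      ev <- .pair_events(isoforms$exons[[i]], isoforms$exons[[j]],
                         isoforms$strand[i])
      if (nrow(ev) == 0L) next
      ev <- unique(ev)
      for (k in seq_len(nrow(ev))) {
        key <- sprintf("%s:%d-%d", ev$type[k], ev$start[k], ev$end[k])
        if (exists(key, envir = seen)) {
          rec <- get(key, envir = seen)
          rec$n_pairs <- rec$n_pairs + 1L
          assign(key, rec, envir = seen)
        } else {
          assign(key, data.frame(
            locus_id = isoforms$locus_id[i], type = ev$type[k],
            start = ev$start[k], end = ev$end[k],
            isoform_a = isoforms$isoform_id[i],
            isoform_b = isoforms$isoform_id[j],
            n_pairs = 1L, stringsAsFactors = FALSE), envir = seen)
        }
      }
    }
    keys <- sort(ls(envir = seen))
    if (length(keys))
      out[[length(out) + 1L]] <- do.call(rbind, lapply(keys, get,
                                                       envir = seen))
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$locus_id, res$type, res$start, res$end), ]
}

#' Summarize alternative-splicing events
#'
#' @param events output of [enumerate_as_events()].
#' @return list with `counts` (named, ES/AA/AD/IR) and `ir_fraction`
#'   (IR / total; NA with a warning when there are no events).
#' @export
as_summary <- function(events) {
  counts <- table(factor(events$type, levels = c("ES", "AA", "AD", "IR")))
  total <- sum(counts)
  ir_fraction <- if (total == 0L) {
    warning("no AS events: IR fraction undefined", call. = FALSE)
    NA_real_
  } else as.integer(counts[["IR"]]) / total
  list(counts = c(counts), ir_fraction = ir_fraction)
}

#' Detect alternative polyadenylation sites from FLNC 3' ends
#'
#' Strand-resolved 3'-end positions of a locus are clustered by
#' single-linkage within `window` bases; each cluster is summarized at its
#' support-weighted mode (ties to the lower coordinate) and clusters with
#' fewer than `min_support` reads are dropped. A locus retaining two or more
#' sites is an APA locus. Output is invariant to input ordering.
#'
#' @param ends data.frame with columns `locus_id` and `end_pos` (genomic 3'
#'   end per FLNC read).
#' @param window clustering window in bases (default 20).
#' @param min_support minimum FLNC support per retained site (default 2).
#' @return list with `sites` (`locus_id`, `position`, `support`) and
#'   `apa_loci` (locus ids with >= 2 retained sites).
#' @export
detect_apa <- function(ends, window = 20L, min_support = 2L) {
  sites <- list()
  by_locus <- split(ends$end_pos, ends$locus_id)
  for (lid in names(by_locus)) {
    pos <- sort(by_locus[[lid]])
    brk <- c(0L, which(diff(pos) > window), length(pos))
    for (k in seq_len(length(brk) - 1L)) {
      cl <- pos[(brk[k] + 1L):brk[k + 1L]]
      if (length(cl) < min_support) next
      tab <- table(cl)
      sites[[length(sites) + 1L]] <- data.frame(
        locus_id = lid, position = as.integer(names(tab)[which.max(tab)]),
        support = length(cl), stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites)
  else data.frame(locus_id = character(0), position = integer(0),
                  support = integer(0), stringsAsFactors = FALSE)
  tab <- table(sites$locus_id)
  list(sites = sites, apa_loci = sort(names(tab)[tab >= 2L]))
}

#' Detect fusion candidates from split read placements
#'
#' A read supports a fusion when it splits into two non-overlapping segments
#' (in read coordinates), each at least `min_seg_frac` of the read, mapping
#' to two distinct loci (or chromosomes), with combined coverage of at least
#' `min_cov` of the read. Partners are ordered by read orientation: the
#' segment nearer the read 5' end is the 5' partner.
#'
#' @param segments data.frame with columns `read_id`, `read_start`,
#'   `read_end` (0-based half-open read coordinates), `read_length`,
#'   `chrom`, `locus_id`.
#' @param min_seg_frac minimum segment fraction of read length (default 0.1).
#' @param min_cov minimum combined coverage fraction (default 0.9).
#' @return data.frame: `read_id`, `partner_5prime`, `partner_3prime`,
#'   `breakpoint` (read coordinate between the segments).
#' @export
detect_fusion <- function(segments, min_seg_frac = 0.1, min_cov = 0.9) {
  out <- list()
  for (ii in split(seq_len(nrow(segments)), segments$read_id)) {
    if (length(ii) < 2L) next
    s <- segments[ii, ]
    s <- s[order(s$read_start), ]
    len <- s$read_length[1L]
    for (a in seq_len(nrow(s) - 1L)) for (b in (a + 1L):nrow(s)) {
      if (s$read_end[a] > s$read_start[b]) next           # overlap in read
      if (s$locus_id[a] == s$locus_id[b] && s$chrom[a] == s$chrom[b]) next
      wa <- s$read_end[a] - s$read_start[a]
      wb <- s$read_end[b] - s$read_start[b]
      if (wa < min_seg_frac * len || wb < min_seg_frac * len) next
      if ((wa + wb) / len < min_cov) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = s$read_id[1L],
        partner_5prime = s$locus_id[a], partner_3prime = s$locus_id[b],
        breakpoint = s$read_end[a], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), partner_5prime = character(0),
                      partner_3prime = character(0), breakpoint = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
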