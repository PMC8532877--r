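# Transcript cataloguing: strand-aware clustering of alignments into loci,
# intron-chain collapse of redundant isoforms, full-length flags, and
# known/novel calls against a reference annotation.

# union-find with path compression (loci = connected components of the
# pairwise linkage relation)
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# linkage rule: same strand AND span overlap >= span_frac of the denominator
# span AND at least one exon pair overlapping > exon_frac of the shorter exon
.linked <- function(ex_a, ex_b, span_frac, exon_frac, denom) {
  sa <- tx_span(ex_a); sb <- tx_span(ex_b)
  ov <- .ov_len(sa[1L], sa[2L], sb[1L], sb[2L])
  if (ov <= 0L) return(FALSE)
  la <- sa[2L] - sa[1L]; lb <- sb[2L] - sb[1L]
  den <- switch(denom,
                shorter = min(la, lb),
                longer = max(la, lb),
                union = max(sa[2L], sb[2L]) - min(sa[1L], sb[1L]))
  if (ov / den < span_frac) return(FALSE)
  for (i in seq_len(nrow(ex_a))) {
    eov <- .ov_len(ex_a[i, 1L], ex_a[i, 2L], ex_b[, 1L], ex_b[, 2L])
    mins <- pmin(ex_a[i, 2L] - ex_a[i, 1L], ex_b[, 2L] - ex_b[, 1L])
    if (any(eov / mins > exon_frac)) return(TRUE)
  }
  FALSE
}

#' Cluster transcript alignments into loci
#'
#' Two transcripts are directly linked when they share the alignment
#' direction (strand), their spans overlap by at least `span_frac` of the
#' denominator span (default: the shorter), and at least one exon pair
#' overlaps by more than `exon_frac` of the shorter exon. Loci are the
#' connected components of this relation.
#'
#' @param ts a [transcript_set()].
#' @param span_frac span-overlap fraction threshold (default 0.2, reached
#'   counts).
#' @param exon_frac exon-overlap fraction threshold (default 0.2, strict).
#' @param denom denominator of the span rule: `"shorter"` (default),
#'   `"longer"` or `"union"`.
#' @return list with `transcripts` (`ts` plus a `locus_id` column) and
#'   `loci` (locus_id, chrom, strand, start, end, n_transcripts).
#' @export
cluster_loci <- function(ts, span_frac = 0.2, exon_frac = 0.2,
                         denom = c("shorter", "longer", "union")) {
  denom <- match.arg(denom)
  n <- nrow(ts)
  parent <- .uf_new(n)
  key <- paste(ts$chrom, ts$strand)
  spans <- t(vapply(ts$exons, tx_span, integer(2)))
  for (grp in split(seq_len(n), key)) {
    grp <- grp[order(spans[grp, 1L])]
    for (ai in seq_along(grp)) {
      i <- grp[ai]
      for (bi in seq_along(grp)[-seq_len(ai)]) {
        j <- grp[bi]
        if (spans[j, 1L] >= spans[i, 2L]) break  # sorted starts: no overlap
        if (.uf_find(parent, i) == .uf_find(parent, j)) next
        if (.linked(ts$exons[[i]], ts$exons[[j]], span_frac, exon_frac,
                    denom))
          parent <- .uf_union(parent, i, j)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  # stable ids in genome order of the first member
  ord <- order(ts$chrom[root], spans[root, 1L], ts$strand[root], root)
  lid <- integer(n)
  lid[ord] <- cumsum(!duplicated(root[ord]))
  ts$locus_id <- sprintf("LOC%05d", lid)
  loci <- do.call(rbind, lapply(split(seq_len(n), ts$locus_id), function(ii) {
    data.frame(locus_id = ts$locus_id[ii[1L]], chrom = ts$chrom[ii[1L]],
               strand = ts$strand[ii[1L]],
               start = min(spans[ii, 1L]), end = max(spans[ii, 2L]),
               n_transcripts = length(ii), stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  list(transcripts = ts, loci = loci[order(loci$locus_id), ])
}

#' Collapse redundant isoforms within loci
#'
#' Multi-exon transcripts with identical splice sites (identical intron
#' chains) collapse to the longest member; mono-exon transcripts merge when
#' one interval contains the other. Support (read count, best PID) is summed
#' and maximized over folded members, so collapse conserves support. The
#' operation is idempotent.
#'
#' @param ts a [transcript_set()] with a `locus_id` column (from
#'   [cluster_loci()]).
#' @return a data.frame of isoform records: `isoform_id`, `locus_id`,
#'   `chrom`, `strand`, `exons` (list), `chain`, `n_exons`,
#'   `spliced_length`, `support_count`, `support_pid`.
#' @export
collapse_isoforms <- function(ts) {
  if (is.null(ts$locus_id)) .stopf("run cluster_loci() first")
  if (is.null(ts$support_count)) ts$support_count <- 1L
  if (is.null(ts$support_pid)) ts$support_pid <- NA_real_
  rows <- list()
  for (ii in split(seq_len(nrow(ts)), ts$locus_id)) {
    n_ex <- vapply(ts$exons[ii], nrow, integer(1))
    multi <- ii[n_ex > 1L]; mono <- ii[n_ex == 1L]
    if (length(multi)) {
      keys <- vapply(multi, function(i)
        chain_key(ts$chrom[i], ts$strand[i], ts$exons[[i]]), character(1))
      for (grp in split(multi, keys)) {
        slen <- vapply(ts$exons[grp], spliced_length, integer(1))
        rep_i <- grp[which.max(slen)]
        rows[[length(rows) + 1L]] <- list(
          i = rep_i,
          support = sum(ts$support_count[grp]),
          pid = suppressWarnings(max(ts$support_pid[grp], na.rm = TRUE)))
      }
    }
    if (length(mono)) {
      iv <- t(vapply(ts$exons[mono], tx_span, integer(2)))
      ord <- mono[order(iv[, 2L] - iv[, 1L], decreasing = TRUE)]
      reps <- integer(0); members <- list()
      for (i in ord) {
        sp <- tx_span(ts$exons[[i]])
        hit <- 0L
        for (r in seq_along(reps)) {
          rsp <- tx_span(ts$exons[[reps[r]]])
          if (sp[1L] >= rsp[1L] && sp[2L] <= rsp[2L]) { hit <- r; break }
        }
        if (hit) members[[hit]] <- c(members[[hit]], i)
        else { reps <- c(reps, i); members[[length(reps)]] <- i }
      }
      for (r in seq_along(reps)) {
        grp <- members[[r]]
        rows[[length(rows) + 1L]] <- list(
          i = reps[r],
          support = sum(ts$support_count[grp]),
          pid = suppressWarnings(max(ts$support_pid[grp], na.rm = TRUE)))
      }
    }
  }
  i <- vapply(rows, `[[`, integer(1), "i")
  out <- data.frame(
    isoform_id = ts$transcript_id[i],
    locus_id = ts$locus_id[i],
    chrom = ts$chrom[i],
    strand = ts$strand[i],
    chain = vapply(i, function(k)
      chain_key(ts$chrom[k], ts$strand[k], ts$exons[[k]]), character(1)),
    n_exons = vapply(ts$exons[i], nrow, integer(1)),
    spliced_length = vapply(ts$exons[i], spliced_length, integer(1)),
    support_count = vapply(rows, `[[`, numeric(1), "support"),
    support_pid = {
      p <- vapply(rows, `[[`, numeric(1), "pid")
      ifelse(is.finite(p), p, NA_real_)
    },
    stringsAsFactors = FALSE)
  out$exons <- ts$exons[i]
  ord <- order(out$locus_id, out$chrom,
               vapply(out$exons, function(e) e[1L, 1L], integer(1)))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Flag full-length isoforms against a reference annotation
#'
#' A multi-exon isoform is full-length when its intron chain includes the
#' 5'-most splice donor site of an overlapping, same-strand reference
#' isoform (on the minus strand the first donor is the highest-coordinate
#' intron boundary). Mono-exon isoforms are NA (the rule is undefined for
#' them).
#'
#' @param isoforms output of [collapse_isoforms()].
#' @param reference a [transcript_set()] reference annotation.
#' @return logical vector (NA for mono-exon isoforms).
#' @export
flag_full_length <- function(isoforms, reference) {
  ref_multi <- which(vapply(reference$exons, nrow, integer(1)) > 1L)
  ref_span <- t(vapply(reference$exons, tx_span, integer(2)))
  ref_fd <- vapply(seq_len(nrow(reference)), function(i)
    first_donor(reference$strand[i], reference$exons[[i]]), integer(1))
  vapply(seq_len(nrow(isoforms)), function(i) {
    e <- isoforms$exons[[i]]
    if (nrow(e) < 2L) return(NA)
    sp <- tx_span(e)
    intr <- tx_introns(e)
    donors <- if (isoforms$strand[i] == "+") intr[, 1L] else intr[, 2L]
    cand <- ref_multi[reference$chrom[ref_multi] == isoforms$chrom[i] &
                        reference$strand[ref_multi] == isoforms$strand[i]]
    cand <- cand[.ov_len(sp[1L], sp[2L], ref_span[cand, 1L],
                         ref_span[cand, 2L]) > 0L]
    any(ref_fd[cand] %in% donors)
  }, logical(1))
}

#' Classify locus (gene) novelty against reference genes
#'
#' A locus is novel when it overlaps no annotated gene, when its best
#' same-strand overlap is below `min_frac` of the locus span, or when an
#' overlap of at least `min_frac` exists only on the opposite strand;
#' otherwise it is known and the matching gene ids are reported.
#'
#' @param loci locus table from [cluster_loci()].
#' @param reference a [transcript_set()] with `gene_id` set.
#' @param min_frac overlap fraction of the locus span required for a match
#'   (default 0.2).
#' @return `loci` with `novelty` (`known`/`novel`) and `matched_genes`
#'   (comma-separated, empty when novel) appended.
#' @export
classify_gene_novelty <- function(loci, reference, min_frac = 0.2) {
  spans <- t(vapply(reference$exons, tx_span, integer(2)))
  genes <- do.call(rbind, lapply(split(seq_len(nrow(reference)),
                                       reference$gene_id), function(ii) {
    data.frame(gene_id = reference$gene_id[ii[1L]],
               chrom = reference$chrom[ii[1L]],
               strand = reference$strand[ii[1L]],
               start = min(spans[ii, 1L]), end = max(spans[ii, 2L]),
               stringsAsFactors = FALSE)
  }))
  loci$novelty <- "novel"
  loci$matched_genes <- ""
  for (i in seq_len(nrow(loci))) {
    same <- genes$chrom == loci$chrom[i] & genes$strand == loci$strand[i]
    ov <- .ov_len(loci$start[i], loci$end[i], genes$start, genes$end)
    frac <- ov / (loci$end[i] - loci$start[i])
    hit <- same & frac >= min_frac
    if (any(hit)) {
      loci$novelty[i] <- "known"
      loci$matched_genes[i] <- paste(genes$gene_id[hit], collapse = ",")
    }
  }
  loci
}

#' Classify isoform novelty with FLNC support filtering
#'
#' A multi-exon isoform is known when every splice site (donor and acceptor,
#' strand-aware) matches a reference splice site within `fuzz` bases; a
#' mono-exon isoform is known when it equals a reference mono-exon transcript
#' (both ends within `fuzz`). Anything else is a novel candidate, kept when
#' supported by at least two FLNC reads or by a single read with local PID
#' above 99, and discarded otherwise.
#'
#' @param isoforms output of [collapse_isoforms()].
#' @param reference a [transcript_set()] reference annotation.
#' @param fuzz splice-site matching window in bases (default 0 = exact).
#' @return factor (`known`, `novel`, `discarded`) per isoform.
#' @export
classify_isoform_novelty <- function(isoforms, reference, fuzz = 0L) {
  ref_sites <- new.env(parent = emptyenv())
  mono_ref <- list()
  for (i in seq_len(nrow(reference))) {
    ss <- splice_sites(reference$strand[i], reference$exons[[i]])
    if (nrow(ss)) {
      for (k in seq_len(nrow(ss)))
        assign(sprintf("%s:%s:%s:%d", reference$chrom[i],
                       reference$strand[i], ss$kind[k], ss$pos[k]),
               TRUE, envir = ref_sites)
    } else {
      mono_ref[[length(mono_ref) + 1L]] <-
        c(i, tx_span(reference$exons[[i]]))
    }
  }
  mono_ref <- if (length(mono_ref)) do.call(rbind, mono_ref)
  else matrix(integer(0), ncol = 3L)
  site_known <- function(chrom, strand, kind, pos) {
    any(vapply(seq(pos - fuzz, pos + fuzz), function(p)
      exists(sprintf("%s:%s:%s:%d", chrom, strand, kind, p),
             envir = ref_sites), logical(1)))
  }
  out <- character(nrow(isoforms))
  for (i in seq_len(nrow(isoforms))) {
    e <- isoforms$exons[[i]]
    known <- if (nrow(e) > 1L) {
      ss <- splice_sites(isoforms$strand[i], e)
      all(vapply(seq_len(nrow(ss)), function(k)
        site_known(isoforms$chrom[i], isoforms$strand[i], ss$kind[k],
                   ss$pos[k]), logical(1)))
    } else {
      sp <- tx_span(e)
      any(mono_ref[, 1L] > 0L &
            reference$chrom[mono_ref[, 1L]] == isoforms$chrom[i] &
            reference$strand[mono_ref[, 1L]] == isoforms$strand[i] &
            abs(mono_ref[, 2L] - sp[1L]) <= fuzz &
            abs(mono_ref[, 3L] - sp[2L]) <= fuzz)
    }
    out[i] <- if (known) "known"
    else if (isoforms$support_count[i] >= 2L ||
             (isoforms$support_count[i] == 1L &&
              !is.na(isoforms$support_pid[i]) &&
              isoforms$support_pid[i] > 99)) "novel"
    else "discarded"
  }
  factor(out, levels = c("known", "novel", "discarded"))
}

#' Bin locus lengths into the <1K / 1-2K / 2-3K / >=3K classes
#'
#' @param lengths numeric vector of locus length statistics (by convention
#'   the spliced length of the longest member isoform; see
#'   [catalogue_transcripts()]).
#' @param digits decimal places for percentages (default 2).
#' @return data.frame `bin`, `count`, `percent`.
#' @export
locus_length_summary <- function(lengths, digits = 2) {
  bins <- cut(lengths, breaks = c(-Inf, 1000, 2000, 3000, Inf),
              labels = c("<1K", "1-2K", "2-3K", ">=3K"), right = FALSE)
  counts <- as.integer(table(bins))
  data.frame(bin = c("<1K", "1-2K", "2-3K", ">=3K"), count = counts,
             percent = round(100 * counts / sum(counts), digits))
}

#' Build the full isoform catalogue
#'
#' Runs [cluster_loci()], [collapse_isoforms()], [flag_full_length()],
#' [classify_gene_novelty()] and [classify_isoform_novelty()] and attaches a
#' locus length summary. Isoforms failing the novel-candidate support rule
#' are discarded before summaries.
#'
#' @param ts a [transcript_set()] of aligned transcript models (with
#'   `support_count`/`support_pid` when available).
#' @param reference a [transcript_set()] reference annotation.
#' @param ... passed to [cluster_loci()] and (as `fuzz`) to
#'   [classify_isoform_novelty()].
#' @param fuzz splice-site matching window (default 0).
#' @return list of class `isoform_catalogue`: `loci`, `isoforms` (with
#'   `full_length` and `novelty`), `length_summary`.
#' @export
catalogue_transcripts <- function(ts, reference, ..., fuzz = 0L) {
  cl <- cluster_loci(ts, ...)
  iso <- collapse_isoforms(cl$transcripts)
  iso$full_length <- flag_full_length(iso, reference)
  iso$novelty <- classify_isoform_novelty(iso, reference, fuzz = fuzz)
  iso <- iso[iso$novelty != "discarded", , drop = FALSE]
  loci <- classify_gene_novelty(cl$loci, reference)
  loci <- loci[loci$locus_id %in% iso$locus_id, , drop = FALSE]
  longest <- tapply(iso$spliced_length, iso$locus_id, max)
  out <- list(loci = loci, isoforms = iso,
              length_summary = locus_length_summary(
                as.numeric(longest[loci$locus_id])))
  class(out) <- "isoform_catalogue"
  out
}

#' @export
print.isoform_catalogue <- function(x, ...) {
  cat(sprintf("isoform_catalogue: %d loci (%d novel), %d isoforms (%d novel)\n",
              nrow(x$loci), sum(x$loci$novelty == "novel"),
              nrow(x$isoforms), sum(x$isoforms$novelty == "novel")))
  print(x$length_summary)
  invisible(x)
}
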