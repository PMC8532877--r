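# Shared fixtures: small deterministic worlds and hand-built transcript sets.

quiet_cfg <- function(seed = 1L, n_genes = 8L, n_reads = 200L,
                      chromosome_length = 200000L, ...) {
  sim_config(seed = seed, read_error_rate = 0, chimera_rate = 0,
             short_read_rate = 0, trunc5_rate = 0, trunc3_rate = 0,
             n_genes = n_genes, n_reads = n_reads,
             chromosome_length = chromosome_length, ...)
}

# transcript_set from a compact list spec: list(id = list(chrom, strand,
# exon matrix rows))
make_ts <- function(spec, ...) {
  transcript_set(
    transcript_id = names(spec),
    chrom = vapply(spec, `[[`, character(1), 1L),
    strand = vapply(spec, `[[`, character(1), 2L),
    exons = lapply(spec, function(s) matrix(s[[3L]], ncol = 2L, byrow = TRUE)),
    ...)
}

# random single-chromosome transcript set for clustering batteries
random_ts <- function(n, width = 30000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exons <- lapply(seq_len(n), function(i) {
    s <- sample.int(width, 1L)
    n_ex <- sample(1:4, 1L)
    lens <- sample(30:250, n_ex, replace = TRUE)
    gaps <- sample(50:300, n_ex, replace = TRUE)
    starts <- s + c(0L, cumsum(lens + gaps))[seq_len(n_ex)]
    cbind(starts, starts + lens)
  })
  transcript_set(sprintf("t%03d", seq_len(n)), "chr1",
                 sample(c("+", "-"), n, replace = TRUE), exons)
}

# independent re-statement of the loci linkage rule (oracle path)
oracle_linked <- function(ts, i, j, span_frac = 0.2, exon_frac = 0.2) {
  if (ts$chrom[i] != ts$chrom[j] || ts$strand[i] != ts$strand[j])
    return(FALSE)
  ea <- ts$exons[[i]]; eb <- ts$exons[[j]]
  sa <- c(ea[1, 1], ea[nrow(ea), 2]); sb <- c(eb[1, 1], eb[nrow(eb), 2])
  ov <- min(sa[2], sb[2]) - max(sa[1], sb[1])
  if (ov < span_frac * min(sa[2] - sa[1], sb[2] - sb[1])) return(FALSE)
  for (a in seq_len(nrow(ea))) for (b in seq_len(nrow(eb))) {
    eo <- min(ea[a, 2], eb[b, 2]) - max(ea[a, 1], eb[b, 1])
    if (eo > exon_frac * min(ea[a, 2] - ea[a, 1], eb[b, 2] - eb[b, 1]))
      return(TRUE)
  }
  FALSE
}

# brute-force connected components over the oracle linkage (BFS closure)
oracle_loci <- function(ts, ...) {
  n <- nrow(ts)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (comp[j] == 0L && oracle_linked(ts, i, j, ...)) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# partition of indices by component, as a canonical sorted signature
partition_signature <- function(groups) {
  sig <- vapply(split(seq_along(groups), groups), function(ii)
    paste(sort(ii), collapse = ","), character(1))
  sort(unname(sig))
}

# independent pairwise AS-event oracle from the event definitions
oracle_pair_events <- function(ex_a, ex_b, strand) {
  introns <- function(e) if (nrow(e) < 2L)
    matrix(integer(0), ncol = 2L) else cbind(e[-nrow(e), 2L], e[-1L, 1L])
  ia <- introns(ex_a); ib <- introns(ex_b)
  ev <- character(0)
  # ES: internal exon of X spanned exactly by one intron of Y
  es <- function(exq, iq, it) {
    out <- character(0)
    if (nrow(exq) >= 3L && nrow(it) > 0L)
      for (k in 2L:(nrow(exq) - 1L))
        for (q in seq_len(nrow(it)))
          if (it[q, 1L] == iq[k - 1L, 1L] && it[q, 2L] == iq[k, 2L])
            out <- c(out, sprintf("ES:%d-%d", exq[k, 1L], exq[k, 2L]))
    out
  }
  ev <- c(ev, es(ex_a, ia, ib), es(ex_b, ib, ia))
  # an intron pair sharing one boundary is ES-explained when the isoform
  # holding the shorter intron has an exon starting (resp. ending) exactly at
  # the shorter intron's free end whose next (resp. previous) intron closes
  # at the longer intron's far boundary
  explained_start <- function(short_end, long_end, ex_short, i_short) {
    w <- which(ex_short[, 1L] == short_end)
    length(w) == 1L && w <= nrow(i_short) &&
      i_short[w, 2L] == long_end && i_short[w, 1L] == ex_short[w, 2L]
  }
  explained_end <- function(short_start, long_start, ex_short, i_short) {
    w <- which(ex_short[, 2L] == short_start)
    length(w) == 1L && w >= 2L &&
      i_short[w - 1L, 1L] == long_start && i_short[w - 1L, 2L] == ex_short[w, 1L]
  }
  if (nrow(ia) && nrow(ib))
    for (p in seq_len(nrow(ia))) for (q in seq_len(nrow(ib))) {
      s1 <- ia[p, 1L]; e1 <- ia[p, 2L]; s2 <- ib[q, 1L]; e2 <- ib[q, 2L]
      if (s1 == s2 && e1 != e2) {
        skip <- if (e1 < e2) explained_start(e1, e2, ex_a, ia)
        else explained_start(e2, e1, ex_b, ib)
        if (!skip)
          ev <- c(ev, sprintf("%s:%d-%d", if (strand == "+") "AA" else "AD",
                              min(e1, e2), max(e1, e2)))
      } else if (e1 == e2 && s1 != s2) {
        skip <- if (s1 > s2) explained_end(s1, s2, ex_a, ia)
        else explained_end(s2, s1, ex_b, ib)
        if (!skip)
          ev <- c(ev, sprintf("%s:%d-%d", if (strand == "+") "AD" else "AA",
                              min(s1, s2), max(s1, s2)))
      }
    }
  # IR: intron inside an exon of the other chain
  ir <- function(intr, exo) {
    out <- character(0)
    if (nrow(intr))
      for (p in seq_len(nrow(intr)))
        if (any(exo[, 1L] <= intr[p, 1L] & exo[, 2L] >= intr[p, 2L]))
          out <- c(out, sprintf("IR:%d-%d", intr[p, 1L], intr[p, 2L]))
    out
  }
  ev <- c(ev, ir(ia, ex_b), ir(ib, ex_a))
  sort(unique(ev))
}

# exhaustive 3-frame ORF oracle via regex scanning
oracle_orfs <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (f in 1:3) {
    starts <- seq.int(f, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2L)
    for (i in seq_along(codons)) {
      if (codons[i] != "ATG") next
      j <- i
      while (j <= length(codons) && !(codons[j] %in% stops)) j <- j + 1L
      if (j <= length(codons)) {
        aa <- j - i
        if (aa >= min_aa)
          rows[[length(rows) + 1L]] <- c(f, starts[i], starts[j] + 2L, aa, 1L)
      } else {
        aa <- length(codons) - i + 1L
        if (aa >= min_aa)
          rows[[length(rows) + 1L]] <- c(f, starts[i],
                                         starts[length(codons)] + 2L, aa, 2L)
      }
    }
    first_stop <- which(codons %in% stops)[1L]
    open_len <- if (is.na(first_stop)) length(codons) else first_stop - 1L
    atg1 <- which(codons == "ATG")[1L]
    if (open_len >= min_aa && (is.na(atg1) || atg1 > open_len))
      rows[[length(rows) + 1L]] <- c(
        f, f, starts[open_len] + 2L + (if (is.na(first_stop)) 0L else 3L),
        open_len, 3L)
  }
  if (!length(rows)) return(matrix(integer(0), ncol = 5L))
  m <- do.call(rbind, rows)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}
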