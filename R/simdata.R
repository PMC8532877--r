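# Synthetic data with known truth: a toy genome, a multi-isoform annotation
# exercising ES/AA/AD/IR/APA structures, primer-flanked polyadenylated long
# reads with configurable errors/truncations/chimeras, and two-condition
# negative-binomial count matrices. The stated world mirrors the study design
# the package targets: two muscle groups with four biological replicates for
# the short-read arm and one mixed-tissue long-read library.

#' Configuration for the synthetic-data generators
#'
#' All downstream generators ([gen_genome()], [gen_annotation()],
#' [sim_flnc_reads()], [sim_counts()]) are deterministic given `seed`:
#' identical configurations produce byte-identical outputs.
#'
#' @param seed integer RNG seed (keep below 2^31).
#' @param n_chromosomes,chromosome_length toy genome shape (bases).
#' @param n_genes genes placed, non-overlapping, across chromosomes.
#' @param isoforms_per_gene list with `lambda`: extra isoforms per gene are
#'   `rpois(lambda)` (plus the base isoform), or `exact` for a fixed count.
#' @param exon_length,intron_length inclusive base ranges for base-isoform
#'   exons and introns.
#' @param as_event_rates named numeric sampling weights over
#'   `c(ES, AA, AD, IR, APA)` for the structure of each extra isoform; all
#'   zero means every gene is single-isoform.
#' @param read_error_rate per-base substitution+indel probability in [0, 0.5).
#' @param chimera_rate probability a read is a two-fragment concatemer.
#' @param short_read_rate probability a read is a short fragment below the
#'   minimum read length.
#' @param trunc5_rate,trunc3_rate probabilities that a non-chimeric read loses
#'   its 5' primer (plus some 5' sequence) or its polyA tail and 3' primer.
#' @param primer5,primer3 cDNA primer sequences (distinct, length >= 8).
#' @param polya_length simulated polyA tail length (bases).
#' @param n_reads number of long reads.
#' @param n_count_genes,de_fraction,lfc_magnitude,nb_dispersion,
#'   n_samples_per_group count-matrix world: number of genes, fraction of
#'   true DE genes, their |log2 fold change|, NB over-dispersion (0 =
#'   Poisson), and replicates per group.
#' @param depth_factors optional per-sample sequencing-depth multipliers
#'   (length `2 * n_samples_per_group`); default all 1.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 250000L,
                       n_genes = 20L,
                       isoforms_per_gene = list(lambda = 1),
                       exon_length = c(100L, 300L),
                       intron_length = c(200L, 600L),
                       as_event_rates = c(ES = 0.25, AA = 0.2, AD = 0.2,
                                          IR = 0.25, APA = 0.1),
                       read_error_rate = 0.01,
                       chimera_rate = 0.02,
                       short_read_rate = 0.02,
                       trunc5_rate = 0.05,
                       trunc3_rate = 0.05,
                       primer5 = "CAGGAAACAGCTATGACCATG",
                       primer3 = "TGTAAAACGACGGCCAGT",
                       polya_length = 30L,
                       n_reads = 2000L,
                       n_count_genes = 2000L,
                       de_fraction = 0.1,
                       lfc_magnitude = 2,
                       nb_dispersion = 0.05,
                       n_samples_per_group = 4L,
                       depth_factors = NULL) {
  cfg <- as.list(environment())
  rates <- c(cfg$read_error_rate, cfg$chimera_rate, cfg$short_read_rate,
             cfg$trunc5_rate, cfg$trunc3_rate, cfg$de_fraction)
  if (any(rates < 0 | rates > 1)) .stopf("rates must lie in [0, 1]")
  if (cfg$read_error_rate >= 0.5) .stopf("read_error_rate must be < 0.5")
  if (cfg$chromosome_length < 10000L) .stopf("chromosome_length must be >= 10,000")
  if (any(c(cfg$n_chromosomes, cfg$n_genes, cfg$n_reads, cfg$polya_length,
            cfg$exon_length, cfg$intron_length) <= 0L))
    .stopf("sizes and lengths must be positive")
  if (cfg$nb_dispersion < 0) .stopf("nb_dispersion must be >= 0")
  if (cfg$n_samples_per_group < 2L) .stopf("need >= 2 samples per group")
  if (!nzchar(cfg$primer5) || !nzchar(cfg$primer3) ||
      identical(cfg$primer5, cfg$primer3))
    .stopf("primers must be non-empty and distinct")
  bad <- setdiff(names(cfg$as_event_rates), c("ES", "AA", "AD", "IR", "APA"))
  if (length(bad)) .stopf("unknown AS event type(s): %s", paste(bad, collapse = ", "))
  if (any(cfg$as_event_rates < 0)) .stopf("as_event_rates must be >= 0")
  if (is.null(cfg$depth_factors))
    cfg$depth_factors <- rep(1, 2L * cfg$n_samples_per_group)
  if (length(cfg$depth_factors) != 2L * cfg$n_samples_per_group)
    .stopf("depth_factors must have one entry per sample")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy genome
#'
#' Uniform random A/C/G/T sequences; GC fraction is 0.5 in expectation.
#'
#' @param config a [sim_config()].
#' @return named character vector (`chr1`, `chr2`, ...), FASTA-writable via
#'   [write_fasta()].
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    out <- vapply(seq_len(config$n_chromosomes), function(i)
      paste(sample(c("A", "C", "G", "T"), config$chromosome_length,
                   replace = TRUE), collapse = ""),
      character(1))
    names(out) <- paste0("chr", seq_len(config$n_chromosomes))
    out
  })
}

# apply one AS structure to a base exon chain; returns NULL when infeasible
.apply_as_event <- function(exons, strand, type, flank_reserve) {
  n <- nrow(exons)
  switch(type,
    ES = {
      if (n < 3L) return(NULL)
      i <- if (n == 3L) 2L else sample(2:(n - 1L), 1L)
      list(exons = exons[-i, , drop = FALSE],
           coords = exons[i, ])
    },
    AA = {  # extend the exon on the acceptor side of one intron into it
      if (n < 2L) return(NULL)
      i <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
      gap <- exons[i + 1L, 1L] - exons[i, 2L]
      delta <- sample(12:60, 1L)
      if (gap - delta < 30L) return(NULL)
      e2 <- exons
      if (strand == "+") e2[i + 1L, 1L] <- e2[i + 1L, 1L] - delta
      else e2[i, 2L] <- e2[i, 2L] + delta
      a0 <- if (strand == "+") exons[i + 1L, 1L] else exons[i, 2L]
      a1 <- if (strand == "+") e2[i + 1L, 1L] else e2[i, 2L]
      list(exons = e2, coords = c(min(a0, a1), max(a0, a1)))
    },
    AD = {  # extend the exon on the donor side of one intron into it
      if (n < 2L) return(NULL)
      i <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
      gap <- exons[i + 1L, 1L] - exons[i, 2L]
      delta <- sample(12:60, 1L)
      if (gap - delta < 30L) return(NULL)
      e2 <- exons
      if (strand == "+") e2[i, 2L] <- e2[i, 2L] + delta
      else e2[i + 1L, 1L] <- e2[i + 1L, 1L] - delta
      d0 <- if (strand == "+") exons[i, 2L] else exons[i + 1L, 1L]
      d1 <- if (strand == "+") e2[i, 2L] else e2[i + 1L, 1L]
      list(exons = e2, coords = c(min(d0, d1), max(d0, d1)))
    },
    IR = {  # retain one intron: merge its flanking exons
      if (n < 2L) return(NULL)
      i <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
      e2 <- exons
      e2[i, 2L] <- e2[i + 1L, 2L]
      e2 <- e2[-(i + 1L), , drop = FALSE]
      list(exons = e2, coords = c(exons[i, 2L], exons[i + 1L, 1L]))
    },
    APA = {  # alternative 3' end: extend the terminal exon into the reserve
      delta <- sample(100:min(300L, flank_reserve - 10L), 1L)
      e2 <- exons
      if (strand == "+") e2[n, 2L] <- e2[n, 2L] + delta
      else e2[1L, 1L] <- e2[1L, 1L] - delta
      pos <- if (strand == "+") e2[n, 2L] else e2[1L, 1L]
      list(exons = e2, coords = c(pos, pos))
    })
}

# overwrite genome bases so every simulated intron has canonical boundaries
# ('+': GT...AG on the chromosome; '-': CT...AC)
.plant_splice_signals <- function(genome, ts) {
  subst <- function(s, at, what) {  # at: 0-based position of first base
    substring(s, at + 1L, at + nchar(what)) <- what
    s
  }
  for (i in seq_len(nrow(ts))) {
    intr <- tx_introns(ts$exons[[i]])
    if (nrow(intr) == 0L) next
    chr <- ts$chrom[i]
    s <- genome[[chr]]
    for (k in seq_len(nrow(intr))) {
      if (ts$strand[i] == "+") {
        s <- subst(s, intr[k, 1L], "GT")
        s <- subst(s, intr[k, 2L] - 2L, "AG")
      } else {
        s <- subst(s, intr[k, 1L], "CT")
        s <- subst(s, intr[k, 2L] - 2L, "AC")
      }
    }
    genome[[chr]] <- s
  }
  genome
}

#' Generate a toy annotation with known alternative-splicing truth
#'
#' Places non-overlapping genes along the chromosomes. Each gene gets a base
#' isoform (4-8 exons) plus extra isoforms whose structure is one sampled
#' alternative-splicing event: cassette exon (ES), alternative acceptor (AA),
#' alternative donor (AD), retained intron (IR) or alternative 3' end (APA).
#' Canonical GT/AG intron boundaries are written into the returned genome.
#'
#' @param genome output of [gen_genome()].
#' @param config the same [sim_config()].
#' @return list with `annotation` (a [transcript_set()], GTF-writable),
#'   `genome` (sequences with splice signals planted), and `truth`: a list of
#'   `genes`, `isoforms` (with the event type behind each extra isoform) and
#'   `events` data.frames.
#' @export
gen_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  flank <- 400L
  with_seed(config$seed + 202L, {
    chrom_len <- nchar(genome)
    chrom_at <- rep(1000L, length(genome))   # next free position per chrom
    rates <- config$as_event_rates
    types <- names(rates)[rates > 0]
    weights <- rates[rates > 0]

    tx_id <- character(0); tx_chrom <- character(0); tx_strand <- character(0)
    tx_gene <- character(0); tx_exons <- list()
    iso_truth <- list(); gene_truth <- list(); event_truth <- list()

    for (g in seq_len(config$n_genes)) {
      gene_id <- sprintf("SIMG%04d", g)
      n_exons <- sample(4:8, 1L)
      elens <- sample(config$exon_length[1]:config$exon_length[2], n_exons,
                      replace = TRUE)
      ilens <- if (n_exons > 1L)
        sample(config$intron_length[1]:config$intron_length[2], n_exons - 1L,
               replace = TRUE) else integer(0)
      footprint <- sum(elens) + sum(ilens) + 2L * flank
      ci <- which(chrom_at + footprint + 1000L <= chrom_len)
      if (length(ci) == 0L)
        .stopf("genome too small for %d genes", config$n_genes)
      ci <- ci[1L]
      x <- chrom_at[ci] + flank
      starts <- x + c(0L, cumsum(elens[-n_exons] + ilens))
      exons <- cbind(start = starts, end = starts + elens)
      chrom_at[ci] <- chrom_at[ci] + footprint + sample(500:1500, 1L)
      strand <- sample(c("+", "-"), 1L)
      chrom <- names(genome)[ci]

      n_alt <- if (length(types) == 0L) 0L
      else if (!is.null(config$isoforms_per_gene$exact))
        max(0L, as.integer(config$isoforms_per_gene$exact) - 1L)
      else rpois(1L, config$isoforms_per_gene$lambda)

      tx_id <- c(tx_id, sprintf("%s.1", gene_id))
      tx_chrom <- c(tx_chrom, chrom); tx_strand <- c(tx_strand, strand)
      tx_gene <- c(tx_gene, gene_id); tx_exons <- c(tx_exons, list(exons))
      iso_truth[[length(iso_truth) + 1L]] <- data.frame(
        transcript_id = sprintf("%s.1", gene_id), gene_id = gene_id,
        event = "base", stringsAsFactors = FALSE)

      k <- 1L
      for (a in seq_len(n_alt)) {
        ev <- NULL; type <- NA_character_; tries <- 0L
        while (is.null(ev) && tries < 10L) {
          type <- sample(types, 1L, prob = weights)
          ev <- .apply_as_event(exons, strand, type, flank)
          tries <- tries + 1L
        }
        if (is.null(ev)) next
        k <- k + 1L
        tid <- sprintf("%s.%d", gene_id, k)
        tx_id <- c(tx_id, tid)
        tx_chrom <- c(tx_chrom, chrom); tx_strand <- c(tx_strand, strand)
        tx_gene <- c(tx_gene, gene_id); tx_exons <- c(tx_exons, list(ev$exons))
        iso_truth[[length(iso_truth) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gene_id, event = type,
          stringsAsFactors = FALSE)
        event_truth[[length(event_truth) + 1L]] <- data.frame(
          gene_id = gene_id, type = type,
          start = ev$coords[1L], end = ev$coords[2L],
          stringsAsFactors = FALSE)
      }
      gene_truth[[length(gene_truth) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = exons[1L, 1L], end = exons[nrow(exons), 2L],
        n_isoforms = k, stringsAsFactors = FALSE)
    }

    ann <- transcript_set(tx_id, tx_chrom, tx_strand, tx_exons,
                          gene_id = tx_gene)
    genome2 <- .plant_splice_signals(genome, ann)
    list(annotation = ann, genome = genome2,
         truth = list(genes = do.call(rbind, gene_truth),
                      isoforms = do.call(rbind, iso_truth),
                      events = if (length(event_truth))
                        do.call(rbind, event_truth)
                      else data.frame(gene_id = character(0),
                                      type = character(0),
                                      start = integer(0), end = integer(0))))
  })
}

# substitutions/indels at a per-base rate; substitutions dominate (80/10/10)
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit) == 0L) return(s)
  op <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
               prob = c(0.8, 0.1, 0.1))
  bases <- c("A", "C", "G", "T")
  for (j in rev(seq_along(hit))) {  # right-to-left keeps indices valid
    i <- hit[j]
    if (op[j] == "sub") {
      v[i] <- sample(setdiff(bases, v[i]), 1L)
    } else if (op[j] == "ins") {
      v <- append(v, sample(bases, 1L), after = i)
    } else {
      v <- v[-i]
    }
  }
  paste(v, collapse = "")
}

#' Simulate primer-flanked long reads with classification truth
#'
#' Each ordinary read is `primer5 + spliced transcript + polyA +
#' revcomp(primer3)`, optionally 5'/3'-truncated (dropping the corresponding
#' primer and some sequence); chimeric reads concatenate two such full-length
#' units, leaving internal primer copies; short-fragment reads fall below the
#' minimum read length. Sequencing errors are applied last.
#'
#' @param annotation a [transcript_set()] from [gen_annotation()].
#' @param genome genome sequences (as returned by [gen_annotation()]).
#' @param config the same [sim_config()].
#' @return list with `reads` (named character vector, FASTA-writable),
#'   `alignments` (a [transcript_set()] of true read placements,
#'   BED12-writable; chimeric reads contribute one placement per fragment),
#'   `labels` (per-read truth: category, origin transcript, chimera partner)
#'   and `segments` (per-read true split placements in read coordinates, for
#'   fusion calling).
#' @export
sim_flnc_reads <- function(annotation, genome, config) {
  stopifnot(inherits(config, "sim_config"))
  p5 <- config$primer5; p3rc <- revcomp(config$primer3)
  polya <- strrep("A", config$polya_length)
  txseq <- transcript_sequences(annotation, genome)
  ntx <- nrow(annotation)
  with_seed(config$seed + 303L, {
    ab <- exp(rnorm(ntx, 0, 1)); ab <- ab / sum(ab)  # transcript abundances
    reads <- character(config$n_reads)
    lab <- vector("list", config$n_reads)
    seg <- vector("list", config$n_reads)
    aln_rows <- list()
    u <- runif(config$n_reads)
    # deep-coverage world: the first ordinary reads cycle through every
    # annotated isoform twice, the rest follow the abundance profile
    ordinary <- which(!(u < config$chimera_rate + config$short_read_rate))
    tx_assign <- integer(config$n_reads)
    k <- min(length(ordinary), 2L * ntx)
    if (k > 0L) tx_assign[ordinary[seq_len(k)]] <- rep_len(seq_len(ntx), k)
    if (length(ordinary) > k)
      tx_assign[ordinary[-seq_len(k)]] <-
        sample(ntx, length(ordinary) - k, replace = TRUE, prob = ab)
    for (i in seq_len(config$n_reads)) {
      rid <- sprintf("read%06d", i)
      if (u[i] < config$chimera_rate && ntx >= 2L) {
        pair <- sample(ntx, 2L, prob = ab)
        unit <- function(t) paste0(p5, txseq[[t]], polya, p3rc)
        u1 <- unit(pair[1L]); u2 <- unit(pair[2L])
        raw <- paste0(u1, u2)
        lab[[i]] <- data.frame(
          read_id = rid, category = "chimeric",
          transcript_id = annotation$transcript_id[pair[1L]],
          partner_id = annotation$transcript_id[pair[2L]],
          stringsAsFactors = FALSE)
        body1 <- nchar(txseq[[pair[1L]]]); body2 <- nchar(txseq[[pair[2L]]])
        s1 <- nchar(p5); len <- nchar(raw)
        seg[[i]] <- data.frame(
          read_id = rid, seg = 1:2,
          read_start = c(s1, nchar(u1) + s1),
          read_end = c(s1 + body1, nchar(u1) + s1 + body2),
          read_length = len,
          transcript_id = annotation$transcript_id[pair],
          chrom = annotation$chrom[pair], strand = annotation$strand[pair],
          stringsAsFactors = FALSE)
        for (k in 1:2) aln_rows[[length(aln_rows) + 1L]] <- list(
          id = sprintf("%s/%d", rid, k), tx = pair[k])
      } else if (u[i] < config$chimera_rate + config$short_read_rate) {
        t <- sample(ntx, 1L, prob = ab)
        flen <- sample(20:45, 1L)
        s <- txseq[[t]]
        at <- sample(max(1L, nchar(s) - flen), 1L)
        raw <- substring(s, at, at + flen - 1L)
        lab[[i]] <- data.frame(
          read_id = rid, category = "filtered_short",
          transcript_id = annotation$transcript_id[t],
          partner_id = NA_character_, stringsAsFactors = FALSE)
      } else {
        t <- tx_assign[i]
        body <- txseq[[t]]
        t5 <- runif(1) < config$trunc5_rate
        t3 <- runif(1) < config$trunc3_rate
        if (t5) body <- substring(body, sample(10:100, 1L))
        head5 <- if (t5) "" else p5
        tail3 <- if (t3) "" else paste0(polya, p3rc)
        if (t3) body <- substring(body, 1L,
                                  max(50L, nchar(body) - sample(10:100, 1L)))
        raw <- paste0(head5, body, tail3)
        lab[[i]] <- data.frame(
          read_id = rid,
          category = if (t5 || t3) "non_full_length" else "flnc",
          transcript_id = annotation$transcript_id[t],
          partner_id = NA_character_, stringsAsFactors = FALSE)
        aln_rows[[length(aln_rows) + 1L]] <- list(id = rid, tx = t)
      }
      reads[i] <- .mutate_seq(raw, config$read_error_rate)
      names(reads)[i] <- rid
    }
    aln <- if (length(aln_rows)) transcript_set(
      transcript_id = vapply(aln_rows, `[[`, character(1), "id"),
      chrom = annotation$chrom[vapply(aln_rows, `[[`, integer(1), "tx")],
      strand = annotation$strand[vapply(aln_rows, `[[`, integer(1), "tx")],
      exons = annotation$exons[vapply(aln_rows, `[[`, integer(1), "tx")])
    else NULL
    list(reads = reads,
         alignments = aln,
         labels = do.call(rbind, lab),
         segments = if (length(seg)) do.call(rbind, seg) else NULL)
  })
}

#' Simulate a two-group negative-binomial count matrix with DE truth
#'
#' Gene base means are log-normal; a `de_fraction` of genes differ between
#' the two groups by `lfc_magnitude` log2 units (random sign, oriented as
#' group2/group1, i.e. BF/LD); counts are NB with dispersion `nb_dispersion`
#' (Poisson when 0) around `depth_factor * mean`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `lengths`
#'   (effective feature lengths, bases), `groups` (factor `LD`/`BF`) and
#'   `truth` (per-gene `is_de`, `true_lfc`).
#' @export
sim_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 404L, {
    ng <- config$n_count_genes
    ns <- config$n_samples_per_group
    groups <- factor(rep(c("LD", "BF"), each = ns), levels = c("LD", "BF"))
    mu <- exp(rnorm(ng, log(100), 1))
    n_de <- round(config$de_fraction * ng)
    de_idx <- if (n_de > 0) sample(ng, n_de) else integer(0)
    lfc <- numeric(ng)
    if (n_de > 0)
      lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        config$lfc_magnitude
    mu_mat <- matrix(mu, ng, 2L * ns)
    mu_mat[, groups == "BF"] <- mu_mat[, groups == "BF"] * 2^lfc
    mu_mat <- sweep(mu_mat, 2L, config$depth_factors, `*`)
    counts <- matrix(0L, ng, 2L * ns)
    if (config$nb_dispersion == 0) {
      counts[] <- rpois(length(mu_mat), lambda = mu_mat)
    } else {
      counts[] <- rnbinom(length(mu_mat), mu = mu_mat,
                          size = 1 / config$nb_dispersion)
    }
    rownames(counts) <- sprintf("GENE%05d", seq_len(ng))
    colnames(counts) <- paste0(rep(c("LD", "BF"), each = ns),
                               rep(seq_len(ns), 2L))
    list(counts = counts,
         lengths = sample(500:3000, ng, replace = TRUE),
         groups = groups,
         truth = data.frame(gene_id = rownames(counts),
                            is_de = seq_len(ng) %in% de_idx,
                            true_lfc = lfc, stringsAsFactors = FALSE))
  })
}

#' Write sequences as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub(" .*", "", names(x)))
}
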