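# Synthetic-data generators: contracts, determinism, truth bookkeeping.

test_that("gen_genome honors length, alphabet, determinism and GC balance", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 50000)
  g <- gen_genome(cfg)
  expect_length(g, 1L)
  expect_equal(nchar(g[[1]]), 50000L)
  expect_false(grepl("[^ACGT]", g[[1]]))
  expect_identical(g, gen_genome(cfg))

  big <- sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 1000000L)
  s <- gen_genome(big)[[1]]
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.01)  # ~20 binomial SEs at 1 Mb

  expect_error(sim_config(chromosome_length = 5000), "10,000")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(read_error_rate = 0.6), "rate")
})

test_that("gen_annotation builds valid, strand-consistent gene models", {
  cfg <- quiet_cfg(seed = 3, isoforms_per_gene = list(lambda = 2))
  g <- gen_genome(cfg)
  ann <- gen_annotation(g, cfg)
  ts <- ann$annotation
  expect_gte(nrow(ts), cfg$n_genes)
  for (i in seq_len(nrow(ts))) {
    e <- ts$exons[[i]]
    expect_true(all(e[, 2] > e[, 1]))                       # no zero exons
    if (nrow(e) > 1) expect_true(all(e[-1, 1] > e[-nrow(e), 2]))
    expect_true(e[nrow(e), 2] <= nchar(g[[ts$chrom[i]]]))   # within bounds
  }
  # isoforms of one gene share strand and overlap the base isoform
  for (gid in unique(ts$gene_id)) {
    sub <- ts[ts$gene_id == gid, ]
    expect_length(unique(sub$strand), 1L)
  }
  # canonical splice signals planted into the returned genome
  i <- which(vapply(ts$exons, nrow, integer(1)) > 1L)[1L]
  e <- ts$exons[[i]]
  chr <- ann$genome[[ts$chrom[i]]]
  din5 <- substring(chr, e[1, 2] + 1, e[1, 2] + 2)
  din3 <- substring(chr, e[2, 1] - 1, e[2, 1])
  if (ts$strand[i] == "+") {
    expect_identical(din5, "GT"); expect_identical(din3, "AG")
  } else {
    expect_identical(din5, "CT"); expect_identical(din3, "AC")
  }
})

test_that("AS event rates shape the annotation truth", {
  # all-zero rates: single isoform everywhere
  cfg0 <- quiet_cfg(seed = 4, as_event_rates = c(ES = 0, AA = 0, AD = 0,
                                                 IR = 0, APA = 0))
  ann0 <- gen_annotation(gen_genome(cfg0), cfg0)
  expect_true(all(ann0$truth$genes$n_isoforms == 1L))
  expect_equal(nrow(ann0$truth$events), 0L)

  # forced cassette exons: every gene's truth lists >= 1 ES
  cfg1 <- quiet_cfg(seed = 5,
                    isoforms_per_gene = list(exact = 2),
                    as_event_rates = c(ES = 1, AA = 0, AD = 0, IR = 0,
                                       APA = 0))
  ann1 <- gen_annotation(gen_genome(cfg1), cfg1)
  es_genes <- unique(ann1$truth$events$gene_id[ann1$truth$events$type == "ES"])
  expect_setequal(es_genes, ann1$truth$genes$gene_id)
})

test_that("GTF round-trip preserves exon coordinates exactly", {
  cfg <- quiet_cfg(seed = 6)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$annotation, path)
  back <- read_gtf(path)
  ord <- match(ann$annotation$transcript_id, back$transcript_id)
  expect_false(anyNA(ord))
  for (i in seq_len(nrow(ann$annotation)))
    expect_equal(unname(back$exons[[ord[i]]]),
                 unname(ann$annotation$exons[[i]]))
  expect_identical(back$strand[ord], ann$annotation$strand)
})

test_that("BED12 round-trip preserves block structure", {
  ts <- make_ts(list(r1 = list("chr1", "+", c(10, 50, 100, 200)),
                     r2 = list("chr2", "-", c(5, 80))))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed12(ts, path)
  back <- read_bed12(path)
  ord <- match(ts$transcript_id, back$transcript_id)
  for (i in 1:2)
    expect_equal(unname(back$exons[[ord[i]]]), unname(ts$exons[[i]]))
})

test_that("simulated reads carry the stated structure and labels conserve", {
  cfg <- sim_config(seed = 7, read_error_rate = 0, chimera_rate = 0.1,
                    short_read_rate = 0.05, trunc5_rate = 0, trunc3_rate = 0,
                    n_reads = 400, n_genes = 6)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  rd <- sim_flnc_reads(ann$annotation, ann$genome, cfg)
  expect_identical(names(rd$reads), rd$labels$read_id)
  expect_equal(nrow(rd$labels), cfg$n_reads)  # label conservation
  # an error-free ordinary read is primer5 + transcript + polyA + rc(primer3)
  i <- which(rd$labels$category == "flnc")[1L]
  tx <- rd$labels$transcript_id[i]
  body <- transcript_sequences(ann$annotation, ann$genome)[[tx]]
  expected <- paste0(cfg$primer5, body, strrep("A", cfg$polya_length),
                     revcomp(cfg$primer3))
  expect_identical(rd$reads[[i]], expected)
  # chimeras concatenate two units with an internal primer copy
  j <- which(rd$labels$category == "chimeric")[1L]
  expect_gte(lengths(regmatches(rd$reads[[j]],
                                gregexpr(cfg$primer5, rd$reads[[j]],
                                         fixed = TRUE))), 2L)
  # determinism
  rd2 <- sim_flnc_reads(ann$annotation, ann$genome, cfg)
  expect_identical(rd$reads, rd2$reads)
})

test_that("5' truncation rate surfaces as the non-full-length fraction", {
  cfg <- sim_config(seed = 8, read_error_rate = 0, chimera_rate = 0,
                    short_read_rate = 0, trunc5_rate = 0.3, trunc3_rate = 0,
                    n_reads = 2000, n_genes = 6)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  rd <- sim_flnc_reads(ann$annotation, ann$genome, cfg)
  frac <- mean(rd$labels$category == "non_full_length")
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("sim_counts produces the stated DE world", {
  cfg0 <- sim_config(seed = 9, de_fraction = 0, n_count_genes = 500)
  sc0 <- sim_counts(cfg0)
  expect_equal(sum(sc0$truth$is_de), 0L)
  expect_identical(dim(sc0$counts), c(500L, 8L))

  cfg <- sim_config(seed = 10, de_fraction = 0.2, n_count_genes = 1000)
  sc <- sim_counts(cfg)
  expect_equal(sum(sc$truth$is_de), 200L)
  expect_true(all(abs(sc$truth$true_lfc[sc$truth$is_de]) ==
                    cfg$lfc_magnitude))
  expect_identical(sc$counts, sim_counts(cfg)$counts)  # determinism

  # dispersion 0 is the Poisson limit: pooled variance tracks the mean
  cfgp <- sim_config(seed = 11, de_fraction = 0, nb_dispersion = 0,
                     n_count_genes = 3000, n_samples_per_group = 10)
  scp <- sim_counts(cfgp)
  m <- rowMeans(scp$counts)
  v <- apply(scp$counts, 1, var)
  keep <- m > 20
  expect_lt(abs(median(v[keep] / m[keep]) - 1), 0.1)
})
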