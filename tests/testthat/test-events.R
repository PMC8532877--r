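# AS event enumeration, APA clustering, fusion candidates.

iso_df <- function(spec, locus = "L1") {
  ts <- make_ts(spec)
  data.frame(isoform_id = ts$transcript_id, locus_id = locus,
             chrom = ts$chrom, strand = ts$strand,
             stringsAsFactors = FALSE) |>
    (\(d) { d$exons <- ts$exons; d })()
}

test_that("enumerate_as_events types the canonical pairwise differences", {
  # cassette exon: exactly one ES, no side AA/AD bookkeeping leaks
  es <- iso_df(list(a = list("chr1", "+", c(0, 100, 200, 300, 400, 500)),
                    b = list("chr1", "+", c(0, 100, 400, 500))))
  ev <- enumerate_as_events(es)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ES")
  expect_equal(c(ev$start, ev$end), c(200L, 300L))

  # acceptor shift only: 1 AA, 0 AD (plus strand)
  aa <- iso_df(list(a = list("chr1", "+", c(0, 100, 200, 300)),
                    b = list("chr1", "+", c(0, 100, 240, 300))))
  ev <- enumerate_as_events(aa)
  expect_equal(ev$type, "AA")
  expect_equal(c(ev$start, ev$end), c(200L, 240L))

  # the same structural shift on the minus strand is an AD
  ad_m <- iso_df(list(a = list("chr1", "-", c(0, 100, 200, 300)),
                      b = list("chr1", "-", c(0, 100, 240, 300))))
  expect_equal(enumerate_as_events(ad_m)$type, "AD")

  # retained intron
  ir <- iso_df(list(a = list("chr1", "+", c(0, 100, 200, 300)),
                    b = list("chr1", "+", c(0, 300))))
  ev <- enumerate_as_events(ir)
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$start, ev$end), c(100L, 200L))

  # single isoform: empty
  one <- iso_df(list(a = list("chr1", "+", c(0, 100, 200, 300))))
  expect_equal(nrow(enumerate_as_events(one)), 0L)
})

test_that("event enumeration equals the exhaustive pairwise oracle", {
  cfg <- quiet_cfg(seed = 51, n_genes = 12,
                   isoforms_per_gene = list(lambda = 2.5))
  ann <- gen_annotation(gen_genome(cfg), cfg)
  ts <- ann$annotation
  for (gid in unique(ts$gene_id)) {
    sub <- ts[ts$gene_id == gid, ]
    if (nrow(sub) < 2L) next
    iso <- data.frame(isoform_id = sub$transcript_id, locus_id = gid,
                      chrom = sub$chrom, strand = sub$strand,
                      stringsAsFactors = FALSE)
    iso$exons <- sub$exons
    got <- enumerate_as_events(iso)
    got_keys <- sort(unique(sprintf("%s:%d-%d", got$type, got$start,
                                    got$end)))
    want <- character(0)
    for (a in seq_len(nrow(sub) - 1L)) for (b in (a + 1L):nrow(sub))
      want <- c(want, oracle_pair_events(sub$exons[[a]], sub$exons[[b]],
                                         sub$strand[a]))
    expect_identical(got_keys, sort(unique(want)), label = gid)
    # symmetry: reversing isoform order changes nothing
    rev_iso <- iso[rev(seq_len(nrow(iso))), ]
    got_rev <- enumerate_as_events(rev_iso)
    expect_identical(got_keys,
                     sort(unique(sprintf("%s:%d-%d", got_rev$type,
                                         got_rev$start, got_rev$end))))
  }
})

test_that("event enumeration is invariant under coordinate translation", {
  base <- list(a = list("chr1", "+", c(0, 100, 200, 300, 400, 500)),
               b = list("chr1", "+", c(0, 100, 400, 500)),
               c = list("chr1", "+", c(0, 100, 200, 320, 400, 500)))
  ev0 <- enumerate_as_events(iso_df(base))
  shifted <- lapply(base, function(s)
    list(s[[1]], s[[2]], s[[3]] + 10000L))
  ev1 <- enumerate_as_events(iso_df(shifted))
  expect_equal(ev1$type, ev0$type)
  expect_equal(ev1$start - 10000L, ev0$start)
  expect_equal(ev1$end - 10000L, ev0$end)
})

test_that("as_summary tallies types and the IR fraction", {
  ev <- data.frame(type = c("ES", "IR"))
  s <- as_summary(ev)
  expect_equal(s$ir_fraction, 0.5)
  s2 <- as_summary(data.frame(type = c("ES", "ES", "AA", "AD")))
  expect_equal(s2$ir_fraction, 0)
  expect_equal(unname(s2$counts[c("ES", "AA", "AD", "IR")]), c(2L, 1L, 1L, 0L))
  expect_warning(s0 <- as_summary(data.frame(type = character(0))),
                 "undefined")
  expect_true(is.na(s0$ir_fraction))
})

test_that("simulated IR rate is recovered by event enumeration", {
  cfg <- quiet_cfg(seed = 52, n_genes = 60, chromosome_length = 800000L,
                   isoforms_per_gene = list(exact = 2),
                   as_event_rates = c(ES = 0.35, AA = 0.175, AD = 0.175,
                                      IR = 0.3, APA = 0))
  ann <- gen_annotation(gen_genome(cfg), cfg)
  ts <- ann$annotation
  iso <- data.frame(isoform_id = ts$transcript_id, locus_id = ts$gene_id,
                    chrom = ts$chrom, strand = ts$strand,
                    stringsAsFactors = FALSE)
  iso$exons <- ts$exons
  s <- as_summary(enumerate_as_events(iso))
  n <- sum(s$counts)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(s$ir_fraction - 0.3), 3 * se)
})

test_that("detect_apa clusters 3' ends and applies the two-FLNC rule", {
  ends <- data.frame(locus_id = "L1",
                     end_pos = c(rep(1000L, 3), rep(1500L, 2)))
  out <- detect_apa(ends, window = 20)
  expect_equal(nrow(out$sites), 2L)
  expect_equal(out$apa_loci, "L1")
  expect_equal(out$sites$position, c(1000L, 1500L))
  expect_equal(out$sites$support, c(3L, 2L))

  # singleton cluster dropped: one site left, locus not APA
  ends2 <- data.frame(locus_id = "L1",
                      end_pos = c(rep(1000L, 3), 1500L))
  out2 <- detect_apa(ends2, window = 20)
  expect_equal(nrow(out2$sites), 1L)
  expect_length(out2$apa_loci, 0L)

  # window merge: 1000 and 1010 are one cluster of support 2
  out3 <- detect_apa(data.frame(locus_id = "L1", end_pos = c(1000L, 1010L)),
                     window = 20)
  expect_equal(nrow(out3$sites), 1L)
  expect_equal(out3$sites$support, 2L)

  # order invariance
  perm <- ends[sample(nrow(ends)), , drop = FALSE]
  expect_equal(detect_apa(perm, window = 20)$sites, out$sites)
})

test_that("detect_fusion finds split reads across loci and nothing else", {
  seg <- data.frame(
    read_id = c("f1", "f1", "n1", "n1", "s1", "s1"),
    read_start = c(0L, 500L, 0L, 500L, 0L, 950L),
    read_end = c(500L, 1000L, 500L, 1000L, 940L, 1000L),
    read_length = 1000L,
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1", "chr2"),
    locus_id = c("A", "B", "A", "A", "A", "B"),
    stringsAsFactors = FALSE)
  out <- detect_fusion(seg)
  expect_equal(out$read_id, "f1")              # n1 same locus, s1 tiny 3' seg
  expect_equal(out$partner_5prime, "A")
  expect_equal(out$partner_3prime, "B")
  expect_equal(out$breakpoint, 500L)

  # closed loop: error-free simulated chimeras recovered with recall 1
  cfg <- sim_config(seed = 53, read_error_rate = 0, chimera_rate = 0.15,
                    short_read_rate = 0, trunc5_rate = 0, trunc3_rate = 0,
                    n_reads = 300, n_genes = 8)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  rd <- sim_flnc_reads(ann$annotation, ann$genome, cfg)
  chim <- rd$labels$read_id[rd$labels$category == "chimeric"]
  seg <- rd$segments
  seg$locus_id <- ann$annotation$gene_id[match(seg$transcript_id,
                                               ann$annotation$transcript_id)]
  fus <- detect_fusion(seg)
  cross <- tapply(seg$locus_id, seg$read_id, function(x) length(unique(x)) > 1)
  expect_gt(sum(cross), 0L)
  expect_setequal(fus$read_id, names(cross)[cross])  # recall 1 on truth
})
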