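# Loci clustering, isoform collapse, novelty rules, length bins.

test_that("cluster_loci applies the strand, span and exon overlap rules", {
  # 50% span overlap with a fully shared exon: one locus
  ts1 <- make_ts(list(a = list("chr1", "+", c(0, 400, 600, 1000)),
                      b = list("chr1", "+", c(500, 1000, 1200, 1500))))
  cl1 <- cluster_loci(ts1)
  expect_equal(length(unique(cl1$transcripts$locus_id)), 1L)

  # identical coordinates, opposite strands: two loci
  ts2 <- make_ts(list(a = list("chr1", "+", c(0, 500)),
                      b = list("chr1", "-", c(0, 500))))
  expect_equal(length(unique(cluster_loci(ts2)$transcripts$locus_id)), 2L)

  # 10% span overlap: below the 20% bar, two loci
  ts3 <- make_ts(list(a = list("chr1", "+", c(0, 1000)),
                      b = list("chr1", "+", c(900, 1900))))
  expect_equal(length(unique(cluster_loci(ts3)$transcripts$locus_id)), 2L)

  # exactly 20% span overlap ("reached") with a dominant exon pair: linked
  ts4 <- make_ts(list(a = list("chr1", "+", c(0, 100, 800, 1000)),
                      b = list("chr1", "+", c(800, 1800))))
  expect_equal(length(unique(cluster_loci(ts4)$transcripts$locus_id)), 1L)
  # same span geometry but only a sliver of exon overlap (20% not exceeded):
  # two loci, since the exon rule is strict
  ts4b <- make_ts(list(a = list("chr1", "+", c(0, 1000)),
                       b = list("chr1", "+", c(800, 1800))))
  expect_equal(length(unique(cluster_loci(ts4b)$transcripts$locus_id)), 2L)

  # span overlap met but no exon pair above 20%: not linked
  ts5 <- make_ts(list(a = list("chr1", "+", c(0, 100, 900, 1000)),
                      b = list("chr1", "+", c(890, 1000, 1800, 1900))))
  # exon pair (900,1000) vs (890,1000): overlap 100 of shorter 100 -> linked;
  # shift b to make the shared exon overlap tiny instead
  ts5 <- make_ts(list(a = list("chr1", "+", c(0, 100, 900, 1000)),
                      b = list("chr1", "+", c(995, 1500, 1800, 1900))))
  expect_equal(length(unique(cluster_loci(ts5)$transcripts$locus_id)), 2L)
})

test_that("cluster_loci equals brute-force transitive closure on random sets", {
  for (seed in 1:20) {
    ts <- random_ts(n = sample(10:60, 1), seed = seed)
    got <- cluster_loci(ts)$transcripts$locus_id
    want <- oracle_loci(ts)
    expect_identical(partition_signature(got), partition_signature(want),
                     label = sprintf("seed %d", seed))
  }
})

test_that("collapse_isoforms removes the shorter of identical chains", {
  ts <- make_ts(list(long = list("chr1", "+", c(0, 500, 700, 1200)),
                     short = list("chr1", "+", c(100, 500, 700, 1100)),
                     other = list("chr1", "+", c(0, 450, 700, 1200))))
  cl <- cluster_loci(ts)
  iso <- collapse_isoforms(cl$transcripts)
  # identical chains (500,700) collapse to the longer representative
  expect_equal(nrow(iso), 2L)
  rep1 <- iso[iso$isoform_id == "long", ]
  expect_equal(rep1$support_count, 2)
  expect_equal(rep1$spliced_length, 1000L)
  expect_false("short" %in% iso$isoform_id)
  # support conservation
  expect_equal(sum(iso$support_count), nrow(ts))
  # idempotence: collapsing the collapsed records changes nothing
  again <- transcript_set(iso$isoform_id, iso$chrom, iso$strand, iso$exons,
                          support_count = iso$support_count,
                          support_pid = iso$support_pid)
  again$locus_id <- iso$locus_id
  iso2 <- collapse_isoforms(again)
  expect_equal(iso2$chain[order(iso2$isoform_id)],
               iso$chain[order(iso$isoform_id)])
  expect_equal(sum(iso2$support_count), sum(iso$support_count))
})

test_that("mono-exon transcripts merge by containment", {
  ts <- make_ts(list(big = list("chr1", "+", c(0, 1000)),
                     inside = list("chr1", "+", c(100, 900)),
                     apart = list("chr1", "+", c(600, 1600))))
  cl <- cluster_loci(ts)
  iso <- collapse_isoforms(cl$transcripts)
  expect_false("inside" %in% iso$isoform_id)
  expect_equal(sum(iso$support_count), 3)
})

test_that("flag_full_length requires the reference's first donor, strand-aware", {
  ref <- make_ts(list(R = list("chr1", "+", c(0, 100, 200, 300, 400, 500))),
                 gene_id = "G")
  # shares the first donor (100) and downstream introns: full-length
  iso_full <- make_ts(list(q = list("chr1", "+", c(10, 100, 200, 300, 400, 480))))
  # starts downstream of the first donor: not full-length
  iso_trunc <- make_ts(list(q = list("chr1", "+", c(220, 300, 400, 480))))
  cl_f <- cluster_loci(iso_full)$transcripts; cl_f$locus_id <- "L1"
  cl_t <- cluster_loci(iso_trunc)$transcripts
  expect_true(flag_full_length(collapse_isoforms(cl_f), ref))
  expect_false(flag_full_length(collapse_isoforms(cl_t), ref))

  # minus strand: the first donor is the highest-coordinate intron boundary
  ref_m <- make_ts(list(R = list("chr1", "-", c(0, 100, 200, 300, 400, 500))),
                   gene_id = "G")
  iso_m_full <- make_ts(list(q = list("chr1", "-", c(20, 100, 200, 300, 400, 500))))
  iso_m_trunc <- make_ts(list(q = list("chr1", "-", c(20, 100, 200, 280))))
  expect_true(flag_full_length(
    collapse_isoforms(cluster_loci(iso_m_full)$transcripts), ref_m))
  expect_false(flag_full_length(
    collapse_isoforms(cluster_loci(iso_m_trunc)$transcripts), ref_m))

  # mono-exon: rule undefined
  mono <- collapse_isoforms(cluster_loci(
    make_ts(list(q = list("chr1", "+", c(0, 500)))))$transcripts)
  expect_true(is.na(flag_full_length(mono, ref)))
})

test_that("gene novelty follows the 20% same-strand overlap rule", {
  ref <- make_ts(list(R = list("chr1", "+", c(1000, 2000))), gene_id = "G1")
  loci <- data.frame(locus_id = c("L1", "L2", "L3", "L4"),
                     chrom = "chr1",
                     strand = c("+", "+", "-", "+"),
                     start = c(5000L, 1850L, 1000L, 1200L),
                     end = c(6000L, 2850L, 2000L, 2200L))
  out <- classify_gene_novelty(loci, ref)
  expect_equal(out$novelty, c("novel",   # zero overlap
                              "novel",   # 15% same-strand overlap
                              "novel",   # 100% overlap, converse direction
                              "known"))  # 80% same-strand overlap
  expect_equal(out$matched_genes[4], "G1")
})

test_that("isoform novelty applies splice-site matching and FLNC support", {
  ref <- make_ts(list(R = list("chr1", "+", c(0, 100, 200, 300, 400, 500)),
                      M = list("chr1", "+", c(800, 1200))), gene_id = "G")
  mk_iso <- function(exons, support, pid) {
    ts <- transcript_set("q", "chr1", "+",
                         list(matrix(exons, ncol = 2, byrow = TRUE)),
                         support_count = support, support_pid = pid)
    ts$locus_id <- "L1"
    collapse_isoforms(ts)
  }
  known <- mk_iso(c(0, 100, 200, 300), 1L, 95)      # all junctions known
  expect_equal(as.character(classify_isoform_novelty(known, ref)), "known")
  novel2 <- mk_iso(c(0, 100, 250, 300), 2L, 95)     # novel acceptor, 2 FLNC
  expect_equal(as.character(classify_isoform_novelty(novel2, ref)), "novel")
  novel1hi <- mk_iso(c(0, 100, 250, 300), 1L, 99.5) # 1 FLNC, PID > 99
  expect_equal(as.character(classify_isoform_novelty(novel1hi, ref)), "novel")
  novel1lo <- mk_iso(c(0, 100, 250, 300), 1L, 98.5) # 1 FLNC, PID <= 99
  expect_equal(as.character(classify_isoform_novelty(novel1lo, ref)),
               "discarded")
  # mono-exon: same single exon is known, a different one is candidate-novel
  mono_same <- mk_iso(c(800, 1200), 1L, 95)
  expect_equal(as.character(classify_isoform_novelty(mono_same, ref)), "known")
  mono_diff <- mk_iso(c(850, 1250), 2L, 95)
  expect_equal(as.character(classify_isoform_novelty(mono_diff, ref)), "novel")
})

test_that("locus_length_summary bins and percentages are exact", {
  s <- locus_length_summary(c(500, 1500, 2500, 3500))
  expect_equal(s$count, c(1L, 1L, 1L, 1L))
  expect_equal(s$percent, c(25, 25, 25, 25))
  # boundary conventions: 1000 falls in 1-2K, 3000 in >=3K
  s2 <- locus_length_summary(c(999, 1000, 2999, 3000))
  expect_equal(s2$count, c(1L, 1L, 1L, 1L))
})

test_that("catalogue recovers the simulated world exactly when noiseless", {
  cfg <- quiet_cfg(seed = 41, n_genes = 10, n_reads = 300,
                   isoforms_per_gene = list(lambda = 1.5))
  ann <- gen_annotation(gen_genome(cfg), cfg)
  rd <- sim_flnc_reads(ann$annotation, ann$genome, cfg)
  cat_ <- catalogue_transcripts(rd$alignments, ann$annotation)
  # loci = simulated genes
  expect_equal(nrow(cat_$loci), nrow(ann$truth$genes))
  # isoform chains = simulated chains
  truth_chains <- unique(vapply(seq_len(nrow(ann$annotation)), function(i)
    isoforge:::chain_key(ann$annotation$chrom[i], ann$annotation$strand[i],
                         ann$annotation$exons[[i]]), character(1)))
  expect_setequal(unique(cat_$isoforms$chain), truth_chains)
  # reference-only input: everything known
  expect_true(all(cat_$loci$novelty == "known"))
  expect_true(all(cat_$isoforms$novelty == "known"))
  # full-length flags: multi-exon isoforms sharing the first donor
  expect_true(all(na.omit(cat_$isoforms$full_length)))
})
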