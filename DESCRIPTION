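Package: isoforge
Title: Full-Length Transcriptome Characterization from Hybrid Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing a transcriptome from hybrid long- and
    short-read sequencing of the kind used in livestock muscle studies:
    classification of circular consensus (CCS) long reads into full-length
    non-chimeric (FLNC) categories, percent-identity based alignment triage
    with pre/post error-correction merging, strand-aware clustering of
    transcript alignments into loci, intron-chain collapse of redundant
    isoforms, novelty calling against a reference annotation, alternative
    splicing / polyadenylation / fusion event detection, coding-potential
    scoring and lncRNA filtering, FPKM quantification with a negative
    binomial Wald test for differential expression, hypergeometric term
    enrichment, and summary-statistics group tests. A synthetic-data module
    generates toy genomes, annotations, long reads and count matrices with
    known truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
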