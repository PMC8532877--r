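# Coding potential and lncRNA filtering: ORF discovery, a Fickett TESTCODE
# statistic, a small logistic coding-probability model trained on synthetic
# transcripts, and the conjunctive lncRNA rule (length >= 200 nt AND coding
# probability <= 0.5 AND no protein-database hit).

.STOPS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in the three forward frames
#'
#' Transcript orientation is assumed resolved upstream (FLNC reads carry
#' their primers), so only forward frames are scanned. Every ATG-initiated
#' ORF is reported: it ends at the next in-frame stop (`complete`) or at the
#' sequence end (`3'partial`). Additionally, when the region from the frame
#' start to the first in-frame stop contains no ATG, it is reported as a
#' `5'partial` ORF. Amino-acid length excludes the stop codon.
#'
#' @param seq a single nucleotide sequence (A/C/G/T/N).
#' @param min_aa minimum amino-acid length to keep (default 100).
#' @return data.frame: `frame` (1-3), `start`, `end` (1-based nucleotide
#'   coordinates, end inclusive of the stop codon when complete),
#'   `aa_length`, `completeness`.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (f in 1:3) {
    starts <- seq.int(f, n - 2L, by = 3L)
    if (length(starts) == 0L || starts[1L] > n - 2L) next
    codons <- substring(seq, starts, starts + 2L)
    stop_i <- which(codons %in% .STOPS)
    atg_i <- which(codons == "ATG")
    next_stop <- function(i) {
      s <- stop_i[stop_i >= i]
      if (length(s)) s[1L] else NA_integer_
    }
    for (i in atg_i) {
      s <- next_stop(i)
      if (!is.na(s)) {
        aa <- s - i  # codons before the stop
        if (aa >= min_aa)
          rows[[length(rows) + 1L]] <- data.frame(
            frame = f, start = starts[i], end = starts[s] + 2L,
            aa_length = aa, completeness = "complete",
            stringsAsFactors = FALSE)
      } else {
        aa <- length(codons) - i + 1L
        if (aa >= min_aa)
          rows[[length(rows) + 1L]] <- data.frame(
            frame = f, start = starts[i],
            end = starts[length(codons)] + 2L,
            aa_length = aa, completeness = "3'partial",
            stringsAsFactors = FALSE)
      }
    }
    # leading open region with no ATG: open at the 5' end
    first_stop <- if (length(stop_i)) stop_i[1L] else NA_integer_
    open_len <- if (is.na(first_stop)) length(codons) else first_stop - 1L
    no_atg_in_open <- length(atg_i) == 0L || atg_i[1L] > open_len
    if (open_len >= min_aa && no_atg_in_open)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, start = f,
        end = starts[open_len] + 2L + (if (is.na(first_stop)) 0L else 3L),
        aa_length = open_len, completeness = "5'partial",
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      completeness = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$frame, out$start), ]
}

# Fickett (1982) TESTCODE lookup tables: probability that a sequence with a
# given position/content parameter is coding, and the weight of each base.
.FICKETT <- list(
  pos_cut = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
  pos_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  cont_cut = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0),
  cont_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  cont_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14))

#' Fickett TESTCODE coding statistic
#'
#' Combines the positional asymmetry (max/min occupancy of each base over
#' the three codon positions) and the composition of each base through the
#' published TESTCODE lookup tables. Higher scores indicate coding-like
#' periodicity; the attainable range given the tables is roughly
#' [0.16, 1.30].
#'
#' @param seq a single nucleotide sequence of length >= 200.
#' @return numeric score.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 200L) .stopf("fickett_score requires length >= 200")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  phase <- rep_len(1:3, n)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(phase[v == b], nbins = 3L)
    pos_param <- max(cnt) / (min(cnt) + 1)
    pi <- which(pos_param >= .FICKETT$pos_cut)[1L]
    cont_param <- sum(v == b) / n
    ci <- which(cont_param >= .FICKETT$cont_cut)[1L]
    score <- score +
      .FICKETT$pos_prob[[b]][pi] * .FICKETT$pos_weight[[b]] +
      .FICKETT$cont_prob[[b]][ci] * .FICKETT$cont_weight[[b]]
  }
  score
}

# feature vector for the coding model: Fickett score, log10 max ORF length
# (aa), ORF coverage of the transcript
.coding_features <- function(seqs, min_aa = 30L) {
  t(vapply(seqs, function(s) {
    orfs <- find_orfs(s, min_aa = 1L)
    max_aa <- if (nrow(orfs)) max(orfs$aa_length) else 0L
    max_nt <- if (nrow(orfs)) max(orfs$end - orfs$start + 1L) else 0L
    c(fickett = fickett_score(s),
      log_orf = log10(max_aa + 1),
      orf_cov = max_nt / nchar(s))
  }, numeric(3)))
}

# synthetic training world: coding = random UTRs around a long stop-free ORF;
# noncoding = base-shuffled versions (composition kept, periodicity lost)
.sim_coding_set <- function(n, seed) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rand <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
    codon_pool <- apply(expand.grid(bases, bases, bases), 1L, paste,
                        collapse = "")
    codon_pool <- setdiff(codon_pool, .STOPS)
    coding <- vapply(seq_len(n), function(i) {
      n_codons <- sample(120:400, 1L)
      orf <- paste0("ATG",
                    paste(sample(codon_pool, n_codons, replace = TRUE),
                          collapse = ""),
                    sample(.STOPS, 1L))
      paste0(rand(sample(30:150, 1L)), orf, rand(sample(30:150, 1L)))
    }, character(1))
    noncoding <- vapply(coding, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    list(coding = coding, noncoding = noncoding)
  })
}

#' Train the logistic coding-probability model
#'
#' Fits a logistic regression of coding status on the Fickett score, the
#' log10 maximal ORF length and the ORF coverage, using synthetic coding
#' transcripts (long stop-free ORF with UTRs) versus their base-shuffled
#' counterparts. Deterministic given `seed`.
#'
#' @param n training transcripts per class (default 300).
#' @param seed RNG seed (default 2021).
#' @return list of class `coding_model` with `coef` (named coefficients).
#' @export
train_coding_model <- function(n = 300L, seed = 2021L) {
  sets <- .sim_coding_set(n, seed)
  x <- rbind(.coding_features(sets$coding), .coding_features(sets$noncoding))
  y <- rep(c(1L, 0L), each = n)
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(glm(y ~ fickett + log_orf + orf_cov, data = df,
                              family = binomial()))
  structure(list(coef = coef(fit)), class = "coding_model")
}

# frozen coefficients of train_coding_model(300, 2021), shipped as a plain
# text table so default scoring needs no refit
.default_coding_model <- function() {
  path <- system.file("extdata", "coding_model_synthetic.tsv",
                      package = "isoforge")
  tab <- utils::read.delim(path)
  structure(list(coef = setNames(tab$estimate, tab$term)),
            class = "coding_model")
}

#' Coding probability of transcript sequences
#'
#' Logistic combination of the Fickett score, maximal ORF length and ORF
#' coverage. With `model = NULL` the frozen synthetic-trained weights shipped
#' with the package are used.
#'
#' @param seqs character vector of transcript sequences (length >= 200 each).
#' @param model a `coding_model` from [train_coding_model()], or NULL.
#' @return numeric probabilities in [0, 1].
#' @export
coding_probability <- function(seqs, model = NULL) {
  if (is.null(model)) model <- .default_coding_model()
  if (!inherits(model, "coding_model") || anyNA(model$coef))
    .stopf("untrained or invalid coding model")
  x <- .coding_features(seqs)
  eta <- model$coef[1L] + x %*% model$coef[c("fickett", "log_orf", "orf_cov")]
  as.numeric(plogis(eta))
}

#' Classify long non-coding RNAs
#'
#' A transcript is called lncRNA when it is at least 200 nt long, its coding
#' probability is at most 0.5, and it has no protein-database hit. All three
#' conditions are required (conjunctive reading); raising the coding
#' probability can therefore never turn a non-lncRNA into an lncRNA.
#'
#' @param length transcript lengths (nt).
#' @param coding_prob coding probabilities in [0, 1].
#' @param db_hit logical: any protein-database hit.
#' @return logical vector.
#' @export
classify_lncrna <- function(length, coding_prob, db_hit) {
  if (any(coding_prob < 0 | coding_prob > 1, na.rm = TRUE))
    .stopf("coding_prob must lie in [0, 1]")
  length >= 200L & coding_prob <= 0.5 & !db_hit
}
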