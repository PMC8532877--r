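# Quantification and differential expression: FPKM, sample correlations,
# median-of-ratios size factors, a negative-binomial Wald test (unpaired,
# two groups), Benjamini-Hochberg adjustment, the DE thresholds
# (FPKM > 0, padj < 0.05, |log2FC| > 1), and shared/exclusive set tallies.

#' FPKM normalization of a count matrix
#'
#' FPKM = count / (length/1e3) / (library_size/1e6). Zero counts map to zero
#' FPKM and uniform scaling of a sample's counts leaves its FPKM vector
#' unchanged.
#'
#' @param counts features x samples matrix of non-negative counts.
#' @param lengths effective feature lengths in bases (one per row).
#' @return matrix of FPKM values, same shape and dimnames.
#' @export
compute_fpkm <- function(counts, lengths) {
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (any(lengths <= 0)) .stopf("feature lengths must be positive")
  if (length(lengths) != nrow(counts))
    .stopf("one length per feature required")
  libsize <- colSums(counts)
  if (any(libsize == 0)) .stopf("zero library size")
  sweep(counts / (lengths / 1e3), 2L, libsize / 1e6, `/`)
}

#' Pearson correlation between samples
#'
#' @param expr features x samples expression matrix (FPKM).
#' @return samples x samples symmetric correlation matrix with unit
#'   diagonal; constant columns give NA off-diagonals with a warning.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 2L) .stopf("need at least two samples")
  if (any(apply(expr, 2L, stats::sd) == 0))
    warning("constant sample column: undefined correlations set to NA",
            call. = FALSE)
  r <- suppressWarnings(cor(expr, method = "pearson"))
  diag(r) <- 1
  r
}

#' Median-of-ratios size factors
#'
#' The factor of a sample is the median over features (with all-positive
#' counts) of the ratio of its count to the feature's geometric mean across
#' samples. Falls back to library-size ratios, with a warning, when no
#' feature is positive in every sample.
#'
#' @param counts features x samples count matrix.
#' @return numeric size factors, one per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with positive counts in all samples; ",
            "using library-size ratios", call. = FALSE)
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  lk <- log(counts[pos, , drop = FALSE])
  gm <- rowMeans(lk)
  apply(exp(lk - gm), 2L, median)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Unpaired two-group design. Counts are normalized by size factors; the
#' per-feature dispersion is a method-of-moments estimate pooled across both
#' groups (floored at 1e-8); group means feed a Wald statistic on the log
#' ratio with the NB variance model, referred to a t distribution with
#' n1 + n2 - 2 degrees of freedom. Fold changes are oriented
#' `group2 / group1` (with groups in factor-level order, e.g. BF/LD for
#' levels LD, BF) and stabilized by a pseudo-count.
#'
#' @param counts features x samples count matrix.
#' @param groups factor with two levels, one per sample.
#' @param sf size factors (default [size_factors()]).
#' @param pseudo pseudo-count added to normalized group means for the fold
#'   change (default 0.5).
#' @return data.frame: `feature_id`, `base_mean_1`, `base_mean_2` (normalized
#'   group means), `log2_fold_change`, `dispersion`, `stat`, `p_value`,
#'   `padj` (Benjamini-Hochberg). Features with zero totals in both groups
#'   get NA statistics.
#' @export
nb_wald_test <- function(counts, groups, sf = size_factors(counts),
                         pseudo = 0.5) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) .stopf("exactly two groups required")
  if (min(table(groups)) < 2L) .stopf("need >= 2 samples per group")
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  z <- sweep(counts, 2L, sf, `/`)
  m1 <- rowMeans(z[, g1, drop = FALSE])
  m2 <- rowMeans(z[, g2, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(g2)
  # pooled within-group moments -> dispersion alpha in Var(K) = mu + alpha mu^2
  ss <- (z[, g1, drop = FALSE] - m1)^2 |> rowSums()
  ss <- ss + ((z[, g2, drop = FALSE] - m2)^2 |> rowSums())
  v_pool <- ss / (n1 + n2 - 2L)
  mu_bar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  # E Var(K_j/s_j) = q/s_j + alpha q^2; subtract the Poisson part on the
  # normalized scale before dividing by q^2
  s_inv <- mean(1 / sf)
  alpha <- pmax((v_pool - mu_bar * s_inv) / mu_bar^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  q1 <- m1 + pseudo; q2 <- m2 + pseudo
  var_m1 <- vapply(seq_along(m1), function(i)
    sum(q1[i] / sf[g1] + alpha[i] * q1[i]^2) / n1^2, numeric(1))
  var_m2 <- vapply(seq_along(m2), function(i)
    sum(q2[i] / sf[g2] + alpha[i] * q2[i]^2) / n2^2, numeric(1))
  se <- sqrt(var_m1 / q1^2 + var_m2 / q2^2)
  stat <- (log(q2) - log(q1)) / se
  p <- 2 * pt(-abs(stat), df = n1 + n2 - 2L)
  skip <- m1 == 0 & m2 == 0
  stat[skip] <- NA_real_; p[skip] <- NA_real_
  out <- data.frame(
    feature_id = rownames(counts) %||% sprintf("feature%05d",
                                               seq_len(nrow(counts))),
    base_mean_1 = m1, base_mean_2 = m2,
    log2_fold_change = log2(q2 / q1),
    dispersion = alpha, stat = stat, p_value = p,
    padj = NA_real_, stringsAsFactors = FALSE)
  ok <- !is.na(p)
  out$padj[ok] <- bh_adjust(p[ok])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (monotone over the p-value ranks, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call differential expression under the study thresholds
#'
#' A feature is differentially expressed when its adjusted p-value is below
#' 0.05, |log2 fold change| exceeds 1, and it is expressed (FPKM > 0 in at
#' least one sample by default, or in all samples with
#' `fpkm_filter = "all"`). Up = log2FC > 1, down = log2FC < -1, so
#' |up| + |down| = |DE|.
#'
#' @param results output of [nb_wald_test()].
#' @param fpkm FPKM matrix over the same features (rows aligned by
#'   position).
#' @param padj_max,lfc_min thresholds (defaults 0.05 and 1).
#' @param fpkm_filter `"any"` (default) or `"all"`: samples in which
#'   FPKM > 0 is required.
#' @return `results` with logical `is_de` and `direction`
#'   (`up`/`down`/`none`) appended.
#' @export
call_de <- function(results, fpkm, padj_max = 0.05, lfc_min = 1,
                    fpkm_filter = c("any", "all")) {
  fpkm_filter <- match.arg(fpkm_filter)
  if (nrow(fpkm) != nrow(results)) .stopf("results and fpkm must share features")
  expressed <- if (fpkm_filter == "any") rowSums(fpkm > 0) > 0
  else rowSums(fpkm > 0) == ncol(fpkm)
  de <- !is.na(results$padj) & results$padj < padj_max &
    abs(results$log2_fold_change) > lfc_min & expressed
  results$is_de <- de
  results$direction <- ifelse(de & results$log2_fold_change > lfc_min, "up",
                              ifelse(de & results$log2_fold_change < -lfc_min,
                                     "down", "none"))
  results
}

#' Shared and exclusive feature tallies
#'
#' @param sets named list of character vectors (duplicates ignored).
#' @return list with `shared_all` (n-way intersection size), `union`
#'   (union size), `exclusive` (named counts of features in exactly one
#'   set) and, for each unordered pair, `pairwise` (data.frame `set_a`,
#'   `set_b`, `shared`).
#' @export
set_overlap <- function(sets) {
  sets <- lapply(sets, unique)
  all_feat <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_feat %in% s,
                   logical(length(all_feat)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(all_feat))
  n_in <- rowSums(member)
  exclusive <- vapply(seq_along(sets), function(j)
    sum(member[, j] & n_in == 1L), integer(1))
  names(exclusive) <- names(sets)
  pairs <- if (length(sets) > 1L) {
    idx <- utils::combn(length(sets), 2L)
    data.frame(set_a = names(sets)[idx[1L, ]],
               set_b = names(sets)[idx[2L, ]],
               shared = apply(idx, 2L, function(ij)
                 sum(member[, ij[1L]] & member[, ij[2L]])),
               stringsAsFactors = FALSE)
  } else data.frame(set_a = character(0), set_b = character(0),
                    shared = integer(0))
  list(shared_all = sum(n_in == length(sets)),
       union = length(all_feat),
       exclusive = exclusive,
       pairwise = pairs)
}
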