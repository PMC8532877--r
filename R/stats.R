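# Small-sample group statistics: a pooled t test reconstructed from printed
# mean +/- SEM summaries, qPCR 2^-ddCt fold changes, and hypergeometric term
# enrichment with Benjamini-Hochberg FDR.

#' Two-sample t test from group summaries (mean, SEM, n)
#'
#' Reconstructs the test from printed summary statistics. The default pooled
#' (equal-variance) form with `df = n1 + n2 - 2` is the convention that
#' reproduces trait-table p-values in livestock studies reporting
#' mean +/- SEM at n = 4; with equal group sizes the statistic reduces to
#' `(m1 - m2) / sqrt(sem1^2 + sem2^2)`. Welch's form is available via
#' `var_equal = FALSE`.
#'
#' @param mean1,sem1,n1 first group: mean, standard error of the mean, size.
#' @param mean2,sem2,n2 second group.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return data.frame with `t`, `df`, `p_value` (vectorized over traits).
#' @export
pooled_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                                  var_equal = TRUE) {
  if (any(c(n1, n2) < 2L)) .stopf("need n >= 2 per group")
  if (any(c(sem1, sem2) < 0)) .stopf("SEM must be >= 0")
  s1 <- sem1 * sqrt(n1)  # back to sample SDs
  s2 <- sem2 * sqrt(n2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sem1^2 + sem2^2)
    df <- (sem1^2 + sem2^2)^2 /
      (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  # degenerate summaries: both SEMs zero
  zero <- se == 0
  t[zero & mean1 == mean2] <- 0
  p <- 2 * pt(-abs(t), df)
  if (any(zero & mean1 != mean2)) {
    warning("zero SEM with unequal means: p degenerates to 0", call. = FALSE)
    t[zero & mean1 != mean2] <- Inf * sign((mean1 - mean2)[zero & mean1 != mean2])
    p[zero & mean1 != mean2] <- 0
  }
  p[zero & mean1 == mean2] <- 1
  data.frame(t = t, df = df, p_value = p)
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' `fold = 2^-((Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator))`: the qPCR expression of a
#' target gene normalized to a reference gene (e.g. GAPDH) and a calibrator
#' sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the test sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator sample.
#' @return numeric fold changes.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  if (any(c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
            ct_ref_calibrator) <= 0))
    .stopf("Ct values must be positive")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

# upper-tail hypergeometric probability P(X >= k) by direct summation of
# the density ratio (no stats::phyper; that function serves as the oracle
# in the test suite)
.hyper_upper <- function(k, N, K, n) {
  hi <- min(K, n)
  if (k <= max(0L, K + n - N)) return(1)
  if (k > hi) return(0)
  # P(X = x) = C(K,x) C(N-K,n-x) / C(N,n), summed x = k..hi in log space
  x <- k:hi
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  min(1, sum(exp(logp)))
}

#' Hypergeometric term enrichment
#'
#' For every term, tests over-representation of the study set within the
#' population: `p = P(X >= k)` under Hypergeometric(N population features,
#' K annotated to the term, n study features). FDR is Benjamini-Hochberg
#' across terms; a term is significant at FDR <= 0.05.
#'
#' @param study character vector of study features (e.g. DE genes); must be
#'   a subset of `population`.
#' @param population character vector: the background (e.g. all genes with
#'   FPKM >= 1 in all samples).
#' @param term_map data.frame with columns `feature`, `term` (features
#'   outside the population are ignored).
#' @param fdr_max significance threshold (default 0.05).
#' @return data.frame: `term`, `population_size`, `annotated`, `study_size`,
#'   `study_hits`, `p_value`, `fdr`, `significant`, sorted by p-value.
#' @export
hypergeom_enrich <- function(study, population, term_map, fdr_max = 0.05) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    .stopf("study set must be a subset of the population")
  term_map <- term_map[term_map$feature %in% population, , drop = FALSE]
  N <- length(population); n <- length(study)
  terms <- split(unique(term_map)$feature, unique(term_map)$term)
  rows <- lapply(names(terms), function(tm) {
    feats <- terms[[tm]]
    K <- length(feats)
    k <- sum(study %in% feats)
    data.frame(term = tm, population_size = N, annotated = K,
               study_size = n, study_hits = k,
               p_value = .hyper_upper(k, N, K, n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$fdr <= fdr_max
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
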