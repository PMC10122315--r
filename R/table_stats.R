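#' Pearson chi-squared test on a contingency table of counts
#'
#' Cohort characteristic tables compare categorical covariates (sex,
#' primiparity, maternal smoking) between conception groups with
#' Pearson's chi-squared test on the printed counts:
#' `chi2 = sum((O - E)^2 / E)` with expected counts from the
#' independence margins and `df = (r - 1)(c - 1)`.  No continuity
#' correction is applied by default; the Yates correction is available
#' for 2x2 tables only.
#'
#' @param counts Matrix (r x c) of non-negative integer counts.
#' @param continuity_correction Apply the Yates correction (2x2 only).
#' @return List: `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(counts, continuity_correction = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("all row and column sums must be positive")
  if (continuity_correction && !all(dim(counts) == 2))
    stopf("the continuity correction applies to 2x2 tables only")
  ht <- stats::chisq.test(counts, correct = continuity_correction)
  list(chi2 = unname(ht$statistic), df = as.integer(ht$parameter),
       p = unname(ht$p.value))
}

#' Wilcoxon rank-sum test for two samples
#'
#' Two-sided rank-sum comparison of a continuous characteristic between
#' two groups.  Small untied samples use the exact distribution;
#' otherwise the tie-corrected normal approximation is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List: `statistic` (rank-sum W of `x`), `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stopf("both samples must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE))
  list(statistic = unname(ht$statistic), p = min(unname(ht$p.value), 1))
}
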