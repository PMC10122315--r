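#' Build candidate regions from per-CpG results
#'
#' A candidate is a maximal run of consecutive CpGs (in genomic order)
#' that all pass the nominal entry threshold (`p_adj < p_enter`), share
#' the effect sign, and are separated by at most `maxgap_bp`.  A
#' non-passing CpG between two passing ones breaks the run.
#'
#' @param results Per-CpG result table with `probe_id`, `effect` and
#'   `p_adj` (empirical-null-corrected nominal p-values).
#' @param manifest Probe manifest providing chromosome and position.
#' @param maxgap_bp Maximal distance between consecutive members
#'   (default 500 bp).
#' @param p_enter Nominal entry p-value (default 0.05).
#' @return List of candidates; each is a data.frame of member rows
#'   (`probe_id`, `chromosome`, `position`, `effect`, `se`, `p_adj`)
#'   sorted by position.
#' @export
find_candidates <- function(results, manifest, maxgap_bp = 500,
                            p_enter = 0.05) {
  idx <- match(results$probe_id, manifest$probe_id)
  if (anyNA(idx)) stopf("results contain probes absent from the manifest")
  tab <- data.frame(probe_id = results$probe_id,
                    chromosome = manifest$chromosome[idx],
                    position = manifest$position[idx],
                    effect = results$effect,
                    se = results$se,
                    p_adj = results$p_adj,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chromosome, tab$position), , drop = FALSE]
  pass <- !is.na(tab$p_adj) & tab$p_adj < p_enter & !is.na(tab$effect)
  if (!any(pass)) return(list())
  n <- nrow(tab)
  ## a new run starts when: not consecutive in the table, chromosome or
  ## sign changes, or the gap exceeds maxgap
  run_id <- integer(n)
  cur <- 0L
  last_i <- -10L
  for (i in which(pass)) {
    new_run <- i != last_i + 1L || cur == 0L ||
      tab$chromosome[i] != tab$chromosome[last_i] ||
      sign(tab$effect[i]) != sign(tab$effect[last_i]) ||
      tab$position[i] - tab$position[last_i] > maxgap_bp
    if (new_run) cur <- cur + 1L
    run_id[i] <- cur
    last_i <- i
  }
  lapply(seq_len(cur), function(k) {
    rows <- tab[run_id == k, , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
}

#' Correlation-adjusted inverse-variance region statistic
#'
#' Combines the per-CpG effects of a candidate region by
#' inverse-variance weighting while accounting for the correlation of
#' the member methylation levels:
#' \deqn{B = \frac{\sum_i w_i b_i}{\sum_i w_i}, \qquad
#'   \mathrm{var}(B) = \frac{\sum_i \sum_j w_i w_j R_{ij} s_i s_j}
#'   {(\sum_i w_i)^2}, \qquad w_i = 1 / s_i^2.}
#' With `R = I` this is the classical fixed-effect meta-analysis; with
#' perfectly correlated members there is no precision gain and `se_B`
#' equals the member standard error.
#'
#' @param b Member effect estimates.
#' @param se Member standard errors (> 0).
#' @param R Member correlation matrix (symmetric, unit diagonal).
#' @return List: `B`, `se_B`, `z`, `p`.
#' @export
dmr_stat <- function(b, se, R) {
  k <- length(b)
  if (length(se) != k || !all(dim(R) == k))
    stopf("b, se and R must agree in dimension")
  if (any(se <= 0)) stopf("standard errors must be positive")
  if (any(abs(R - t(R)) > 1e-8) || any(abs(diag(R) - 1) > 1e-8))
    stopf("R must be symmetric with unit diagonal")
  w <- 1 / se^2
  sw <- sum(w)
  B <- sum(w * b) / sw
  ws <- w * se                       # = 1/se
  varB <- as.numeric(t(ws) %*% R %*% ws) / sw^2
  if (varB <= 0) stopf("non-positive combined variance; R is not valid")
  se_B <- sqrt(varB)
  z <- B / se_B
  list(B = B, se_B = se_B, z = z, p = 2 * pnorm(-abs(z)))
}

#' Call differentially methylated regions
#'
#' Builds candidates with [find_candidates()], computes the
#' correlation-adjusted combined statistic of each candidate using the
#' empirical correlation of member M-values across the stratum's
#' children, applies BH across all candidates, and flags regions
#' significant when they contain at least `min_cpgs` CpGs and reach
#' `q < fdr`.
#'
#' @param results Per-CpG result table (see [find_candidates()]).
#' @param m M-value matrix restricted to the same children used for the
#'   per-CpG fits.
#' @param manifest Probe manifest.
#' @param maxgap_bp,p_enter Candidate construction parameters.
#' @param min_cpgs Minimal region size for significance (default 3).
#' @param fdr FDR threshold on the region q-values (default 0.01).
#' @param min_pairs Minimal complete pairs for a member correlation;
#'   sparser pairs fall back to 0 with a warning (default 10).
#' @return Data.frame of regions: `chromosome`, `start`, `end` (1-based
#'   inclusive bounds of the first/last member), `n_cpgs`,
#'   `member_probe_ids` (comma-separated), `effect_B`, `se_B`, `z`, `p`,
#'   `q`, `significant`.
#' @export
call_dmrs <- function(results, m, manifest, maxgap_bp = 500,
                      p_enter = 0.05, min_cpgs = 3, fdr = 0.01,
                      min_pairs = 10) {
  cands <- find_candidates(results, manifest, maxgap_bp, p_enter)
  if (length(cands) == 0)
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      member_probe_ids = character(), effect_B = numeric(),
                      se_B = numeric(), z = numeric(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(cands, function(cd) {
    miss <- setdiff(cd$probe_id, rownames(m))
    if (length(miss) > 0)
      stopf("candidate member '%s' missing from the M matrix", miss[1])
    k <- nrow(cd)
    if (k == 1) {
      R <- matrix(1, 1, 1)
    } else {
      R <- cor(t(m[cd$probe_id, , drop = FALSE]),
               use = "pairwise.complete.obs")
      npairs <- crossprod(!is.na(t(m[cd$probe_id, , drop = FALSE])))
      sparse <- npairs < min_pairs & row(R) != col(R)
      if (any(sparse | is.na(R))) {
        warnf("correlations with < %d complete pairs set to 0", min_pairs)
        R[sparse | is.na(R)] <- 0
      }
    }
    st <- dmr_stat(cd$effect, cd$se, R)
    data.frame(chromosome = cd$chromosome[1],
               start = min(cd$position), end = max(cd$position),
               n_cpgs = k,
               member_probe_ids = paste(cd$probe_id, collapse = ","),
               effect_B = st$B, se_B = st$se_B, z = st$z, p = st$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$n_cpgs >= min_cpgs & out$q < fdr
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Co-methylation report around a center CpG
#'
#' Collects the probes within a genomic window around a center probe
#' (total width `window_bp`, i.e. half the width on each side, closed at
#' the boundaries), computes all pairwise Pearson correlations of their
#' methylation levels over complete pairs, and adjusts the two-sided
#' correlation p-values of the upper triangle with the
#' Benjamini-Yekutieli procedure.
#'
#' @param m Methylation matrix (M-values or betas), probes x samples.
#' @param manifest Probe manifest.
#' @param center_probe Probe id at the window center.
#' @param window_bp Total window width in bp (default 50,000, i.e.
#'   +/- 25 kb).
#' @param alpha Significance level on the adjusted p-values (default
#'   0.05).
#' @return Object of class `cometh_report`: `center_probe_id`,
#'   `window_bp`, `member_probe_ids`, `r` (correlation matrix), `p_adj`
#'   (BY-adjusted p-value matrix), `significant` (logical matrix).
#' @export
comethylation <- function(m, manifest, center_probe, window_bp = 50000,
                          alpha = 0.05) {
  ci <- match(center_probe, manifest$probe_id)
  if (is.na(ci)) stopf("center probe '%s' absent from manifest", center_probe)
  half <- window_bp / 2
  members <- manifest$probe_id[
    manifest$chromosome == manifest$chromosome[ci] &
      abs(manifest$position - manifest$position[ci]) <= half]
  members <- intersect(members, rownames(m))
  if (!center_probe %in% members)
    stopf("center probe '%s' absent from the matrix", center_probe)
  k <- length(members)
  sub <- t(m[members, , drop = FALSE])
  r <- cor(sub, use = "pairwise.complete.obs")
  npair <- crossprod(!is.na(sub))
  ## two-sided p from the t reference; complete correlation -> p = 0
  df <- pmax(npair - 2, 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-tstat, df)
  p[abs(r) >= 1] <- .Machine$double.xmin
  diag(p) <- NA
  up <- upper.tri(p)
  p_adj <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  p_adj[up] <- by_fdr(p[up])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(center_probe_id = center_probe, window_bp = window_bp,
                 member_probe_ids = members, r = r, p_adj = p_adj,
                 significant = !is.na(p_adj) & p_adj < alpha,
                 alpha = alpha),
            class = "cometh_report")
}

#' @export
print.cometh_report <- function(x, ...) {
  k <- length(x$member_probe_ids)
  cat(sprintf(
    "cometh_report: %d probes within %g kb of %s; %d/%d significant pairs\n",
    k, x$window_bp / 1000, x$center_probe_id,
    sum(x$significant[upper.tri(x$significant)]), k * (k - 1) / 2))
  invisible(x)
}
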