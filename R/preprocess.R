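#' Beta/M-value transforms
#'
#' The analysis scale is the M-value, `m = log2(beta / (1 - beta))`
#' (logit2); `m_to_beta()` is its inverse `2^m / (1 + 2^m)`.  Betas at
#' exactly 0 or 1 are nudged into the open interval by `epsilon` so the
#' transform stays finite.
#'
#' @param beta Beta values in \[0, 1\] (vector or matrix).
#' @param m M-values (vector or matrix).
#' @param epsilon Open-interval nudge (default 1e-6).
#' @return Transformed values with the same shape and dimnames.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  beta <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

logit2 <- beta_to_m
inv_logit2 <- m_to_beta

#' Remove probes flagged in the manifest
#'
#' Drops cross-reactive probes and probes whose last three bases overlap
#' a SNP, the standard array exclusion lists.  Relative probe order is
#' preserved.
#'
#' @param x A [meth_matrix()].
#' @param manifest Probe manifest covering all probes of `x`.
#' @return Filtered [meth_matrix()].
#' @export
exclude_flagged_probes <- function(x, manifest) {
  missing_pr <- setdiff(rownames(x$beta), manifest$probe_id)
  if (length(missing_pr) > 0)
    stopf("probe '%s' absent from manifest", missing_pr[1])
  flags <- manifest$cross_reactive | manifest$snp_overlap_last3
  bad <- manifest$probe_id[flags]
  keep <- setdiff(rownames(x$beta), bad)
  if (length(keep) == 0)
    warnf("all probes are flagged; returning an empty matrix")
  subset_meth(x, probes = keep)
}

#' Mask unreliable measurements by detection p-value
#'
#' Beta entries whose detection p-value exceeds `threshold` become
#' missing; probes that end up missing in every sample are dropped.
#' Partial failure is left for [greedy_filter()] to arbitrate.
#'
#' @param x A [meth_matrix()] with detection p-values.
#' @param threshold Detection p-value cutoff (default 0.01).
#' @return Masked [meth_matrix()] (detection p-values retained).
#' @export
mask_by_detection <- function(x, threshold = 0.01) {
  if (is.null(x$detection_p))
    stopf(paste("no detection p-values present; skip the masking stage",
                "explicitly if they are unavailable"))
  b <- x$beta
  b[!is.na(x$detection_p) & x$detection_p > threshold] <- NA
  all_na <- rowSums(!is.na(b)) == 0
  out <- meth_matrix(b, x$detection_p)
  if (any(all_na)) out <- subset_meth(out, probes = which(!all_na))
  out
}

#' Greedy removal of unreliable probes and samples
#'
#' Iteratively removes the single probe *or* sample with the highest
#' fraction of unreliable (missing) entries, recomputing fractions after
#' each removal, until the worst fraction is at most
#' `max_unreliable_frac`.  Ties are broken deterministically: probes
#' before samples, then lowest current index.
#'
#' @param x A [meth_matrix()] whose missing entries mark unreliable
#'   measurements (e.g. after [mask_by_detection()]).
#' @param max_unreliable_frac Stopping threshold (default 0.05).
#' @return List with the filtered `matrix` ([meth_matrix()]),
#'   `removed_probes` and `removed_samples` (character vectors, in
#'   removal order).
#' @export
greedy_filter <- function(x, max_unreliable_frac = 0.05) {
  bad <- is.na(x$beta)
  removed_p <- character()
  removed_s <- character()
  repeat {
    if (nrow(bad) == 0 || ncol(bad) == 0) {
      warnf("greedy filtering removed all probes or samples")
      break
    }
    pf <- rowMeans(bad)
    sf <- colMeans(bad)
    worst <- max(max(pf), max(sf))
    if (worst <= max_unreliable_frac) break
    if (max(pf) >= max(sf)) {        # probe wins ties
      i <- which.max(pf)             # lowest index among ties
      removed_p <- c(removed_p, rownames(bad)[i])
      bad <- bad[-i, , drop = FALSE]
    } else {
      j <- which.max(sf)
      removed_s <- c(removed_s, colnames(bad)[j])
      bad <- bad[, -j, drop = FALSE]
    }
  }
  list(matrix = subset_meth(x, probes = rownames(bad),
                            samples = colnames(bad)),
       removed_probes = removed_p, removed_samples = removed_s)
}

#' Gap-based multimodality detection for one probe
#'
#' Sorts the beta values of a probe within one sex stratum and splits
#' them into groups wherever the gap between consecutive sorted values
#' exceeds `gap_threshold`.  The probe is flagged as multimodal when
#' there are at least two groups and every group is larger than
#' `outlier_frac` of the sample (i.e. the split is not driven by lone
#' outliers).  Beta distributions are sex-specific on the X chromosome,
#' so this check must be run for girls and boys separately.
#'
#' @param values Beta values of one probe within one sex (NAs dropped).
#' @param gap_threshold Minimal gap defining a split (default 0.05).
#' @param outlier_frac Groups of at most this fraction of samples do not
#'   count toward the flag (default 0.01).
#' @return List: `n_groups`, `group_assignment` (integer vector aligned
#'   to the non-missing input order), `flagged`.
#' @export
detect_gaps <- function(values, gap_threshold = 0.05, outlier_frac = 0.01) {
  keep <- !is.na(values)
  v <- values[keep]
  if (length(v) == 0) stopf("detect_gaps needs at least one non-missing value")
  o <- order(v)
  splits <- which(diff(v[o]) > gap_threshold)
  grp_sorted <- cumsum(c(1L, as.integer(seq_along(v)[-1] %in% (splits + 1L))))
  grp <- integer(length(v))
  grp[o] <- grp_sorted
  n_groups <- max(grp_sorted)
  sizes <- tabulate(grp_sorted, n_groups)
  flagged <- n_groups >= 2 && all(sizes > outlier_frac * length(v))
  out <- rep(NA_integer_, length(values))
  out[keep] <- grp
  list(n_groups = n_groups, group_assignment = out, flagged = flagged)
}

## Three-state beta-mixture EM fit (unmethylated / hemimethylated /
## methylated).  Deterministic: states are initialized by distance to
## the 5%/50%/95% quantiles (robust to probe-type compression, which
## narrows the observed beta range), shape parameters by weighted
## method of moments.
.beta_mix_fit <- function(b, max_iter = 100, tol = 1e-6) {
  b <- pmin(pmax(b, 1e-6), 1 - 1e-6)
  n <- length(b)
  cent <- quantile(b, c(0.05, 0.5, 0.95), names = FALSE)
  if (min(diff(cent)) < 1e-3) return(NULL)   # no mixture structure
  state <- max.col(-abs(outer(b, cent, "-")))
  w <- matrix(0, n, 3)
  w[cbind(seq_len(n), state)] <- 1
  mom <- function(ww) {
    sw <- colSums(ww)
    mu <- colSums(ww * b) / sw
    v <- colSums(ww * (b - rep(mu, each = n))^2) / sw
    v <- pmax(pmin(v, mu * (1 - mu) * 0.99), 1e-6)
    k <- mu * (1 - mu) / v - 1
    list(a = pmax(mu * k, 0.05), b = pmax((1 - mu) * k, 0.05),
         pi = sw / n)
  }
  par <- mom(w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d <- vapply(1:3, function(k)
      par$pi[k] * dbeta(b, par$a[k], par$b[k]), numeric(n))
    tot <- rowSums(d)
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    w <- d / tot
    par <- mom(w)
    if (any(!is.finite(unlist(par)))) return(NULL)
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  par$state <- max.col(w)
  par
}

#' Beta-mixture quantile normalization of type II probes
#'
#' Per sample, fits a three-state (unmethylated / hemimethylated /
#' methylated) beta-mixture by EM separately to the type I and type II
#' probe betas.  Type I probes are the reference and pass through
#' unchanged.  Type II probes in the unmethylated and methylated states
#' are quantile-mapped onto the corresponding type I mixture component;
#' hemimethylated values are rescaled by the monotone dilation that
#' interpolates between the mapped state boundaries.  Output stays in
#' \[0, 1\] and preserves the within-type ranking of each sample.
#'
#' @param x A [meth_matrix()].
#' @param manifest Probe manifest providing `design_type`.
#' @param min_per_type Minimal non-missing probes per design type needed
#'   to attempt normalization of a sample (default 50).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return Normalized [meth_matrix()].  Samples whose EM fit fails fall
#'   back to identity with a warning.
#' @export
bmiq_normalize <- function(x, manifest, min_per_type = 50,
                           max_iter = 100, tol = 1e-6) {
  idx <- match(rownames(x$beta), manifest$probe_id)
  if (anyNA(idx)) stopf("matrix probe missing from manifest")
  t2 <- manifest$design_type[idx] == "II"
  b <- x$beta
  for (s in seq_len(ncol(b))) {
    b1 <- b[!t2, s]
    b2 <- b[t2, s]
    ok1 <- !is.na(b1); ok2 <- !is.na(b2)
    if (sum(ok1) < min_per_type || sum(ok2) < min_per_type) {
      warnf("sample '%s': too few probes per design type; left unchanged",
            colnames(b)[s])
      next
    }
    f1 <- .beta_mix_fit(b1[ok1], max_iter, tol)
    f2 <- .beta_mix_fit(b2[ok2], max_iter, tol)
    if (is.null(f1) || is.null(f2) ||
        any(tabulate(f1$state, 3) == 0) || any(tabulate(f2$state, 3) == 0)) {
      warnf("sample '%s': EM fit degenerate; left unchanged",
            colnames(b)[s])
      next
    }
    v <- b2[ok2]
    st <- f2$state
    out <- v
    ## U and M states: CDF map from the type II onto the type I component
    u <- st == 1
    out[u] <- qbeta(pbeta(v[u], f2$a[1], f2$b[1]), f1$a[1], f1$b[1])
    m <- st == 3
    out[m] <- qbeta(pbeta(v[m], f2$a[3], f2$b[3]), f1$a[3], f1$b[3])
    ## H state: monotone dilation between the mapped boundaries
    h <- st == 2
    if (any(h)) {
      lo_new <- if (any(u)) max(out[u]) else min(v[h])
      hi_new <- if (any(m)) min(out[m]) else max(v[h])
      lo_old <- min(v[h]); hi_old <- max(v[h])
      if (hi_new < lo_new) { tmp <- lo_new; lo_new <- hi_new; hi_new <- tmp }
      if (hi_old > lo_old && sum(h) > 1) {
        out[h] <- lo_new + (v[h] - lo_old) / (hi_old - lo_old) *
          (hi_new - lo_new)
      } else {
        out[h] <- (lo_new + hi_new) / 2
      }
    }
    b[t2, s][ok2] <- pmin(pmax(out, 0), 1)
  }
  meth_matrix(b, x$detection_p)
}

#' Run the full QC/normalization chain on one sex stratum
#'
#' Fixed stage order: flagged-probe exclusion, detection p-value
#' masking, greedy probe/sample filtering, per-probe gap-based
#' multimodality flagging, beta-mixture type I/II normalization, and the
#' logit2 transform to M-values.  No stage combines information across
#' sexes; call this separately on the samples of each sex.
#'
#' @param x A [meth_matrix()] holding the samples of one sex stratum.
#' @param manifest Probe manifest.
#' @param detection_threshold Detection p-value cutoff; `NULL` (or a
#'   matrix without detection p-values) skips masking.
#' @param max_unreliable_frac Greedy-filter stopping threshold.
#' @param gap_threshold,outlier_frac Gap-detection parameters.
#' @param drop_flagged Drop gap-flagged multimodal probes (default
#'   `FALSE`: flag only).
#' @param normalize Apply [bmiq_normalize()] (default `TRUE`).
#' @param epsilon Open-interval nudge for the logit2 transform.
#' @return List: `beta` ([meth_matrix()]), `m` (M-value matrix),
#'   `gap_flagged` (character vector of multimodal probes),
#'   `removed_probes`, `removed_samples`, and `log` (stage-by-stage
#'   record).
#' @export
preprocess_pipeline <- function(x, manifest, detection_threshold = 0.01,
                                max_unreliable_frac = 0.05,
                                gap_threshold = 0.05, outlier_frac = 0.01,
                                drop_flagged = FALSE, normalize = TRUE,
                                epsilon = 1e-6) {
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  n0 <- nrow(x$beta)
  x <- exclude_flagged_probes(x, manifest)
  note("exclude_flagged: %d -> %d probes", n0, nrow(x$beta))
  if (!is.null(detection_threshold) && !is.null(x$detection_p)) {
    n0 <- nrow(x$beta)
    x <- mask_by_detection(x, detection_threshold)
    note("mask_by_detection(%g): %d -> %d probes, %d cells masked",
         detection_threshold, n0, nrow(x$beta), sum(is.na(x$beta)))
  } else note("mask_by_detection: skipped (no detection p-values)")
  gf <- greedy_filter(x, max_unreliable_frac)
  x <- gf$matrix
  note("greedy_filter(%g): removed %d probes, %d samples",
       max_unreliable_frac, length(gf$removed_probes),
       length(gf$removed_samples))
  flagged <- character()
  if (nrow(x$beta) > 0) {
    fl <- vapply(seq_len(nrow(x$beta)), function(i)
      detect_gaps(x$beta[i, ], gap_threshold, outlier_frac)$flagged,
      logical(1))
    flagged <- rownames(x$beta)[fl]
    note("detect_gaps: %d multimodal probes %s", length(flagged),
         if (drop_flagged) "(dropped)" else "(flag only)")
    if (drop_flagged && length(flagged) > 0)
      x <- subset_meth(x, probes = setdiff(rownames(x$beta), flagged))
  }
  if (normalize && nrow(x$beta) > 0) {
    x <- bmiq_normalize(x, manifest)
    note("bmiq_normalize: applied")
  }
  m <- beta_to_m(x$beta, epsilon)
  list(beta = x, m = m, gap_flagged = flagged,
       removed_probes = gf$removed_probes,
       removed_samples = gf$removed_samples, log = log)
}
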