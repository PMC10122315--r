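#' Stratified bootstrap consistency of XWAS findings
#'
#' Measures how consistently each CpG is selected at the FDR threshold
#' under resampling.  Trios (a child together with its parents) are
#' resampled with replacement separately within the ART and non-ART
#' strata of one sex, so every replicate has exactly the original group
#' sizes; the full analysis — model fit, empirical-null estimation,
#' rescaling, BH selection — is rerun on each replicate, and the
#' per-CpG proportion of replicates in which the CpG was significant is
#' reported.  The resampling unit is the trio so that parental-
#' adjustment models stay well defined within every replicate.
#'
#' @param m M-value matrix covering the stratum's children (and parents
#'   for M2/M4).
#' @param sheet Sample sheet.
#' @param model_id,sex Model and child stratum to rerun.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param fdr FDR threshold defining selection (default 0.01).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param null_min_n Floor on the number of features for the per-
#'   replicate empirical-null fit (passed to
#'   [estimate_empirical_null()]).
#' @param null_iter,null_burn_in Gibbs settings for the per-replicate
#'   empirical-null fit.
#' @return Data.frame (class `bootstrap_summary`): `probe_id`,
#'   `n_selected`, `proportion`, `rank` (descending proportion, ties
#'   broken by probe id).  The per-replicate discovery-set sizes are in
#'   the `"n_discoveries"` attribute.
#' @export
bootstrap_consistency <- function(m, sheet, model_id = "M1", sex,
                                  n_boot = 1000, fdr = 0.01, seed = 1,
                                  null_min_n = 500, null_iter = 5000,
                                  null_burn_in = 1000) {
  if (n_boot < 1) stopf("n_boot must be >= 1")
  kids <- sheet[sheet$role == "child" & !is.na(sheet$child_sex) &
                  sheet$child_sex == sex & !is.na(sheet$art), ,
                drop = FALSE]
  trios_art <- kids$trio_id[kids$art == 1]
  trios_non <- kids$trio_id[kids$art == 0]
  if (length(trios_art) == 0 || length(trios_non) == 0)
    stopf("both ART and non-ART trios are required in the '%s' stratum",
          sex)
  seeds <- derive_seeds(seed, n_boot)
  probes <- rownames(m)
  n_sel <- setNames(integer(length(probes)), probes)
  n_disc <- integer(n_boot)
  for (r in seq_len(n_boot)) {
    draw <- with_seed(seeds[r], c(
      sample(trios_art, length(trios_art), replace = TRUE),
      sample(trios_non, length(trios_non), replace = TRUE)))
    boot <- .resample_trios(m, sheet, draw)
    res <- run_xwas(boot$m, boot$sheet, model_id, sex)
    res <- adjust_inflation(res, seed = seeds[r], min_n = null_min_n,
                            n_iter = null_iter, burn_in = null_burn_in)
    hits <- res$probe_id[!is.na(res$q) & res$q < fdr]
    n_disc[r] <- length(hits)
    n_sel[hits] <- n_sel[hits] + 1L
  }
  out <- data.frame(probe_id = probes, n_selected = unname(n_sel),
                    proportion = unname(n_sel) / n_boot,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$proportion, out$probe_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_discoveries") <- n_disc
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}

## Materialize a bootstrap replicate: duplicate the drawn trios' samples
## under unique ids ("<sample>.b<k>" for the k-th draw of a trio).
.resample_trios <- function(m, sheet, trio_draw) {
  pieces_sheet <- vector("list", length(trio_draw))
  cols <- character()
  new_ids <- character()
  for (k in seq_along(trio_draw)) {
    rows <- sheet[sheet$trio_id == trio_draw[k], , drop = FALSE]
    ids <- rows$sample_id
    nid <- paste0(ids, ".b", k)
    rows$sample_id <- nid
    rows$trio_id <- paste0(rows$trio_id, ".b", k)
    pieces_sheet[[k]] <- rows
    keep <- ids %in% colnames(m)
    cols <- c(cols, ids[keep])
    new_ids <- c(new_ids, nid[keep])
  }
  bm <- m[, cols, drop = FALSE]
  colnames(bm) <- new_ids
  list(m = bm, sheet = do.call(rbind, pieces_sheet))
}
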