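model_ids <- c("M1", "M2", "M3", "M4")

## Fixed-effect covariate sets per model.  M1 is the main model:
## CpG ~ ART + maternal age + maternal smoking + maternal BMI +
## primiparity, with plate as a random intercept.  M2 adds per-CpG
## parental M-values (maternal only in the boys stratum, maternal and
## paternal in the girls stratum), M3 adds birthweight and gestational
## age, M4 combines both extensions.
model_covariates <- function(model_id) {
  base <- c("maternal_age", "maternal_smoking", "maternal_bmi",
            "primiparity")
  extra <- if (model_id %in% c("M3", "M4"))
    c("birthweight", "gestational_age") else character()
  c(base, extra)
}

model_uses_parents <- function(model_id) model_id %in% c("M2", "M4")

#' Build the fixed-effects design for one sex stratum and model
#'
#' Rows are the children of the requested sex with complete data on the
#' exposure and all model covariates (complete-case analysis; children
#' with missing ART status are excluded, mirroring exclusion rather than
#' imputation of the exposure).  Maternal smoking is expanded into three
#' indicator columns with `Never` as the reference level.
#'
#' @param sheet Sample sheet (see [as_sample_sheet()]).
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param sex Child stratum, `"M"` or `"F"`.
#' @param parental_m Optional per-CpG parental M-values for M2/M4: a
#'   list with elements `mother` (and `father` for the girls stratum),
#'   numeric vectors named by child sample id.  When omitted for M2/M4,
#'   the parental columns are appended later per CpG (see
#'   [run_xwas()]); the design then carries the trio mapping needed to
#'   do so.
#' @return List: `X` (design matrix incl. intercept and `art` column),
#'   `sample_ids` (children, row order of `X`), `plate_id`,
#'   `mother_ids`/`father_ids` (aligned parental sample ids, `NA` when a
#'   parent is absent), `n_excluded`, `model_id`, `sex`.
#' @export
build_design <- function(sheet, model_id = "M1", sex, parental_m = NULL) {
  stopifnot(model_id %in% model_ids, sex %in% c("M", "F"))
  kids <- sheet[sheet$role == "child" & !is.na(sheet$child_sex) &
                  sheet$child_sex == sex, , drop = FALSE]
  if (nrow(kids) == 0) stopf("no children of sex '%s' in the sheet", sex)
  covs <- model_covariates(model_id)
  need <- c("art", covs)
  ok <- stats::complete.cases(kids[need])
  n_excluded <- sum(!ok)
  kids <- kids[ok, , drop = FALSE]
  if (nrow(kids) == 0) stopf("no usable rows after complete-case filtering")

  smk <- factor(kids$maternal_smoking, levels = smoking_levels)
  X <- cbind(intercept = 1, art = kids$art,
             maternal_age = kids$maternal_age,
             maternal_bmi = kids$maternal_bmi,
             primiparity = kids$primiparity,
             smoking_Past = as.numeric(smk == "Past"),
             smoking_FirstTrimester = as.numeric(smk == "FirstTrimester"),
             smoking_FirstTrimesterAndAfter =
               as.numeric(smk == "FirstTrimesterAndAfter"))
  if (model_id %in% c("M3", "M4"))
    X <- cbind(X, birthweight = kids$birthweight,
               gestational_age = kids$gestational_age)
  ## indicator columns of factor levels unobserved in this stratum are
  ## dropped (they would make the design singular); the exposure and
  ## intercept must always carry contrast
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  const["intercept"] <- FALSE
  if (const["art"])
    stopf("ART status is constant in the '%s' stratum; no contrast", sex)
  dropped <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]

  mother_ids <- father_ids <- rep(NA_character_, nrow(kids))
  if (model_uses_parents(model_id)) {
    mothers <- sheet[sheet$role == "mother", , drop = FALSE]
    fathers <- sheet[sheet$role == "father", , drop = FALSE]
    mother_ids <- mothers$sample_id[match(kids$trio_id, mothers$trio_id)]
    if (any(is.na(mother_ids)))
      stopf("model %s needs maternal samples; missing for trio(s): %s",
            model_id,
            paste(head(kids$trio_id[is.na(mother_ids)], 5), collapse = ", "))
    if (sex == "F") {
      father_ids <- fathers$sample_id[match(kids$trio_id, fathers$trio_id)]
      if (any(is.na(father_ids)))
        stopf(paste("girls-stratum model %s needs paternal samples;",
                    "missing for trio(s): %s"), model_id,
              paste(head(kids$trio_id[is.na(father_ids)], 5),
                    collapse = ", "))
    }
    if (!is.null(parental_m)) {
      mm <- parental_m$mother[kids$sample_id]
      X <- cbind(X, mother_m = unname(mm))
      if (sex == "F") X <- cbind(X, father_m =
                                   unname(parental_m$father[kids$sample_id]))
    }
  }
  rownames(X) <- kids$sample_id
  list(X = X, sample_ids = kids$sample_id, plate_id = kids$plate_id,
       mother_ids = mother_ids, father_ids = father_ids,
       n_excluded = n_excluded, dropped_columns = dropped,
       model_id = model_id, sex = sex)
}

## Profiled REML for a single random intercept (plate).  The covariance
## is sigma^2 (I + lambda Z Z') with Z the plate indicator; for a given
## lambda the GLS quantities reduce to per-plate sums, and lambda is
## profiled by 1-D minimization of the REML criterion.  lambda = 0
## reproduces OLS exactly.
.reml_rint <- function(y, X, g) {
  n <- length(y); p <- ncol(X)
  gi <- split(seq_len(n), g)
  ng <- lengths(gi)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  Sg <- vapply(gi, function(ii) colSums(X[ii, , drop = FALSE]), numeric(p))
  syg <- vapply(gi, function(ii) sum(y[ii]), 0)
  SSm <- matrix(vapply(seq_along(gi), function(k) tcrossprod(Sg[, k]),
                       numeric(p * p)), p * p, length(gi))
  quantities <- function(lam) {
    cg <- lam / (1 + lam * ng)
    A <- XtX - matrix(SSm %*% cg, p, p)
    bvec <- Xty - Sg %*% (cg * syg)
    q <- yty - sum(cg * syg^2)
    list(A = A, b = bvec, q = q, cg = cg)
  }
  crit <- function(loglam) {
    lam <- exp(loglam)
    qt <- quantities(lam)
    ch <- tryCatch(chol(qt$A), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), qt$b))
    rss <- qt$q - sum(qt$b * beta)
    if (rss <= 0) return(Inf)
    sum(log1p(lam * ng)) + 2 * sum(log(diag(ch))) + (n - p) * log(rss)
  }
  opt <- optimize(crit, c(-12, 8))
  lam <- if (crit(-30) <= opt$objective) 0 else exp(opt$minimum)
  qt <- quantities(lam)
  Ainv <- chol2inv(chol(qt$A))
  beta <- drop(Ainv %*% qt$b)
  rss <- qt$q - sum(qt$b * beta)
  s2 <- rss / (n - p)
  list(beta = beta, se = sqrt(pmax(s2 * diag(Ainv), 0)), lambda = lam,
       sigma2 = s2)
}

#' Fit the per-CpG random-intercept model
#'
#' Linear mixed model for one CpG: fixed effects from `design`, a plate
#' random intercept estimated by profiled restricted maximum likelihood.
#' The reported effect is the coefficient of the ART indicator;
#' `z = effect / se` is referred to the standard normal (the large-sample
#' reference also used by the downstream empirical-null rescaling).
#' When the estimated plate variance is zero the fit coincides with
#' ordinary least squares; with fewer than two plates the model falls
#' back to OLS with a notice.
#'
#' @param y Numeric vector of child M-values for one CpG, named by
#'   sample id or aligned with `design$X`; missing values are dropped
#'   (complete case).
#' @param design A design from [build_design()] (with any parental
#'   columns already appended).
#' @param min_extra Minimal excess of observations over fixed-effect
#'   columns (default 2).
#' @return List: `effect`, `se`, `z`, `p`, `n_used`, `lambda` (ratio of
#'   plate to residual variance), `method` (`"REML"` or `"OLS"`).
#' @export
fit_cpg <- function(y, design, min_extra = 2) {
  X <- design$X
  plate <- design$plate_id
  if (!is.null(names(y))) y <- y[rownames(X)]
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; plate <- plate[ok]
  n <- length(y); p <- ncol(X)
  if (n < p + min_extra)
    stopf("too few usable observations (%d) for %d fixed effects", n, p)
  qrX <- qr(X)
  if (qrX$rank < p)
    stopf("singular design; collinear column(s): %s",
          paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))
  art_col <- which(colnames(X) == "art")
  if (length(unique(plate)) < 2) {
    fit <- stats::lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    eff <- fit$coefficients[art_col]
    se <- sqrt(s2 * XtXi[art_col, art_col])
    method <- "OLS"
    lambda <- 0
  } else {
    fit <- .reml_rint(y, X, plate)
    eff <- fit$beta[art_col]
    se <- fit$se[art_col]
    method <- "REML"
    lambda <- fit$lambda
  }
  z <- eff / se
  list(effect = unname(eff), se = unname(se), z = unname(z),
       p = 2 * pnorm(-abs(z)), n_used = n, lambda = lambda,
       method = method)
}

#' Run a sex-stratified XWAS over all CpGs
#'
#' Fits the requested model at every probe of the M-value matrix for the
#' children of one sex and returns the raw per-CpG summary statistics.
#' For models M2/M4 the parental M-values at the same CpG are appended
#' to the design per CpG (maternal in the boys stratum, maternal and
#' paternal in the girls stratum).  Per-CpG failures are recorded in the
#' `"failures"` attribute rather than aborting the scan; sample order in
#' the input matrix is irrelevant (alignment is by sample id).
#'
#' @param m M-value matrix (probes x samples) covering the children of
#'   the stratum and, for M2/M4, their parents.
#' @param sheet Sample sheet.
#' @param model_id `"M1"` (main model), `"M2"`, `"M3"` or `"M4"`.
#' @param sex `"M"` or `"F"`.
#' @return Data.frame with one row per probe: `probe_id`, `model_id`,
#'   `sex_stratum`, `effect`, `se`, `z_raw`, `p_raw`, `n_used`.
#' @export
run_xwas <- function(m, sheet, model_id = "M1", sex) {
  design <- build_design(sheet, model_id, sex)
  missing_kids <- setdiff(design$sample_ids, colnames(m))
  if (length(missing_kids) > 0)
    stopf("children absent from the M matrix: %s",
          paste(head(missing_kids, 5), collapse = ", "))
  use_parents <- model_uses_parents(model_id)
  if (use_parents) {
    par_ids <- design$mother_ids
    if (sex == "F") par_ids <- c(par_ids, design$father_ids)
    missing_par <- setdiff(par_ids, colnames(m))
    if (length(missing_par) > 0)
      stopf("model %s: parental samples absent from the M matrix: %s",
            model_id, paste(head(missing_par, 5), collapse = ", "))
  }
  probes <- rownames(m)
  ykids <- m[, design$sample_ids, drop = FALSE]
  res <- data.frame(probe_id = probes, model_id = model_id,
                    sex_stratum = sex, effect = NA_real_, se = NA_real_,
                    z_raw = NA_real_, p_raw = NA_real_,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  failures <- character()
  for (j in seq_along(probes)) {
    dj <- design
    if (use_parents) {
      Xj <- cbind(design$X, mother_m = m[j, design$mother_ids])
      if (sex == "F") Xj <- cbind(Xj, father_m = m[j, design$father_ids])
      dj$X <- Xj
    }
    f <- tryCatch(fit_cpg(unname(ykids[j, ]), dj),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      failures <- c(failures, sprintf("%s: %s", probes[j], f))
      next
    }
    res$effect[j] <- f$effect; res$se[j] <- f$se
    res$z_raw[j] <- f$z; res$p_raw[j] <- f$p
    res$n_used[j] <- f$n_used
  }
  attr(res, "failures") <- failures
  attr(res, "n_excluded") <- design$n_excluded
  res
}
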