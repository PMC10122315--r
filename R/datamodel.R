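#' Construct a methylation matrix object
#'
#' Bundles a probe-by-sample matrix of beta values (methylated fraction,
#' in \[0, 1\]) with an optional aligned matrix of detection p-values.
#' Missing measurements are `NA` and stay `NA` through the pipeline; they
#' are never recoded as 0.
#'
#' @param beta Numeric matrix, probes in rows and samples in columns, with
#'   rownames (probe ids) and colnames (sample ids).  Non-missing values
#'   must lie in \[0, 1\].
#' @param detection_p Optional numeric matrix of per-measurement detection
#'   p-values with the same dimensions and dimnames as `beta`.
#' @return An object of class `meth_matrix`: a list with elements `beta`
#'   and `detection_p`.
#' @export
meth_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stopf("`beta` must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stopf("`beta` must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(beta)))
    stopf("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta)))
    stopf("duplicate sample ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
          rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
          beta[bad[1, 1], bad[1, 2]])
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta)) ||
        !identical(dimnames(detection_p), dimnames(beta)))
      stopf("`detection_p` must have the same shape and dimnames as `beta`")
    badp <- !is.na(detection_p) & (detection_p < 0 | detection_p > 1)
    if (any(badp)) stopf("detection p-values must lie in [0, 1]")
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d probes x %d samples (%s detection p-values)\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "without" else "with"))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

#' Subset a methylation matrix by probes and/or samples
#'
#' Selects probes and samples (by id, logical mask or integer index)
#' from a [meth_matrix()], keeping the beta and detection p-value
#' matrices aligned.
#'
#' @param x A [meth_matrix()].
#' @param probes,samples Row/column selection; `NULL` keeps everything.
#' @return The subsetted [meth_matrix()].
#' @export
subset_meth <- function(x, probes = NULL, samples = NULL) {
  b <- x$beta
  d <- x$detection_p
  if (!is.null(probes)) {
    b <- b[probes, , drop = FALSE]
    if (!is.null(d)) d <- d[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    b <- b[, samples, drop = FALSE]
    if (!is.null(d)) d <- d[, samples, drop = FALSE]
  }
  structure(list(beta = b, detection_p = d), class = "meth_matrix")
}

manifest_columns <- c("probe_id", "chromosome", "position", "design_type",
                      "gene_annotation", "regulatory_annotation",
                      "cross_reactive", "snp_overlap_last3", "par_region")

#' Validate and normalize a probe manifest
#'
#' A probe manifest is a data.frame with one row per array probe:
#' `probe_id`, `chromosome`, 1-based `position`, `design_type`
#' (Infinium chemistry, `"I"` or `"II"`), optional `gene_annotation` and
#' `regulatory_annotation`, and logical flags `cross_reactive`,
#' `snp_overlap_last3` (last three bases overlap a SNP) and `par_region`
#' (pseudoautosomal).  Coordinates follow the 1-based inclusive
#' convention throughout the package.
#'
#' @param manifest A data.frame with at least `probe_id`, `chromosome`,
#'   `position`, `design_type`.  Missing optional columns are filled with
#'   defaults (empty annotation, `FALSE` flags).
#' @param sort_by_position Sort rows by chromosome then position
#'   (default `TRUE`); region detection requires positional order.
#' @return The validated manifest data.frame.
#' @export
as_probe_manifest <- function(manifest, sort_by_position = TRUE) {
  manifest <- as.data.frame(manifest)
  req <- c("probe_id", "chromosome", "position", "design_type")
  miss <- setdiff(req, names(manifest))
  if (length(miss) > 0)
    stopf("manifest is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stopf("duplicate probe_id in manifest: '%s'",
          manifest$probe_id[duplicated(manifest$probe_id)][1])
  if (any(is.na(manifest$position)) || any(manifest$position < 1))
    stopf("manifest positions must be integers >= 1")
  if (!all(manifest$design_type %in% c("I", "II")))
    stopf("design_type must be 'I' or 'II'; offending value '%s'",
          setdiff(unique(manifest$design_type), c("I", "II"))[1])
  manifest$position <- as.integer(manifest$position)
  if (is.null(manifest$gene_annotation)) manifest$gene_annotation <- NA_character_
  if (is.null(manifest$regulatory_annotation)) manifest$regulatory_annotation <- NA_character_
  for (fl in c("cross_reactive", "snp_overlap_last3", "par_region")) {
    if (is.null(manifest[[fl]])) manifest[[fl]] <- FALSE
    manifest[[fl]] <- as.logical(manifest[[fl]])
  }
  if (sort_by_position)
    manifest <- manifest[order(manifest$chromosome, manifest$position), ,
                         drop = FALSE]
  rownames(manifest) <- NULL
  manifest[manifest_columns]
}

smoking_levels <- c("Never", "Past", "FirstTrimester", "FirstTrimesterAndAfter")

samplesheet_columns <- c("sample_id", "trio_id", "role", "child_sex", "art",
                         "plate_id", "maternal_age", "maternal_smoking",
                         "maternal_bmi", "primiparity", "birthweight",
                         "gestational_age")

#' Validate and normalize a sample sheet
#'
#' One row per measured sample.  `role` is `child`, `mother` or `father`;
#' `child_sex` (`M`/`F`) and the birth covariates are defined on child
#' rows; `art` is the binary conception-mode exposure (1 = assisted
#' reproduction) and must be constant within a trio.  Maternal covariates
#' (`maternal_age` in years, `maternal_smoking` with levels
#' `Never`, `Past`, `FirstTrimester`, `FirstTrimesterAndAfter`,
#' `maternal_bmi` in kg/m^2,
#' `primiparity` 0/1) may be missing; missingness stays explicit (`NA`).
#'
#' @param sheet A data.frame with the columns listed above (`plate_id` is
#'   the bisulfite-conversion plate used as the batch factor).
#' @return The validated sample sheet data.frame.
#' @export
as_sample_sheet <- function(sheet) {
  sheet <- as.data.frame(sheet)
  req <- c("sample_id", "trio_id", "role", "art")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0)
    stopf("sample sheet is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stopf("duplicate sample_id in sample sheet: '%s'",
          sheet$sample_id[duplicated(sheet$sample_id)][1])
  if (!all(sheet$role %in% c("child", "mother", "father")))
    stopf("role must be one of child/mother/father; offending value '%s'",
          setdiff(unique(sheet$role), c("child", "mother", "father"))[1])
  sx <- sheet$child_sex[sheet$role == "child"]
  if (!all(is.na(sx) | sx %in% c("M", "F")))
    stopf("child_sex must be 'M' or 'F' on child rows")
  if (!all(sheet$art %in% c(0, 1, NA)))
    stopf("art must be binary 0/1 (1 = ART conception)")
  smk <- sheet$maternal_smoking
  if (!is.null(smk) && !all(is.na(smk) | smk %in% smoking_levels))
    stopf("unknown maternal_smoking level '%s'; allowed levels: %s",
          setdiff(unique(smk[!is.na(smk)]), smoking_levels)[1],
          paste(smoking_levels, collapse = ", "))
  ## trio structure: exactly one child, at most one mother/father per trio
  tab <- table(sheet$trio_id, factor(sheet$role,
                                     c("child", "mother", "father")))
  if (any(tab[, "child"] != 1))
    stopf("each trio_id must have exactly one child row (violated by '%s')",
          rownames(tab)[tab[, "child"] != 1][1])
  if (any(tab[, c("mother", "father")] > 1))
    stopf("a trio may have at most one mother and one father row")
  art_by_trio <- tapply(sheet$art, sheet$trio_id,
                        function(a) length(unique(a[!is.na(a)])))
  if (any(art_by_trio > 1, na.rm = TRUE))
    stopf("art status must be identical across members of a trio")
  for (cc in setdiff(samplesheet_columns, names(sheet))) sheet[[cc]] <- NA
  rownames(sheet) <- NULL
  sheet[samplesheet_columns]
}
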