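#' Read a beta-value matrix (and optional detection p-values) from disk
#'
#' Expects delimited text (TSV/CSV autodetected) with the probe id in the
#' first column and one column per sample; the header row carries sample
#' ids.  Values are validated against \[0, 1\]; the configured missing
#' token becomes `NA`.
#'
#' @param beta_path Path to the beta-value table.
#' @param detection_path Optional path to an aligned detection p-value
#'   table with identical probe/sample labels.
#' @param na_token Missing-value token in the files (default `"NA"`).
#' @return A [meth_matrix()].
#' @export
read_methylation <- function(beta_path, detection_path = NULL,
                             na_token = "NA") {
  beta <- .read_matrix(beta_path, na_token)
  detp <- NULL
  if (!is.null(detection_path)) {
    detp <- .read_matrix(detection_path, na_token)
    if (!identical(dim(detp), dim(beta)) ||
        !identical(dimnames(detp), dimnames(beta)))
      stopf("detection matrix '%s' does not match the shape/labels of '%s'",
            detection_path, beta_path)
  }
  meth_matrix(beta, detp)
}

.read_matrix <- function(path, na_token) {
  dt <- data.table::fread(path, na.strings = na_token, data.table = FALSE)
  if (ncol(dt) < 2) stopf("'%s' has no sample columns", path)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a beta-value matrix (and optional detection p-values) to disk
#'
#' Inverse of [read_methylation()]; round-trips values at full precision.
#'
#' @param x A [meth_matrix()].
#' @param beta_path Output path for the beta table.
#' @param detection_path Optional output path for the detection p-values.
#' @param sep Field separator (default tab).
#' @return Invisibly, `beta_path`.
#' @export
write_methylation <- function(x, beta_path, detection_path = NULL,
                              sep = "\t") {
  .write_matrix(x$beta, beta_path, sep)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p))
      stopf("no detection p-values to write")
    .write_matrix(x$detection_p, detection_path, sep)
  }
  invisible(beta_path)
}

.write_matrix <- function(m, path, sep) {
  ## full %.17g precision so read/write round-trips bit-identically
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- NA_character_
  df <- data.frame(probe_id = rownames(m), chr, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
}

#' Read a probe manifest from delimited text
#'
#' @param path Path to a TSV/CSV with the columns described in
#'   [as_probe_manifest()] (required: `probe_id`, `chromosome`,
#'   `position`, `design_type`).
#' @return A validated, position-sorted manifest data.frame.
#' @export
read_manifest <- function(path) {
  as_probe_manifest(data.table::fread(path, data.table = FALSE,
                                      na.strings = "NA"))
}

#' Read a sample sheet from delimited text
#'
#' @param path Path to a TSV/CSV with the columns described in
#'   [as_sample_sheet()].
#' @return A validated sample sheet data.frame.
#' @export
read_samplesheet <- function(path) {
  as_sample_sheet(data.table::fread(path, data.table = FALSE,
                                    na.strings = "NA"))
}

#' Write differentially methylated regions as a BED file
#'
#' Internal coordinates are 1-based inclusive (the convention used for
#' reporting array loci); BED uses 0-based half-open, so a region
#' `start..end` is written as `start - 1`, `end`.  Output is BED3+score:
#' chrom, bed start, bed end, region name, -log10(q) score rounded to 3
#' decimals.
#'
#' @param dmrs A DMR result data.frame from [call_dmrs()] (columns
#'   `chromosome`, `start`, `end`, `n_cpgs`, `q`).
#' @param path Output path.
#' @param metadata Optional named list written to a `.json` sidecar next
#'   to `path` (seed, model, thresholds, ...).
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# DMR export: BED 0-based half-open; score = -log10(q)", con)
  if (nrow(dmrs) > 0) {
    if (any(dmrs$start > dmrs$end))
      stopf("DMR with start > end cannot be written")
    lines <- sprintf("%s\t%d\t%d\tDMR_%d\t%.3f",
                     dmrs$chromosome, dmrs$start - 1L, dmrs$end,
                     seq_len(nrow(dmrs)), -log10(dmrs$q))
    writeLines(lines, con)
  }
  if (!is.null(metadata)) write_run_metadata(path, metadata)
  invisible(path)
}

#' Write a result table with a run-metadata sidecar
#'
#' Writes `x` as TSV and a `<path>.json` sidecar recording how the table
#' was produced (seed, model id, thresholds, package version, timestamp).
#'
#' @param x A data.frame.
#' @param path Output TSV path.
#' @param metadata Named list of run parameters for the sidecar.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(x, path, metadata = list()) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA",
                     quote = FALSE)
  write_run_metadata(path, metadata)
  invisible(path)
}

write_run_metadata <- function(path, metadata) {
  metadata$package <- "xwastrio"
  metadata$version <- as.character(utils::packageVersion("xwastrio"))
  metadata$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(path, ".json"))
}
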