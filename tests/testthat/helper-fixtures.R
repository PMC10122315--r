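## Small hand-built fixtures shared across tests.

tiny_manifest <- function(n = 5, positions = NULL, design = NULL,
                          cross = NULL, snp = NULL) {
  as_probe_manifest(data.frame(
    probe_id = sprintf("cg%02d", seq_len(n)),
    chromosome = "X",
    position = positions %||% seq(100, by = 1000, length.out = n),
    design_type = design %||% rep("II", n),
    cross_reactive = cross %||% rep(FALSE, n),
    snp_overlap_last3 = snp %||% rep(FALSE, n),
    stringsAsFactors = FALSE
  ))
}

tiny_beta <- function(n_probes = 5, n_samples = 4, seed = 1) {
  m <- with_seed_t(seed, matrix(runif(n_probes * n_samples, 0.05, 0.95),
                                n_probes, n_samples))
  dimnames(m) <- list(sprintf("cg%02d", seq_len(n_probes)),
                      sprintf("S%02d", seq_len(n_samples)))
  m
}

## test-local seed sandbox (the package-internal helper is not exported)
with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## A minimal valid sample sheet of complete trios.
tiny_sheet <- function(n_art = 3, n_non = 3, sexes = NULL, seed = 1) {
  n <- n_art + n_non
  trio <- sprintf("T%03d", seq_len(n))
  art <- rep(c(1, 0), c(n_art, n_non))
  sexes <- sexes %||% with_seed_t(seed, sample(c("M", "F"), n, TRUE))
  rows <- lapply(seq_len(n), function(i) {
    data.frame(
      sample_id = paste0(trio[i], c("_C", "_M", "_F")),
      trio_id = trio[i],
      role = c("child", "mother", "father"),
      child_sex = c(sexes[i], NA, NA),
      art = art[i],
      plate_id = sprintf("P%d", (i %% 2) + 1),
      maternal_age = 30 + (i %% 5),
      maternal_smoking = "Never",
      maternal_bmi = 23 + (i %% 3),
      primiparity = i %% 2,
      birthweight = c(3500 + 10 * i, NA, NA),
      gestational_age = c(40, NA, NA),
      stringsAsFactors = FALSE
    )
  })
  as_sample_sheet(do.call(rbind, rows))
}
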