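#' Configuration for the synthetic trio-methylation generator
#'
#' Bundles and validates the parameters of [generate_trio_dataset()].
#' Defaults emulate the salient structure of X-chromosome methylation in
#' a newborn trio cohort measured on an Illumina-style array:
#' \itemize{
#' \item Males carry one X, so male beta values are bimodal near 0 and 1.
#' \item In females, random X inactivation silences one copy; at probes
#'   where the two alleles are discordant the measured beta is the
#'   average of a near-0 and a near-1 allelic state, producing the
#'   intermediate "bump" of the female beta distribution
#'   (`frac_xci_mid` of non-escape probes).
#' \item Probes escaping X inactivation (`frac_escape`) are
#'   hypomethylated in both sexes.
#' \item Type II probes are compressed toward 0.5 relative to type I
#'   (`type2_compression` multiplies the deviation from 0.5), giving the
#'   normalization stage a real distortion to correct.
#' \item Effects, batch shifts, covariate slopes and noise act on the
#'   M (logit2) scale; betas are derived by the inverse-logit2 map and
#'   clipped to the open unit interval by `epsilon`.
#' }
#'
#' @param n_trios_art,n_trios_nonart Number of complete trios per
#'   conception group.
#' @param n_cpgs Number of probes.
#' @param frac_type2 Fraction of design-type II probes (EPIC-like 0.84).
#' @param frac_escape Fraction of probes escaping X inactivation (~0.12
#'   of X-linked genes are reported to escape).
#' @param frac_xci_mid Fraction of non-escape probes with discordant
#'   allelic states in females (the XCI intermediate mode).
#' @param block_size,block_rho Probes per co-methylation block and the
#'   within-block latent correlation in \[0, 1).
#' @param n_plates Number of bisulfite-conversion plates; samples are
#'   assigned uniformly at random.
#' @param plate_sd SD of the per-plate random intercept on the M scale.
#' @param noise_sd Residual SD on the M scale.
#' @param parent_child_rho Correlation between parental and child
#'   M-value deviations at heritable probes (must be <= 0.5 so that a
#'   child can correlate equally with both unrelated parents).
#' @param frac_heritable Fraction of probes at which parent and child
#'   deviations are correlated.
#' @param planted_effects List of planted ART effects; each element is
#'   `list(probes = <integer indices>, delta = <M-value shift>,
#'   sex = "M"|"F"|"both")`.  Multi-probe entries are planted regions:
#'   the generator tightens the genomic gaps inside a planted span so
#'   the span is a genuine region (gaps drawn from `gap_range`).
#' @param covariate_effects Named list of M-scale slopes applied to the
#'   centered child covariates (`maternal_age`, `maternal_bmi`,
#'   `primiparity`, `birthweight`, `gestational_age`, `maternal_smoking`
#'   as an any-smoking indicator).
#' @param type2_compression Multiplier (0, 1\] shrinking type II beta
#'   deviations from 0.5; 1 disables the distortion.
#' @param gap_range,large_gap_range,frac_large_gaps Inter-probe distance
#'   model (bp): most gaps uniform in `gap_range`, a fraction
#'   `frac_large_gaps` uniform in `large_gap_range`.
#' @param detection_fail_frac Background fraction of failed
#'   measurements (detection p drawn from U(0.01, 1) instead of
#'   U(0, 0.001)).
#' @param n_bad_samples,n_bad_probes,bad_fail_rate Number of
#'   deliberately unreliable samples/probes and their per-cell failure
#'   rate, to exercise greedy filtering.
#' @param epsilon Open-interval clip for betas (prevents infinite
#'   M-values; below array quantization).
#' @param seed Integer seed; the same configuration and seed reproduce
#'   the dataset bit-identically.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_trios_art = 100, n_trios_nonart = 100,
                             n_cpgs = 1000,
                             frac_type2 = 0.84, frac_escape = 0.12,
                             frac_xci_mid = 0.35,
                             block_size = 5, block_rho = 0.4,
                             n_plates = 8, plate_sd = 0.15,
                             noise_sd = 0.5,
                             parent_child_rho = 0.3, frac_heritable = 0.4,
                             planted_effects = list(),
                             covariate_effects = list(),
                             type2_compression = 0.8,
                             gap_range = c(150, 450),
                             large_gap_range = c(600, 3000),
                             frac_large_gaps = 0.15,
                             detection_fail_frac = 0.002,
                             n_bad_samples = 0, n_bad_probes = 0,
                             bad_fail_rate = 0.5,
                             epsilon = 1e-6, seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_type2 = frac_type2, frac_escape = frac_escape,
          frac_xci_mid = frac_xci_mid, frac_heritable = frac_heritable,
          frac_large_gaps = frac_large_gaps,
          detection_fail_frac = detection_fail_frac,
          bad_fail_rate = bad_fail_rate)
  if (any(fr < 0 | fr > 1))
    stopf("fractions must lie in [0, 1]; offending: %s",
          paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (n_cpgs < 1) stopf("n_cpgs must be >= 1")
  if (block_rho < 0 || block_rho >= 1) stopf("block_rho must be in [0, 1)")
  if (parent_child_rho < 0 || parent_child_rho > 0.5)
    stopf("parent_child_rho must be in [0, 0.5]")
  if (type2_compression <= 0 || type2_compression > 1)
    stopf("type2_compression must be in (0, 1]")
  for (pe in planted_effects) {
    if (is.null(pe$probes) || is.null(pe$delta) || is.null(pe$sex))
      stopf("each planted effect needs probes, delta and sex")
    if (any(pe$probes < 1 | pe$probes > n_cpgs))
      stopf("planted effect references probe index out of range 1..%d",
            n_cpgs)
    if (!is.finite(pe$delta)) stopf("planted delta must be finite")
    if (!pe$sex %in% c("M", "F", "both"))
      stopf("planted effect sex must be 'M', 'F' or 'both'")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic trio methylation dataset
#'
#' Draws a complete mother-father-child trio dataset with the
#' statistical structure the downstream analysis assumes (see
#' [synthetic_config()]), plus a truth table of planted effects for
#' recovery scoring.  All randomness is governed by `config$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param config A [synthetic_config()].
#' @return A `trio_dataset` list: `meth` ([meth_matrix()] over children,
#'   mothers and fathers), `sheet` (sample sheet), `manifest` (probe
#'   manifest), `truth` (data.frame `probe_id`, `delta`, `sex`), and the
#'   `config`.
#' @export
generate_trio_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, .generate_trios(config))
}

.generate_trios <- function(cfg) {
  J <- cfg$n_cpgs
  n_trios <- cfg$n_trios_art + cfg$n_trios_nonart
  art <- rep(c(1L, 0L), c(cfg$n_trios_art, cfg$n_trios_nonart))
  trio_id <- sprintf("T%04d", seq_len(n_trios))
  child_sex <- sample(c("M", "F"), n_trios, replace = TRUE)

  ## ---- manifest -------------------------------------------------------
  probe_id <- sprintf("cg%06d", seq_len(J))
  gaps <- round(runif(J, cfg$gap_range[1], cfg$gap_range[2]))
  big <- runif(J) < cfg$frac_large_gaps
  gaps[big] <- round(runif(sum(big), cfg$large_gap_range[1],
                           cfg$large_gap_range[2]))
  ## planted multi-probe spans are genuine regions: keep their internal
  ## gaps small regardless of the background gap model
  for (pe in cfg$planted_effects) {
    pr <- sort(pe$probes)
    if (length(pr) > 1) {
      inner <- pr[-1]  # gap i is distance position[i] - position[i-1]
      gaps[inner] <- pmin(gaps[inner], 200)  # RNG-free: planting never
    }                                        # shifts the random stream
  }
  position <- 1000L + cumsum(as.integer(gaps))
  design_type <- ifelse(runif(J) < cfg$frac_type2, "II", "I")
  manifest <- as_probe_manifest(data.frame(
    probe_id = probe_id, chromosome = "X", position = position,
    design_type = design_type, stringsAsFactors = FALSE
  ), sort_by_position = FALSE)

  ## ---- probe archetypes and per-sex baselines (M scale) ---------------
  archetype <- ifelse(runif(J) < cfg$frac_escape, "escape",
                      ifelse(runif(J) < cfg$frac_xci_mid, "xci_mid",
                             "concordant"))
  male_high <- runif(J) < 0.5
  m_low <- rnorm(J, -4, 0.4)   # beta ~ 0.06
  m_high <- rnorm(J, 4, 0.4)   # beta ~ 0.94
  mu_male <- ifelse(archetype == "escape", m_low,
                    ifelse(male_high, m_high, m_low))
  ## female: average allelic *betas*, then back to M scale
  beta_low <- inv_logit2(m_low)
  beta_high <- inv_logit2(m_high)
  mu_female <- ifelse(
    archetype == "escape", m_low,
    ifelse(archetype == "xci_mid",
           logit2((beta_low + beta_high) / 2),
           mu_male))

  ## ---- samples --------------------------------------------------------
  roles <- c("C", "M", "F")
  sample_id <- as.vector(t(outer(trio_id, roles, paste, sep = "_")))
  role <- rep(c("child", "mother", "father"), times = n_trios)
  s_trio <- rep(seq_len(n_trios), each = 3)
  n_samp <- length(sample_id)
  plate <- sample(sprintf("P%02d", seq_len(cfg$n_plates)), n_samp,
                  replace = TRUE)
  plate_eff <- rnorm(cfg$n_plates, 0, cfg$plate_sd)
  names(plate_eff) <- sprintf("P%02d", seq_len(cfg$n_plates))

  ## sample-level sex of the measured tissue/person
  samp_sex <- ifelse(role == "mother", "F",
                     ifelse(role == "father", "M", child_sex[s_trio]))

  ## ---- correlated deviations (M scale, unit variance) -----------------
  n_blocks <- ceiling(J / cfg$block_size)
  block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(J)]
  heritable <- runif(J) < cfg$frac_heritable
  rho_b <- cfg$block_rho
  rho_pc <- cfg$parent_child_rho

  ## per-trio shared factors for the parent-child correlation:
  ## child = sqrt(pc)*(t_m + t_f) + sqrt(1-2pc)*e ; parent = sqrt(pc)*t +
  ## sqrt(1-pc)*e  ->  cor(child, each parent) = pc, cor(mother, father) = 0
  t_m <- matrix(rnorm(J * n_trios), J, n_trios)
  t_f <- matrix(rnorm(J * n_trios), J, n_trios)
  e <- matrix(rnorm(J * n_samp), J, n_samp)
  g <- matrix(rnorm(n_blocks * n_samp), n_blocks, n_samp)
  base <- e
  if (any(heritable) && rho_pc > 0) {
    H <- which(heritable)
    for (rl in c("child", "mother", "father")) {
      cls <- which(role == rl)
      tr <- s_trio[cls]
      shared <- switch(rl,
        child  = sqrt(rho_pc) * (t_m[H, tr, drop = FALSE] +
                                   t_f[H, tr, drop = FALSE]),
        mother = sqrt(rho_pc) * t_m[H, tr, drop = FALSE],
        father = sqrt(rho_pc) * t_f[H, tr, drop = FALSE])
      own <- if (rl == "child") sqrt(1 - 2 * rho_pc) else sqrt(1 - rho_pc)
      base[H, cls] <- shared + own * e[H, cls, drop = FALSE]
    }
  }
  dev <- sqrt(rho_b) * g[block_of, , drop = FALSE] +
    sqrt(1 - rho_b) * base

  ## ---- covariates (anchored to a typical ART cohort table) ------------
  mat_age <- round(rnorm(n_trios, ifelse(art == 1, 33, 30.5), 4), 1)
  mat_age <- pmin(pmax(mat_age, 18), 45)
  mat_bmi <- round(rnorm(n_trios, 23.5, 3.2), 1)
  mat_bmi <- pmin(pmax(mat_bmi, 16), 45)
  primi <- rbinom(n_trios, 1, ifelse(art == 1, 0.70, 0.47))
  smoke_p_non <- c(0.50, 0.26, 0.13, 0.11)
  smoke_p_art <- c(0.52, 0.37, 0.065, 0.045)
  smoking <- vapply(seq_len(n_trios), function(i) {
    p <- if (art[i] == 1) smoke_p_art else smoke_p_non
    sample(smoking_levels, 1, prob = p)
  }, "")
  bw <- round(rnorm(n_trios, ifelse(art == 1, 3540, 3650), 480))
  ga <- round(rnorm(n_trios, 39.8, 1.4), 1)
  ga <- pmin(pmax(ga, 30), 43)

  ## ---- assemble M-value matrix ---------------------------------------
  mu <- cbind(M = mu_male, F = mu_female)
  m_mat <- mu[, samp_sex] + cfg$noise_sd * dev
  m_mat <- sweep(m_mat, 2, plate_eff[plate], "+")

  ## covariate links (children only, centered covariates)
  if (length(cfg$covariate_effects) > 0) {
    child_cols <- which(role == "child")
    covs <- list(maternal_age = mat_age, maternal_bmi = mat_bmi,
                 primiparity = primi, birthweight = bw,
                 gestational_age = ga,
                 maternal_smoking = as.numeric(smoking != "Never"))
    for (nm in names(cfg$covariate_effects)) {
      if (!nm %in% names(covs))
        stopf("unknown covariate in covariate_effects: '%s'", nm)
      v <- covs[[nm]][s_trio[child_cols]]
      shift <- cfg$covariate_effects[[nm]] * (v - mean(v))
      m_mat[, child_cols] <- sweep(m_mat[, child_cols, drop = FALSE], 2,
                                   shift, "+")
    }
  }

  ## planted ART effects (children with art == 1, matching sex)
  truth <- list()
  for (pe in cfg$planted_effects) {
    if (pe$delta == 0) next
    sexes <- if (pe$sex == "both") c("M", "F") else pe$sex
    target <- which(role == "child" & art[s_trio] == 1L &
                      child_sex[s_trio] %in% sexes)
    m_mat[pe$probes, target] <- m_mat[pe$probes, target] + pe$delta
    truth[[length(truth) + 1L]] <- data.frame(
      probe_id = probe_id[sort(pe$probes)], delta = pe$delta,
      sex = pe$sex, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(probe_id = character(), delta = numeric(),
               sex = character(), stringsAsFactors = FALSE)

  ## ---- betas, probe-type compression, detection p-values --------------
  beta <- inv_logit2(m_mat)
  t2 <- manifest$design_type == "II"
  beta[t2, ] <- 0.5 + (beta[t2, , drop = FALSE] - 0.5) *
    cfg$type2_compression
  beta <- pmin(pmax(beta, cfg$epsilon), 1 - cfg$epsilon)
  dimnames(beta) <- list(probe_id, sample_id)

  fail_p <- matrix(cfg$detection_fail_frac, J, n_samp)
  if (cfg$n_bad_samples > 0) {
    bad_s <- sample(n_samp, min(cfg$n_bad_samples, n_samp))
    fail_p[, bad_s] <- cfg$bad_fail_rate
  }
  if (cfg$n_bad_probes > 0) {
    bad_p <- sample(J, min(cfg$n_bad_probes, J))
    fail_p[bad_p, ] <- pmax(fail_p[bad_p, ], cfg$bad_fail_rate)
  }
  fails <- matrix(runif(J * n_samp) < fail_p, J, n_samp)
  detp <- matrix(runif(J * n_samp, 0, 0.001), J, n_samp)
  detp[fails] <- runif(sum(fails), 0.01, 1)
  dimnames(detp) <- dimnames(beta)

  ## ---- sample sheet ---------------------------------------------------
  sheet <- data.frame(
    sample_id = sample_id,
    trio_id = trio_id[s_trio],
    role = role,
    child_sex = ifelse(role == "child", child_sex[s_trio], NA_character_),
    art = art[s_trio],
    plate_id = plate,
    maternal_age = mat_age[s_trio],
    maternal_smoking = smoking[s_trio],
    maternal_bmi = mat_bmi[s_trio],
    primiparity = primi[s_trio],
    birthweight = ifelse(role == "child", bw[s_trio], NA_real_),
    gestational_age = ifelse(role == "child", ga[s_trio], NA_real_),
    stringsAsFactors = FALSE
  )

  structure(list(meth = meth_matrix(beta, detp),
                 sheet = as_sample_sheet(sheet),
                 manifest = manifest,
                 truth = truth,
                 config = cfg),
            class = "trio_dataset")
}

#' @export
print.trio_dataset <- function(x, ...) {
  cat(sprintf(
    "trio_dataset: %d probes x %d samples (%d trios; %d ART, %d non-ART), %d planted effect(s)\n",
    nrow(x$meth$beta), ncol(x$meth$beta),
    x$config$n_trios_art + x$config$n_trios_nonart,
    x$config$n_trios_art, x$config$n_trios_nonart, nrow(x$truth)))
  invisible(x)
}

#' Extract the planted-effect truth table of a synthetic dataset
#'
#' @param dataset A `trio_dataset` from [generate_trio_dataset()].
#' @return Data.frame with one row per affected probe: `probe_id`,
#'   `delta` (planted M-scale shift in ART children) and `sex` (stratum
#'   carrying the effect).  Zero-delta entries are excluded.
#' @export
truth_table <- function(dataset) {
  stopifnot(inherits(dataset, "trio_dataset"))
  dataset$truth
}

#' Count the modes of a beta-value distribution
#'
#' Kernel-density mode count at a fixed bandwidth, used to check the
#' sex-specific distributional shape of synthetic (or real) beta values:
#' males should show two modes (near 0 and 1), females at least three
#' (the XCI intermediate bump).
#'
#' @param x Numeric vector of beta values.
#' @param bw Kernel bandwidth (default 0.05).
#' @param min_height Modes below `min_height` times the tallest mode are
#'   ignored (default 0.01).
#' @return Integer number of modes.
#' @export
count_beta_modes <- function(x, bw = 0.05, min_height = 0.01) {
  x <- x[!is.na(x)]
  d <- density(x, bw = bw, n = 512, from = -0.1, to = 1.1)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] > min_height * max(y))
}
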