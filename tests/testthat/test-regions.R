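mk_results <- function(manifest, p_adj, effect = NULL, se = NULL) {
  data.frame(probe_id = manifest$probe_id,
             effect = effect %||% rep(0.3, nrow(manifest)),
             se = se %||% rep(0.1, nrow(manifest)),
             p_adj = p_adj, stringsAsFactors = FALSE)
}

test_that("candidate construction follows gap, sign and entry rules", {
  mf <- tiny_manifest(3, positions = c(100, 400, 2000))
  res <- mk_results(mf, p_adj = c(0.01, 0.01, 0.01))
  cands <- find_candidates(res, mf, maxgap_bp = 500, p_enter = 0.05)
  expect_length(cands, 2L)                       # 1600 bp gap splits
  expect_identical(cands[[1]]$probe_id, c("cg01", "cg02"))
  expect_identical(cands[[2]]$probe_id, "cg03")

  ## sign flip between adjacent passing probes splits the run
  mf2 <- tiny_manifest(3, positions = c(100, 300, 500))
  res2 <- mk_results(mf2, p_adj = rep(0.01, 3), effect = c(0.3, -0.3, -0.2))
  cands2 <- find_candidates(res2, mf2)
  expect_length(cands2, 2L)
  expect_identical(cands2[[2]]$probe_id, c("cg02", "cg03"))

  ## a non-passing probe in between breaks the run
  res3 <- mk_results(mf2, p_adj = c(0.01, 0.5, 0.01))
  expect_length(find_candidates(res3, mf2), 2L)

  ## nothing passes
  res4 <- mk_results(mf2, p_adj = rep(0.9, 3))
  expect_length(find_candidates(res4, mf2), 0L)
})

test_that("the region statistic matches its closed forms", {
  ## single CpG reduces to the input
  s1 <- dmr_stat(0.3, 0.1, matrix(1, 1, 1))
  expect_equal(s1$B, 0.3); expect_equal(s1$se_B, 0.1)
  expect_equal(s1$z, 3)

  ## independent members: fixed-effect meta-analysis
  s2 <- dmr_stat(c(0.2, 0.4), c(0.1, 0.1), diag(2))
  expect_equal(s2$B, 0.3)
  expect_equal(s2$se_B, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(s2$z, 0.3 / (0.1 / sqrt(2)), tolerance = 1e-12)

  ## perfect correlation: no precision gain
  R1 <- matrix(1, 2, 2)
  s3 <- dmr_stat(c(0.3, 0.3), c(0.1, 0.1), R1)
  expect_equal(s3$B, 0.3); expect_equal(s3$se_B, 0.1)
  expect_equal(s3$z, 3)

  expect_error(dmr_stat(c(0.1, 0.2), c(0.1, -0.1), diag(2)), "positive")
  expect_error(dmr_stat(c(0.1, 0.2), c(0.1, 0.1),
                        matrix(c(1, 0.5, 0.4, 1), 2)), "symmetric")
})

test_that("region statistic equals the meta-analysis oracle for R = I", {
  with_seed_t(13, {
    for (i in 1:1000) {
      k <- sample(2:6, 1)
      b <- rnorm(k); se <- runif(k, 0.05, 0.5)
      got <- dmr_stat(b, se, diag(k))
      w <- 1 / se^2
      expect_equal(got$B, sum(w * b) / sum(w), tolerance = 1e-10)
      expect_equal(got$se_B, sqrt(1 / sum(w)), tolerance = 1e-10)
    }
  })
})

test_that("region statistic is permutation invariant and saturates at rho -> 1", {
  with_seed_t(14, {
    k <- 5
    b <- rnorm(k); se <- runif(k, 0.05, 0.3)
    A <- matrix(rnorm(k * k), k); S <- cov2cor(crossprod(A) + diag(k))
    ref <- dmr_stat(b, se, S)
    pm <- sample(k)
    got <- dmr_stat(b[pm], se[pm], S[pm, pm])
    expect_equal(got$B, ref$B, tolerance = 1e-12)
    expect_equal(got$se_B, ref$se_B, tolerance = 1e-12)
  })
  ## equicorrelated members, equal effects: se_B -> se as rho -> 1
  for (rho in c(0.9, 0.99, 0.999)) {
    R <- matrix(rho, 4, 4); diag(R) <- 1
    s <- dmr_stat(rep(0.2, 4), rep(0.1, 4), R)
    expect_equal(s$se_B, 0.1, tolerance = (1 - rho))
  }
})

test_that("regions are called, combined and thresholded correctly", {
  cfg <- synthetic_config(n_trios_art = 60, n_trios_nonart = 60,
                          n_cpgs = 200, seed = 60, type2_compression = 1,
                          planted_effects = list(
                            list(probes = 101:104, delta = 0.9,
                                 sex = "both")))
  ds <- generate_trio_dataset(cfg)
  girls <- ds$sheet$sample_id[ds$sheet$role == "child" &
                                ds$sheet$child_sex == "F"]
  m <- beta_to_m(ds$meth$beta)
  res <- run_xwas(m, ds$sheet, "M1", "F")
  res <- adjust_inflation(res, seed = 3, min_n = 100,
                          n_iter = 2000, burn_in = 400)
  dmrs <- call_dmrs(res, m[, girls], ds$manifest)
  sig <- dmrs[dmrs$significant, ]
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$member_probe_ids,
                   paste(sprintf("cg%06d", 101:104), collapse = ","))
  ## span bounds are the member positions
  pos <- ds$manifest$position[match(sprintf("cg%06d", 101:104),
                                    ds$manifest$probe_id)]
  expect_identical(sig$start, min(pos))
  expect_identical(sig$end, max(pos))
  ## the two-member rule: a short candidate is never significant
  expect_true(all(dmrs$n_cpgs[dmrs$significant] >= 3))
})

test_that("co-methylation windows are closed and BY-adjusted", {
  mf <- tiny_manifest(5, positions = c(1000, 20000, 26000, 51000, 80000))
  with_seed_t(15, {
    base <- rnorm(40)
    m <- rbind(cg01 = base + rnorm(40, 0, 0.2),
               cg02 = base + rnorm(40, 0, 0.2),   # correlated with cg01
               cg03 = -(base + rnorm(40, 0, 0.2)),# anti-correlated
               cg04 = rnorm(40),
               cg05 = rnorm(40))
  })
  colnames(m) <- sprintf("S%02d", 1:40)
  ## center cg02 at 20 kb: window +/- 25 kb covers 1000..45000
  rep1 <- comethylation(m, mf, "cg02", window_bp = 50000)
  expect_identical(rep1$member_probe_ids, c("cg01", "cg02", "cg03"))
  ## boundary probe exactly at the window edge is included
  mfb <- tiny_manifest(3, positions = c(1000, 20000, 45000))
  repb <- comethylation(m[1:3, ], mfb, "cg02", window_bp = 50000)
  expect_identical(repb$member_probe_ids, c("cg01", "cg02", "cg03"))

  ## correlation signs and significance
  expect_gt(rep1$r["cg01", "cg02"], 0.8)
  expect_lt(rep1$r["cg02", "cg03"], -0.8)
  expect_true(rep1$significant["cg01", "cg02"])
  ## symmetry of both matrices; unit diagonal
  expect_equal(rep1$r, t(rep1$r))
  expect_equal(rep1$p_adj, t(rep1$p_adj))
  expect_equal(unname(diag(rep1$r)), rep(1, 3))

  ## a duplicated probe vector gives r = 1 and minimal adjusted p
  m2 <- rbind(m[1:2, ], dup = m["cg01", ])
  rownames(m2) <- c("cg01", "cg02", "cg03")
  rep2 <- comethylation(m2, mfb, "cg02")
  expect_equal(rep2$r["cg01", "cg03"], 1)
  expect_true(rep2$significant["cg01", "cg03"])

  ## exact antisymmetry: x and -x give r = -1
  m3 <- rbind(cg01 = m[1, ], cg02 = -m[1, ], cg03 = m[4, ])
  rep3 <- comethylation(m3, mfb, "cg02")
  expect_equal(rep3$r["cg01", "cg02"], -1)

  expect_error(comethylation(m, mf, "cg99"), "absent")
})

test_that("the BY adjustment in the report scales the BH values", {
  mf <- tiny_manifest(3, positions = c(100, 200, 300))
  with_seed_t(16, m <- matrix(rnorm(120), 3, 40,
                              dimnames = list(mf$probe_id, NULL)))
  colnames(m) <- sprintf("S%02d", 1:40)
  rep <- comethylation(m, mf, "cg02")
  up <- upper.tri(rep$p_adj)
  ## recompute from the raw correlations
  r <- rep$r[up]; n <- 40
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-t, n - 2)
  expect_equal(rep$p_adj[up], p.adjust(p, "BY"), tolerance = 1e-10)
})
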