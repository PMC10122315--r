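test_that("logit2 transform is exact and symmetric", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)          # log2(4)
  expect_equal(beta_to_m(0.2), -2)
  with_seed_t(1, {
    b <- runif(1000, 1e-5, 1 - 1e-5)
    expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  })
  ## boundary values are nudged, never infinite
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("flagged probes are excluded in order", {
  mf <- tiny_manifest(5, cross = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  x <- meth_matrix(tiny_beta(5, 3))
  out <- exclude_flagged_probes(x, mf)
  expect_identical(rownames(out$beta), c("cg02", "cg03", "cg05"))

  ## no flags -> identity
  mf0 <- tiny_manifest(5)
  expect_identical(exclude_flagged_probes(x, mf0)$beta, x$beta)

  ## all flagged -> empty with warning
  mfa <- tiny_manifest(5, cross = rep(TRUE, 5))
  expect_warning(out <- exclude_flagged_probes(x, mfa), "all probes")
  expect_identical(nrow(out$beta), 0L)

  ## probe missing from manifest
  expect_error(exclude_flagged_probes(x, mf[-1, ]), "absent from manifest")
})

test_that("detection masking hides cells and drops dead probes", {
  b <- tiny_beta(3, 3)
  d <- b; d[] <- 0.0001
  d[1, 2] <- 0.5          # one failing cell
  d[3, ] <- 0.9           # probe failing everywhere
  x <- meth_matrix(b, d)
  out <- mask_by_detection(x)
  expect_identical(rownames(out$beta), c("cg01", "cg02"))
  expect_true(is.na(out$beta[1, 2]))
  expect_identical(sum(is.na(out$beta)), 1L)

  ## threshold 1 keeps everything
  expect_identical(mask_by_detection(x, threshold = 1)$beta, x$beta)

  expect_error(mask_by_detection(meth_matrix(b)), "skip the masking")
})

test_that("greedy filtering follows the worst-first hand trace", {
  ## S3 fails all probes; P1 additionally fails in S1.
  b <- tiny_beta(3, 3)
  rownames(b) <- c("P1", "P2", "P3"); colnames(b) <- c("S1", "S2", "S3")
  b[, "S3"] <- NA
  b["P1", "S1"] <- NA
  x <- structure(list(beta = b, detection_p = NULL), class = "meth_matrix")
  out <- greedy_filter(x, max_unreliable_frac = 0.05)
  expect_identical(out$removed_samples, "S3")   # fraction 1.0 first
  expect_identical(out$removed_probes, "P1")    # then 1/2
  expect_identical(rownames(out$matrix$beta), c("P2", "P3"))
  expect_identical(colnames(out$matrix$beta), c("S1", "S2"))

  ## no failures, and the trivial threshold, leave the data untouched
  clean <- meth_matrix(tiny_beta(4, 4))
  expect_identical(greedy_filter(clean)$matrix$beta, clean$beta)
  expect_identical(greedy_filter(x, 1)$matrix$beta, x$beta)
})

test_that("greedy filtering is permutation invariant", {
  with_seed_t(11, {
    b <- tiny_beta(8, 8)
    b[runif(64) < 0.2] <- NA
  })
  x <- structure(list(beta = b, detection_p = NULL), class = "meth_matrix")
  ref <- greedy_filter(x, 0.1)
  perm <- structure(list(beta = b[sample(8), sample(8)],
                         detection_p = NULL), class = "meth_matrix")
  got <- greedy_filter(perm, 0.1)
  expect_setequal(rownames(got$matrix$beta), rownames(ref$matrix$beta))
  expect_setequal(colnames(got$matrix$beta), colnames(ref$matrix$beta))
})

test_that("gap detection splits on sorted gaps and applies the outlier rule", {
  r <- detect_gaps(c(0.10, 0.11, 0.12, 0.13, 0.75, 0.76))
  expect_identical(r$n_groups, 2L)
  expect_identical(as.integer(table(r$group_assignment)), c(4L, 2L))
  expect_true(r$flagged)

  ## constant vector: one group, not flagged
  r0 <- detect_gaps(rep(0.4, 10))
  expect_identical(r0$n_groups, 1L)
  expect_false(r0$flagged)

  ## one isolated outlier whose group is below the outlier fraction
  v <- c(rep(0.2, 99) + seq(0, 0.002, length.out = 99), 0.9)
  r1 <- detect_gaps(v, outlier_frac = 0.01)
  expect_identical(r1$n_groups, 2L)
  expect_false(r1$flagged)    # outlier group has exactly 1 = 1% of 100

  ## values are assigned to groups in input order
  r2 <- detect_gaps(c(0.9, 0.1, 0.88))
  expect_identical(r2$group_assignment, c(2L, 1L, 2L))
})

test_that("beta-mixture normalization aligns type II onto type I", {
  cfg <- synthetic_config(n_trios_art = 10, n_trios_nonart = 10,
                          n_cpgs = 1500, seed = 11, frac_type2 = 0.5,
                          type2_compression = 0.5)
  ds <- generate_trio_dataset(cfg)
  kids <- ds$sheet$sample_id[ds$sheet$role == "child"][1:6]
  x <- subset_meth(ds$meth, samples = kids)
  t2 <- ds$manifest$design_type == "II"
  xn <- bmiq_normalize(x, ds$manifest)

  ## type I probes are the untouched reference
  expect_identical(xn$beta[!t2, ], x$beta[!t2, ])

  ## output in [0,1]; within-type ranking preserved per sample
  expect_true(all(xn$beta >= 0 & xn$beta <= 1))
  for (s in seq_along(kids)) {
    o <- order(x$beta[t2, s])
    expect_false(is.unsorted(xn$beta[t2, s][o]))
  }

  ## the probe-type compression is corrected: KS distance between the
  ## type I and type II distributions strictly decreases in every sample
  ks <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  for (s in seq_along(kids)) {
    expect_lt(ks(xn$beta[!t2, s], xn$beta[t2, s]),
              ks(x$beta[!t2, s], x$beta[t2, s]))
  }
})

test_that("normalization is distributionally idempotent", {
  ## a second application must not re-distort the data: the type II
  ## distribution stays where the first pass put it (per-value changes
  ## are bounded by EM refit noise, concentrated at state boundaries)
  cfg <- synthetic_config(n_trios_art = 8, n_trios_nonart = 8,
                          n_cpgs = 1500, seed = 12, frac_type2 = 0.5,
                          type2_compression = 0.6)
  ds <- generate_trio_dataset(cfg)
  kids <- ds$sheet$sample_id[ds$sheet$role == "child"][1:4]
  x <- subset_meth(ds$meth, samples = kids)
  t2 <- ds$manifest$design_type == "II"
  x1 <- bmiq_normalize(x, ds$manifest)
  x2 <- bmiq_normalize(x1, ds$manifest)
  d <- abs(x2$beta[t2, ] - x1$beta[t2, ])
  expect_lt(median(d), 0.01)
  ks <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  for (s in seq_along(kids))
    expect_lt(abs(ks(x2$beta[!t2, s], x2$beta[t2, s]) -
                    ks(x1$beta[!t2, s], x1$beta[t2, s])), 0.02)
})

test_that("the pipeline composes the stages in the documented order", {
  cfg <- synthetic_config(n_trios_art = 15, n_trios_nonart = 15,
                          n_cpgs = 600, seed = 4, frac_type2 = 0.5,
                          n_bad_probes = 3, bad_fail_rate = 0.9)
  ds <- generate_trio_dataset(cfg)
  girls <- ds$sheet$sample_id[ds$sheet$role == "child" &
                                ds$sheet$child_sex == "F"]
  pp <- suppressWarnings(
    preprocess_pipeline(subset_meth(ds$meth, samples = girls),
                        ds$manifest))
  expect_match(pp$log[1], "exclude_flagged")
  expect_match(pp$log[2], "mask_by_detection")
  expect_match(pp$log[3], "greedy_filter")
  expect_match(pp$log[4], "detect_gaps")
  expect_match(pp$log[5], "bmiq_normalize")
  ## the three deliberately unreliable probes are gone
  expect_lte(nrow(pp$m), 600 - 3)
  expect_identical(rownames(pp$beta$beta), rownames(pp$m))
  expect_true(all(is.finite(pp$m[!is.na(pp$m)])))
})
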