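test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(2, 4, 6), c(1, 3, 5)), 0.5)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(10); b <- rnorm(10, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("bootstrap effect sizes are calibrated and deterministic", {
  set.seed(42)
  # identical group distributions: CI contains 0
  v <- rnorm(50)
  r0 <- bootstrap_effect(v, v, n_iter = 1000, seed = 1)
  expect_lt(r0$ci_low, 0)
  expect_gt(r0$ci_high, 0)
  # planted shift of 1 pooled SD at n = 200/200
  a <- rnorm(200, 1, 1); b <- rnorm(200, 0, 1)
  r1 <- bootstrap_effect(a, b, n_iter = 2000, seed = 2)
  expect_gt(r1$d, 0.8)
  expect_lt(r1$d, 1.2)
  expect_lt(r1$p, 0.05)
  # determinism under a fixed seed
  r2 <- bootstrap_effect(a, b, n_iter = 500, seed = 7)
  r3 <- bootstrap_effect(a, b, n_iter = 500, seed = 7)
  expect_identical(r2$d, r3$d)
  expect_identical(r2$ci_low, r3$ci_low)
})

test_that("bootstrap CI of d covers a planted effect at nominal-ish rate", {
  # 60 synthetic cohorts with true d = 0.6 (the heavier 200-cohort sweep
  # runs in the acceptance suite)
  set.seed(99)
  cover <- vapply(1:60, function(k) {
    a <- rnorm(50, 0.6); b <- rnorm(50, 0)
    r <- bootstrap_effect(a, b, n_iter = 400)
    r$ci_low <= 0.6 && 0.6 <= r$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("epoch sampling is uniform, non-overlapping and boundary-correct", {
  expect_error(sample_epochs(43 * 60, 22 * 60, k = 2), "do not fit")
  expect_error(sample_epochs(100, 200), "exceeds")
  expect_equal(sample_epochs(120, 120, k = 1, seed = 1), 0)
  set.seed(5)
  for (k in 1:200) {
    se <- sample_epochs(300, 60, k = 2)
    expect_true(all(se >= 0 & se + 60 <= 300))
    expect_true(se[2] + 60 <= se[1] || se[2] >= se[1] + 60)
  }
  # empirical start distribution ~ uniform
  set.seed(6)
  starts <- vapply(1:10000, function(i) sample_epochs(300, 60, k = 1),
                   numeric(1))
  ks <- suppressWarnings(ks.test(starts, "punif", 0, 241))
  expect_gt(ks$p.value, 0.01)
})

test_that("partial rank correlation reproduces the worked example", {
  x <- c(1, 2, 3, 4); z <- c(1, 3, 2, 4)
  y <- c(2, 1, 4, 3); w <- c(1, 2, 3, 4)
  expect_equal(partial_rank_correlation(x, y, z, w), 0.8)
  # constant covariates reduce to plain Spearman
  xs <- c(3, 1, 4, 1, 5); ys <- c(2, 7, 1, 8, 2)
  expect_equal(partial_rank_correlation(xs, ys, rep(1, 5), rep(1, 5)),
               cor(xs, ys, method = "spearman"))
  expect_error(partial_rank_correlation(x, y, x, w), "zero-variance")
})

test_that("partial correlation equals Spearman under rank-orthogonal covariates", {
  # covariate ranks orthogonal (in centred-rank inner product) to the
  # variable ranks: the regression slope is 0 and nothing is removed
  x <- c(1, 2, 3, 4)
  z <- c(3, 1, 4, 2)  # centred ranks orthogonal to x's
  y <- c(4, 3, 1, 2)
  w <- c(2, 4, 3, 1)  # centred ranks orthogonal to y's
  expect_equal(sum((rank(x) - 2.5) * (rank(z) - 2.5)), 0)
  expect_equal(sum((rank(y) - 2.5) * (rank(w) - 2.5)), 0)
  expect_equal(partial_rank_correlation(x, y, z, w),
               cor(x, y, method = "spearman"))
})

test_that("FDR adjustment is BH, monotone, and fixes equal p-values", {
  expect_equal(fdr_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))  # BH fixed point
  expect_identical(fdr_adjust(numeric()), numeric())
  set.seed(8)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
})

test_that("pooled t and Yates chi-square match hand calculations", {
  tt <- two_sample_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(tt$t, -2.449, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(two_sample_t(rnorm(105), rnorm(48))$df, 151)

  expect_equal(chi_square_independence(matrix(c(20, 10, 10, 20), 2))$statistic,
               5.4)
  expect_equal(chi_square_independence(matrix(c(10, 10, 10, 10), 2))$statistic,
               0)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("epoch-sampled effects agree with the plain bootstrap at full duration", {
  set.seed(31)
  tl <- fake_timeline(p_face = c(rnorm(12, 0.62, 0.06), rnorm(12, 0.78, 0.06)),
                      groups = rep(c("ASD", "TD"), each = 12), minutes = 3,
                      seed = 31)
  full <- epoch_features(tl)
  ref <- bootstrap_effect(full[tl$groups == "TD", "pct_face"],
                          full[tl$groups == "ASD", "pct_face"],
                          n_iter = 2000, seed = 1)
  es <- epoch_sampled_effect(tl, features = "pct_face", duration_s = 180,
                             n_iter = 2000, seed = 2)
  expect_equal(es$d, ref$d, tolerance = 0.1)
  expect_lt(es$p, 0.05)
  # without resampling at full duration it reduces to the sample d exactly
  es0 <- epoch_sampled_effect(tl, features = "pct_face", duration_s = 180,
                              n_iter = 3, seed = 3, resample = FALSE)
  expect_equal(es0$d, cohens_d(full[tl$groups == "TD", "pct_face"],
                               full[tl$groups == "ASD", "pct_face"]),
               tolerance = 1e-12)
  # determinism
  es_a <- epoch_sampled_effect(tl, duration_s = 60, n_iter = 50, seed = 9)
  es_b <- epoch_sampled_effect(tl, duration_s = 60, n_iter = 50, seed = 9)
  expect_identical(es_a$d, es_b$d)
})

test_that("shorter epochs weaken the evidence for a planted difference", {
  tl <- fake_timeline(p_face = c(rnorm(10, 0.68, 0.05), rnorm(10, 0.76, 0.05)),
                      groups = rep(c("ASD", "TD"), each = 10), minutes = 4,
                      seed = 17)
  es_long <- epoch_sampled_effect(tl, features = "pct_face",
                                  duration_s = 180, n_iter = 400, seed = 5)
  es_short <- epoch_sampled_effect(tl, features = "pct_face",
                                   duration_s = 5, n_iter = 400, seed = 5)
  expect_lte(es_long$p, es_short$p)
  # frame-sampling noise in short epochs attenuates the estimated d
  expect_lt(es_short$d, es_long$d)
})

test_that("reliability is high for stable traits and degrades with feature noise", {
  # stable per-participant face preference, tight frame-sampling noise
  pf <- seq(0.5, 0.9, length.out = 16)
  tl <- fake_timeline(p_face = pf, groups = rep(c("ASD", "TD"), 8),
                      minutes = 4, corr_noise_sd = 0.01, seed = 23)
  rel <- reliability_sampled(tl, features = c("pct_face",
                                              "mean_heatmap_corr"),
                             duration_s = 60, n_iter = 100, seed = 3)
  expect_true(all(rel$table$rho > 0.8))
  expect_true(all(rel$table$p < 0.05))
  # identical generative processes in both groups: no group difference
  expect_true(all(rel$group_diff$p > 0.05))
  # hand-checkable Spearman value
  expect_equal(cor(c(1, 2, 3), c(2, 1, 3), method = "spearman"), 0.5)
})

test_that("familiarity split excludes rating-5 and missing participants", {
  ft <- data.frame(participant_id = sprintf("p%d", 1:12),
                   group = rep(c("ASD", "TD"), 6), episode_id = "A",
                   pct_face = rnorm(12, 70, 5))
  meta <- participant_meta(data.frame(
    participant_id = ft$participant_id, group = ft$group,
    familiarity_A = c(7, 8, 2, 3, 5, NA, 6, 2, 9, 1, 3, 8)))
  res <- familiarity_split_tests(ft, meta, "A",
                                 feature_names = "pct_face")
  all_row <- res[res$scope == "all", ]
  expect_equal(all_row$n_familiar + all_row$n_unfamiliar, 10L)  # 5, NA out
  # all ratings below 5: familiar stratum empty, test skipped
  meta2 <- meta; meta2$familiarity_A <- rep(2, 12)
  res2 <- familiarity_split_tests(ft, meta2, "A", feature_names = "pct_face")
  expect_true(all(is.na(res2$t)))
  expect_true(all(res2$n_familiar == 0))
})

test_that("severity correlations behave for monotone and independent severity", {
  set.seed(12)
  n <- 14
  ft <- data.frame(participant_id = sprintf("a%02d", 1:n), group = "ASD",
                   episode_id = "A", pct_face = runif(n, 50, 90))
  # severity a monotone function of face gaze -> rho = 1
  meta <- participant_meta(data.frame(
    participant_id = ft$participant_id, group = "ASD",
    severity_css = rank(ft$pct_face)))
  res <- severity_correlation(ft, meta, feature_names = "pct_face")
  expect_equal(res$rho, 1)
  # missing severity dropped pairwise
  meta$severity_css[1:3] <- NA
  res2 <- severity_correlation(ft, meta, feature_names = "pct_face")
  expect_equal(res2$n, n - 3L)
  # independent severity: small correlation across repetitions
  rhos <- vapply(1:20, function(k) {
    m <- meta
    m$severity_css <- sample(3:10, n, replace = TRUE)
    severity_correlation(ft, m, feature_names = "pct_face")$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)
})
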