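test_that("Gaussian naive Bayes separates, ties to majority, and matches the hand case", {
  set.seed(1)
  # classes 10 SDs apart on one feature
  xtr <- rbind(matrix(rnorm(40), 20, 2),
               matrix(rnorm(40, 10), 20, 2))
  ytr <- rep(c("A", "B"), each = 20)
  xte <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 10), 10, 2))
  pred <- gnb_fit_predict(xtr, ytr, xte)
  expect_equal(pred, rep(c("A", "B"), each = 10))

  # hand case: A ~ N(0,1), B ~ N(4,1), equal priors, x = 1 -> A
  xa <- c(-1, 0, 1); xb <- c(3, 4, 5)   # mean 0 / 4, sample-ish variance 1
  pred1 <- gnb_fit_predict(matrix(c(xa, xb)), rep(c("A", "B"), each = 3),
                           matrix(1))
  expect_equal(pred1, "A")

  # exact posterior tie in a mirror-symmetric, equal-prior design: the
  # test point at the axis of symmetry goes to the majority (first) class
  xtr2 <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ytr2 <- rep(c("A", "B"), each = 3)
  xtr2 <- rbind(xtr2, matrix(c(-2, 2, -2.5), ncol = 1))
  ytr2 <- c(ytr2, "A", "B", "A")        # A is now the majority class
  expect_equal(gnb_fit_predict(xtr2[1:6, , drop = FALSE], ytr2[1:6],
                               matrix(0)), "A")
  expect_error(gnb_fit_predict(matrix(1:3), rep("A", 3), matrix(1)),
               "single class")
})

test_that("naive Bayes agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  xtr <- matrix(rnorm(120), 30, 4)
  ytr <- rep(c("ASD", "TD"), 15)
  xtr[ytr == "TD", 1] <- xtr[ytr == "TD", 1] + 1.2
  xte <- matrix(rnorm(40), 10, 4)
  colnames(xtr) <- colnames(xte) <- paste0("f", 1:4)
  ours <- gnb_fit_predict(xtr, ytr, xte)
  ref <- as.character(predict(e1071::naiveBayes(data.frame(xtr),
                                                factor(ytr)),
                              data.frame(xte)))
  expect_equal(ours, ref)
})

test_that("cross-validated classification separates what is separable", {
  # fully separated groups
  tl_sep <- fake_timeline(p_face = c(rnorm(9, 0.45, 0.02),
                                     rnorm(9, 0.85, 0.02)),
                          groups = rep(c("ASD", "TD"), each = 9),
                          minutes = 2, corr_noise_sd = 0.01, seed = 41)
  res <- crossvalidated_classification(tl_sep, duration_s = 30,
                                       n_iter = 120, seed = 2)
  expect_gt(res$mean_accuracy, 0.95)
  # per-participant frequencies only defined when held out
  pp <- res$per_participant
  expect_true(all(is.na(pp$freq_correct[pp$n_held == 0])))
  expect_true(all(pp$freq_correct[pp$n_held > 0] >= 0 &
                    pp$freq_correct[pp$n_held > 0] <= 1))
})

test_that("label permutation gives a calibrated chance level", {
  # identical group-generative processes
  tl0 <- fake_timeline(p_face = rnorm(20, 0.7, 0.05),
                       groups = rep(c("ASD", "TD"), each = 10),
                       minutes = 2, seed = 43)
  obs <- crossvalidated_classification(tl0, duration_s = 30, n_iter = 150,
                                       seed = 3)
  nul <- classification_null(tl0, duration_s = 30, n_iter = 150,
                             observed = obs, seed = 4)
  expect_lt(obs$mean_accuracy, nul$chance_95)
  expect_gt(nul$p, 0.05)
  # null mean is near the held-out majority fraction (here balanced: 0.5)
  expect_lt(abs(nul$null_mean - 0.5), 0.1)
})

test_that("the variational mixture empties superfluous components", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60 * 4, 0, 1), 60, 4),
             matrix(rnorm(40 * 4, 8, 1), 40, 4))
  for (k0 in c(5, 10)) {
    fit <- fit_mixture_clusters(scale(x), init_k = k0, seed = 5)
    expect_equal(fit$n_effective, 2L)
    # the two planted blocks are never split across clusters
    expect_equal(length(unique(fit$assignment[1:60])), 1L)
    expect_equal(length(unique(fit$assignment[61:100])), 1L)
  }
  # all-identical participants collapse to one cluster
  x1 <- matrix(1, 10, 4)
  fit1 <- fit_mixture_clusters(x1, init_k = 5, seed = 6)
  expect_equal(fit1$n_effective, 1L)
  expect_error(fit_mixture_clusters(x[1:3, ], init_k = 5), "init_k")
})

test_that("small clusters dissolve into the nearest large cluster", {
  set.seed(12)
  x <- rbind(matrix(rnorm(60 * 2, 0), 60, 2),
             matrix(rnorm(40 * 2, 6), 40, 2),
             matrix(rnorm(2 * 2, 7), 2, 2))
  assign0 <- c(rep(1L, 60), rep(2L, 40), rep(3L, 2))
  merged <- merge_small_clusters(assign0, x, min_size = 4)
  expect_equal(sort(unique(merged)), c(1L, 2L))
  expect_equal(length(merged), length(assign0))       # conservation
  expect_equal(merged[101:102], c(2L, 2L))            # joins the near cluster
  expect_identical(merge_small_clusters(assign0[1:100], x[1:100, ], 4),
                   assign0[1:100])                    # no small clusters
  # tie between two large means -> lowest-index cluster
  xt <- rbind(matrix(c(rep(-2, 10), rep(0, 10)), 10, 2),
              matrix(c(rep(2, 10), rep(0, 10)), 10, 2),
              c(0, 0))
  at <- c(rep(1L, 10), rep(2L, 10), 3L)
  expect_equal(merge_small_clusters(at, xt, 4)[21], 1L)
  expect_error(merge_small_clusters(rep(1:10, 1), matrix(0, 10, 2), 4),
               "min_size")
})

test_that("moving-window clustering recovers a planted stable split", {
  set.seed(13)
  # two well-separated trait modes with stable per-participant traits on
  # every feature axis (no axis is pure frame-sampling noise)
  pf <- c(rnorm(14, 0.82, 0.03), rnorm(10, 0.50, 0.03))
  planted <- rep(c(1, 2), c(14, 10))
  tl <- fake_timeline(p_face = pf,
                      p_eyes_within = rnorm(24, 0.62, 0.04),
                      p_on = rnorm(24, 0.93, 0.02),
                      corr_mean = 0.3 + 0.4 * pf + rnorm(24, 0, 0.015),
                      groups = rep(c("TD", "ASD"), 12),
                      minutes = 4, corr_noise_sd = 0.01, seed = 44)
  cr <- windowed_cluster_frequencies(tl, window_s = 60, step_s = 30,
                                     init_k = 5, seed = 7)
  expect_equal(unique(cr$n_clusters_per_window), 2L)
  # every participant sits in its planted cluster in every window
  assigned <- max.col(cr$frequencies)
  expect_true(all((cr$frequencies[cbind(seq_along(assigned),
                                        assigned)]) > 0.75))
  expect_equal(length(unique(assigned[planted == 1])), 1L)
  expect_equal(length(unique(assigned[planted == 2])), 1L)
  # a window as long as the timeline gives a single window with 0/1 freqs
  cr1 <- windowed_cluster_frequencies(tl, window_s = 240, step_s = 300,
                                      init_k = 5, seed = 8)
  expect_equal(cr1$n_windows, 1L)
  expect_true(all(cr1$frequencies %in% c(0, 1)))
})
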