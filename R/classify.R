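# Supervised diagnostic classification: Gaussian naive Bayes with
# epoch-sampled cross-validation and an empirical (label-permutation) null.

#' Gaussian naive Bayes fit-and-predict
#'
#' Per-class, per-feature Gaussian densities (mean and variance with a
#' small variance floor) and class priors from training frequencies;
#' prediction is the argmax of the log posterior, with exact posterior
#' ties going to the majority (first-listed on count ties) training class.
#'
#' @param train_x,test_x Numeric matrices (rows = observations).
#' @param train_y Class labels (>= 2 classes, >= 2 members each).
#' @return Character vector of predicted labels for `test_x`.
#' @export
gnb_fit_predict <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  classes <- unique(as.character(train_y))
  if (length(classes) < 2) stop_gp("training set has a single class")
  counts <- table(factor(train_y, levels = classes))
  if (any(counts < 2)) stop_gp("each class needs >= 2 training members")
  var_floor <- 1e-9 * max(apply(train_x, 2, stats::var), 1e-12)
  logpost <- sapply(classes, function(cl) {
    xg <- train_x[train_y == cl, , drop = FALSE]
    mu <- colMeans(xg)
    v <- pmax(apply(xg, 2, stats::var) * (nrow(xg) - 1) / nrow(xg), var_floor)
    ll <- -0.5 * sweep(sweep(test_x, 2, mu)^2, 2, v, "/") -
      0.5 * matrix(log(2 * pi * v), nrow(test_x), ncol(test_x), byrow = TRUE)
    rowSums(ll) + log(counts[[cl]] / length(train_y))
  })
  logpost <- matrix(logpost, ncol = length(classes),
                    dimnames = list(NULL, classes))
  majority <- classes[order(-as.numeric(counts))][1]
  apply(logpost, 1, function(lp) {
    best <- which(lp == max(lp))
    if (length(best) > 1) majority else classes[best]
  })
}

# One CV iteration: sample an epoch, hold out floor(n/3) per group, train
# on the rest, score the held-out participants. Returns held-out indices
# and correctness.
cv_iteration <- function(tl, duration_s, features, labels) {
  total_s <- timeline_duration(tl)
  s1 <- sample_epochs(total_s, duration_s, k = 1)
  m <- epoch_features(tl, s1, duration_s)[, features, drop = FALSE]
  ok <- stats::complete.cases(m)
  held <- unlist(lapply(unique(labels), function(g) {
    gi <- which(labels == g & ok)
    sample(gi, floor(sum(labels == g) / 3))
  }))
  train <- setdiff(which(ok), held)
  if (length(unique(labels[train])) < 2 || length(held) < 1) return(NULL)
  pred <- gnb_fit_predict(m[train, , drop = FALSE], labels[train],
                          m[held, , drop = FALSE])
  list(held = held, correct = pred == labels[held])
}

#' Epoch-sampled cross-validated diagnostic classification
#'
#' Per iteration: sample one epoch of `duration_s`, hold out one third of
#' each group, train a Gaussian naive Bayes classifier on the remaining
#' participants' four gaze features (on-screen, face and eyes percentages
#' and mean reference-heatmap correlation), and score held-out accuracy.
#' Reports mean and SD accuracy across iterations and each participant's
#' correct-classification frequency over the iterations in which they were
#' held out.
#'
#' @param tl A `cohort_timeline`.
#' @param duration_s Epoch duration (seconds).
#' @param n_iter CV iterations.
#' @param features Feature set (default the four headline features).
#' @param seed Optional seed.
#' @return A list of class `classifier_result`: `mean_accuracy`,
#'   `sd_accuracy`, `per_participant` (data.frame id, group, n_held,
#'   freq_correct), `n_iter`, `acc` (per-iteration accuracies).
#' @export
crossvalidated_classification <- function(tl, duration_s = 600, n_iter = 1000,
                                          features = FOUR_FEATURES,
                                          seed = NULL) {
  if (any(table(tl$groups) < 3)) stop_gp("each group needs >= 3 participants")
  with_seed_if(seed, {
    n <- length(tl$ids)
    n_held <- integer(n); n_corr <- integer(n)
    acc <- rep(NA_real_, n_iter)
    for (it in seq_len(n_iter)) {
      res <- cv_iteration(tl, duration_s, features, tl$groups)
      if (is.null(res)) next
      acc[it] <- mean(res$correct)
      n_held[res$held] <- n_held[res$held] + 1L
      n_corr[res$held] <- n_corr[res$held] + res$correct
    }
    acc <- acc[!is.na(acc)]
    structure(list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                   per_participant = data.frame(
                     participant_id = tl$ids, group = tl$groups,
                     n_held = n_held,
                     freq_correct = ifelse(n_held > 0, n_corr / n_held,
                                           NA_real_)),
                   n_iter = length(acc), acc = acc),
              class = "classifier_result")
  })
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> accuracy %.3f +/- %.3f over %d iterations%s\n",
              x$mean_accuracy, x$sd_accuracy, x$n_iter,
              if (!is.null(x$p)) sprintf(", p = %.4g (chance 95%% = %.3f)",
                                         x$p, x$chance_95) else ""))
  invisible(x)
}

#' Empirical null for the diagnostic classifier
#'
#' Repeats the identical cross-validation procedure with diagnosis labels
#' permuted across participants once per iteration before the train/test
#' split, destroying any label-feature association while preserving class
#' imbalance and the CV structure. The 95th percentile of the null
#' accuracies is the empirical chance level.
#'
#' @inheritParams crossvalidated_classification
#' @param observed Optional `classifier_result` whose mean accuracy is
#'   assessed against the null (fills `p`).
#' @return A list: `null` (accuracies), `chance_95`, `null_mean`, and `p`
#'   when `observed` is given.
#' @export
classification_null <- function(tl, duration_s = 600, n_iter = 1000,
                                features = FOUR_FEATURES, observed = NULL,
                                seed = NULL) {
  with_seed_if(seed, {
    null_acc <- rep(NA_real_, n_iter)
    for (it in seq_len(n_iter)) {
      perm_labels <- sample(tl$groups)
      res <- cv_iteration(tl, duration_s, features, perm_labels)
      if (!is.null(res)) null_acc[it] <- mean(res$correct)
    }
    null_acc <- null_acc[!is.na(null_acc)]
    out <- list(null = null_acc,
                chance_95 = stats::quantile(null_acc, 0.95, names = FALSE),
                null_mean = mean(null_acc))
    if (!is.null(observed))
      out$p <- (1 + sum(null_acc >= observed$mean_accuracy)) /
        (length(null_acc) + 1)
    out
  })
}
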