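# Gaze fingerprinting: identifying individuals across epochs from their
# gaze feature vectors by minimum L2 distance, with a permutation null.

#' Standardize a feature matrix across participants
#'
#' Centres and scales each feature column to zero mean and unit variance
#' across participants within its epoch (population SD, i.e. denominator
#' n), so that range and variance differences between features do not
#' dominate the L2 distance.
#'
#' @param m Participants x features numeric matrix.
#' @return The standardized matrix.
#' @export
standardize_features <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop_gp("need >= 2 participants to standardize")
  if (anyNA(m)) stop_gp("feature matrix contains missing entries")
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(m^2) - mu^2)
  const <- sd_pop < 1e-12
  if (any(const))
    stop_gp("constant feature column(s): %s",
            paste(colnames(m)[const] %||% which(const), collapse = ", "))
  sweep(sweep(m, 2, mu), 2, sd_pop, "/")
}

# Index of the nearest epoch-b row for each epoch-a row (ties: lowest index).
nearest_neighbours <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  apply(d2, 1, which.min)
}

#' Identify participants across two epochs by minimum L2 distance
#'
#' For each participant's epoch-a vector, the predicted identity is the
#' owner of the nearest epoch-b vector (the participant's own epoch-b
#' vector is among the candidates). With bootstrap-duplicated rows, an
#' identification counts as a success when the nearest neighbour is any
#' copy of the same original participant; the chance level then stays at
#' about 1 over the number of distinct participants.
#'
#' @param epoch_a,epoch_b Standardized feature matrices with identical
#'   shapes and row order (row i of both epochs is the same participant).
#' @param owners Vector of original participant identities per row
#'   (defaults to row indices; equal entries mark bootstrap copies).
#' @return A list of class `fingerprint_result`: `predicted` (owner of the
#'   nearest neighbour per row), `correct` (logical), `accuracy`,
#'   `n_identified`, `n_total`, `nn` (nearest row indices).
#' @export
identify_participants <- function(epoch_a, epoch_b,
                                  owners = seq_len(nrow(epoch_a))) {
  if (!identical(dim(epoch_a), dim(epoch_b)))
    stop_gp("epoch matrices differ in shape")
  nn <- nearest_neighbours(epoch_a, epoch_b)
  correct <- owners[nn] == owners
  structure(list(predicted = owners[nn], correct = correct,
                 accuracy = mean(correct), n_identified = sum(correct),
                 n_total = length(correct), nn = nn),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> %d/%d identified (%.1f%%)%s\n",
              x$n_identified, x$n_total, 100 * x$accuracy,
              if (!is.null(x$p)) sprintf(", p = %.4g, null 95%% = %.1f%%",
                                         x$p, 100 * x$null_95) else ""))
  invisible(x)
}

#' Permutation null for identification accuracy
#'
#' At each iteration the identities of the epoch-b vectors are shuffled by
#' a uniform random permutation and the fraction of successful
#' identifications is recomputed; with fixed nearest neighbours this is
#' the fraction of fixed points hit through the permutation, so the null
#' accuracy behaves like the fixed-point count of a random permutation
#' (approximately Poisson with mean 1: about 1/n on average, with 95th
#' percentile near 3/n).
#'
#' @param epoch_a,epoch_b Standardized feature matrices.
#' @param n_perm Permutation iterations (default 10,000; < 100 warns).
#' @param seed Optional seed.
#' @return A `fingerprint_result` augmented with `p` (add-one smoothed),
#'   `null_95`, `null_mean` and the `null` accuracy vector.
#' @export
permutation_null <- function(epoch_a, epoch_b, n_perm = 10000, seed = NULL) {
  if (n_perm < 100)
    gp_log("n_perm = %d gives an unstable null percentile", n_perm,
           level = "WARN")
  with_seed_if(seed, {
    res <- identify_participants(epoch_a, epoch_b)
    n <- res$n_total
    ids <- seq_len(n)
    null_acc <- vapply(seq_len(n_perm), function(k) {
      perm <- sample.int(n)
      mean(perm[res$nn] == ids)
    }, numeric(1))
    res$p <- (1 + sum(null_acc >= res$accuracy)) / (n_perm + 1)
    res$null_95 <- stats::quantile(null_acc, 0.95, names = FALSE)
    res$null_mean <- mean(null_acc)
    res$null <- null_acc
    res
  })
}

#' Epoch-sampled gaze fingerprinting
#'
#' Per iteration: draw two non-overlapping epochs, bootstrap-resample the
#' group's participants, build the feature matrices in both epochs
#' (participants with any missing feature are dropped for the iteration),
#' standardize within the epoch, and identify across epochs (success =
#' nearest neighbour is any copy of the same original participant). A
#' matched null accuracy is computed per iteration by shuffling the
#' epoch-b identities. Reports mean accuracy, the permutation p of the
#' mean against the null draws, and the null 95th percentile.
#'
#' @param tl A `cohort_timeline`.
#' @param duration_s Epoch duration (seconds); `2 * duration_s` must fit.
#' @param n_iter Iterations.
#' @param features Feature set: `FEATURE_NAMES` (8) or `FOUR_FEATURES` (4).
#' @param group `"ASD"` or `"TD"`; identification runs within the group.
#' @param resample Bootstrap-resample participants per iteration.
#' @param seed Optional seed.
#' @return A list of class `sampled_fingerprint_result`.
#' @export
sampled_fingerprint <- function(tl, duration_s = 600, n_iter = 500,
                                features = FEATURE_NAMES, group = "ASD",
                                resample = TRUE, seed = NULL) {
  total_s <- timeline_duration(tl)
  if (2 * duration_s > total_s)
    stop_gp("two epochs of %g s do not fit in %g s", duration_s, total_s)
  gi <- which(tl$groups == group)
  if (length(gi) < 3) stop_gp("need >= 3 participants in group %s", group)
  with_seed_if(seed, {
    acc <- rep(NA_real_, n_iter); null_acc <- rep(NA_real_, n_iter)
    dropped <- 0L
    for (it in seq_len(n_iter)) {
      se <- sample_epochs(total_s, duration_s, k = 2)
      idx <- if (resample) sample(gi, length(gi), replace = TRUE) else gi
      m1 <- epoch_features(tl, se[1], duration_s, idx = idx)[, features,
                                                            drop = FALSE]
      m2 <- epoch_features(tl, se[2], duration_s, idx = idx)[, features,
                                                             drop = FALSE]
      ok <- stats::complete.cases(m1) & stats::complete.cases(m2)
      dropped <- dropped + sum(!ok)
      if (sum(ok) < 3) next
      owners <- idx[ok]
      s1 <- tryCatch(standardize_features(m1[ok, , drop = FALSE]),
                     error = function(e) NULL)
      s2 <- tryCatch(standardize_features(m2[ok, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(s1) || is.null(s2)) next
      res <- identify_participants(s1, s2, owners = owners)
      acc[it] <- res$accuracy
      perm <- sample(owners)
      null_acc[it] <- mean(perm[res$nn] == owners)
    }
    if (dropped) gp_log("dropped %d participant-iteration(s) with missing features",
                        dropped)
    acc <- acc[!is.na(acc)]; null_acc <- null_acc[!is.na(null_acc)]
    structure(list(group = group, accuracy = mean(acc),
                   p = (1 + sum(null_acc >= mean(acc))) /
                     (length(null_acc) + 1),
                   null_95 = stats::quantile(null_acc, 0.95, names = FALSE),
                   null_mean = mean(null_acc),
                   epoch_minutes = duration_s / 60,
                   feature_set = if (length(features) == 4) "four" else "eight",
                   n_iter = length(acc), acc = acc, null = null_acc),
              class = "sampled_fingerprint_result")
  })
}

#' @export
print.sampled_fingerprint_result <- function(x, ...) {
  cat(sprintf(paste0("<sampled_fingerprint> %s (%s features, %.3g min): ",
                     "accuracy %.1f%%, p = %.4g, null 95%% = %.1f%%\n"),
              x$group, x$feature_set, x$epoch_minutes, 100 * x$accuracy,
              x$p, 100 * x$null_95))
  invisible(x)
}
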