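# Group effect sizes: Cohen's d with bootstrap resampling, and the
# epoch-sampling variant that combines a random contiguous video epoch with
# bootstrap resampling of participants at every iteration.

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled SD using the
#' `n_a + n_b - 2` denominator. In group analyses the convention is
#' `a` = TD, `b` = ASD, so positive d means the TD group is higher.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A single number.
#' @examples
#' cohens_d(c(2, 4, 6), c(1, 3, 5))  # 0.5
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_gp("cohens_d needs >= 2 values per group")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop_gp("pooled SD is zero; d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Two-sided sign-crossing bootstrap p with add-one smoothing:
# p = min(1, 2 * (1 + #{d* on the other side of 0}) / (n + 1)).
boot_sign_p <- function(boot_stats, observed) {
  n <- length(boot_stats)
  if (observed == 0) return(1)
  crossings <- sum(boot_stats * sign(observed) < 0)
  min(1, 2 * (1 + crossings) / (n + 1))
}

#' Bootstrap estimate of Cohen's d with confidence interval
#'
#' Resamples each group with replacement `n_iter` times; reports the mean
#' bootstrap d, the 2.5/97.5 percentile confidence interval and a
#' two-sided sign-crossing p-value with add-one smoothing. Iterations with
#' a zero pooled SD are redrawn (and counted in the log).
#'
#' @param a,b Numeric vectors (convention: a = TD, b = ASD).
#' @param n_iter Bootstrap iterations (default 10,000).
#' @param seed Optional seed.
#' @param feature Label carried into the result.
#' @return A list of class `effect_size_result`: `feature`, `d` (mean
#'   bootstrap d), `d_obs` (sample d), `ci_low`, `ci_high`, `p`, `n_iter`.
#' @export
bootstrap_effect <- function(a, b, n_iter = 10000, seed = NULL,
                             feature = "feature") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_gp("bootstrap_effect needs >= 2 values per group")
  with_seed_if(seed, {
    d_obs <- cohens_d(a, b)
    na <- length(a); nb <- length(b)
    boot_d <- rep(NA_real_, n_iter)
    todo <- seq_len(n_iter)
    redrawn <- 0L
    while (length(todo)) {
      k <- length(todo)
      ma <- matrix(sample(a, k * na, replace = TRUE), nrow = k)
      mb <- matrix(sample(b, k * nb, replace = TRUE), nrow = k)
      mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
      var_a <- (rowSums(ma^2) - na * mean_a^2) / (na - 1)
      var_b <- (rowSums(mb^2) - nb * mean_b^2) / (nb - 1)
      sp <- sqrt(((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2))
      ok <- sp > 0
      boot_d[todo[ok]] <- (mean_a[ok] - mean_b[ok]) / sp[ok]
      redrawn <- redrawn + sum(!ok)
      todo <- todo[!ok]
    }
    if (redrawn) gp_log("redrew %d degenerate bootstrap iteration(s)", redrawn)
    ci <- stats::quantile(boot_d, c(0.025, 0.975), names = FALSE)
    structure(list(feature = feature, d = mean(boot_d), d_obs = d_obs,
                   ci_low = ci[1], ci_high = ci[2],
                   p = boot_sign_p(boot_d, d_obs), n_iter = n_iter,
                   boot = boot_d),
              class = "effect_size_result")
  })
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("<effect_size_result> %s: d = %.3f [%.3f, %.3f], p = %.4g (%d iter)\n",
              x$feature, x$d, x$ci_low, x$ci_high, x$p, x$n_iter))
  invisible(x)
}

#' Sample contiguous epochs from a timeline
#'
#' Draws `k` contiguous epochs of `duration_s` seconds with whole-second
#' start times uniform over the feasible set; for `k = 2` the second start
#' is uniform over the starts that do not overlap the first.
#'
#' @param total_s Total timeline duration (seconds).
#' @param duration_s Epoch duration (seconds).
#' @param k 1 or 2 epochs.
#' @param seed Optional seed.
#' @return Numeric vector of `k` start times (seconds).
#' @export
sample_epochs <- function(total_s, duration_s, k = 1, seed = NULL) {
  if (duration_s > total_s) stop_gp("epoch duration exceeds the timeline")
  if (k == 2 && 2 * duration_s > total_s)
    stop_gp("two non-overlapping epochs of %g s do not fit in %g s",
            duration_s, total_s)
  with_seed_if(seed, {
    starts_all <- 0:floor(total_s - duration_s)
    if (k == 1) {
      s1 <- if (length(starts_all) == 1L) starts_all else
        sample(starts_all, 1)
      return(s1)
    }
    # the first epoch must leave room for a disjoint second one
    firsts <- starts_all[starts_all >= duration_s |
                           starts_all + 2 * duration_s <= total_s]
    s1 <- if (length(firsts) == 1L) firsts else sample(firsts, 1)
    feasible <- starts_all[starts_all + duration_s <= s1 |
                             starts_all >= s1 + duration_s]
    c(s1, if (length(feasible) == 1L) feasible else sample(feasible, 1))
  })
}

#' Epoch-sampled bootstrap effect sizes
#'
#' Per iteration: (i) draw one random contiguous epoch of `duration_s`
#' from the combined timeline, (ii) resample participants with replacement
#' within each group, (iii) recompute the features within the epoch and
#' Cohen's d (TD - ASD). Reports the mean d over iterations, percentile
#' CI, the sign-crossing p per feature, and FDR-adjusted p across the
#' features of the table.
#'
#' @param tl A `cohort_timeline`.
#' @param features Feature names (default the four headline features).
#' @param duration_s Epoch duration in seconds (`NULL` = full timeline).
#' @param n_iter Iterations.
#' @param seed Optional seed.
#' @param resample Bootstrap-resample participants (TRUE, as in the
#'   sampling procedure; FALSE reduces to plain epoch-sampled d).
#' @return A data.frame, one row per feature, with `d`, `ci_low`,
#'   `ci_high`, `p`, `p_adj`, `epoch_minutes`, `n_iter`.
#' @export
epoch_sampled_effect <- function(tl, features = FOUR_FEATURES,
                                 duration_s = NULL, n_iter = 1000,
                                 seed = NULL, resample = TRUE) {
  with_seed_if(seed, {
    total_s <- timeline_duration(tl)
    if (is.null(duration_s)) duration_s <- total_s
    asd <- which(tl$groups == "ASD"); td <- which(tl$groups == "TD")
    boot_d <- matrix(NA_real_, n_iter, length(features),
                     dimnames = list(NULL, features))
    for (it in seq_len(n_iter)) {
      s1 <- sample_epochs(total_s, duration_s, k = 1)
      idx_td <- if (resample) sample(td, length(td), replace = TRUE) else td
      idx_asd <- if (resample) sample(asd, length(asd), replace = TRUE) else asd
      m <- epoch_features(tl, s1, duration_s, idx = c(idx_td, idx_asd))
      g <- rep(c("TD", "ASD"), c(length(idx_td), length(idx_asd)))
      for (f in features) {
        va <- m[g == "TD", f]; vb <- m[g == "ASD", f]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) < 2 || length(vb) < 2) next
        sp2 <- ((length(va) - 1) * stats::var(va) +
                  (length(vb) - 1) * stats::var(vb)) /
          (length(va) + length(vb) - 2)
        if (sp2 > 0) boot_d[it, f] <- (mean(va) - mean(vb)) / sqrt(sp2)
      }
    }
    full <- epoch_features(tl)
    res <- do.call(rbind, lapply(features, function(f) {
      bd <- boot_d[, f]; bd <- bd[!is.na(bd)]
      d_obs <- cohens_d(full[tl$groups == "TD", f],
                        full[tl$groups == "ASD", f])
      data.frame(feature = f, d = mean(bd),
                 ci_low = stats::quantile(bd, 0.025, names = FALSE),
                 ci_high = stats::quantile(bd, 0.975, names = FALSE),
                 p = boot_sign_p(bd, d_obs),
                 epoch_minutes = duration_s / 60, n_iter = n_iter)
    }))
    res$p_adj <- fdr_adjust(res$p)
    res
  })
}
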