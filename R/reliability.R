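# Within-individual reliability and its controls.
#
# Reliability is the rank-order stability of a gaze feature across two
# non-overlapping epochs: Spearman's correlation, across the participants
# of a group, between the feature computed in epoch 1 and in epoch 2. The
# sampling procedure repeats this over randomly drawn epoch pairs to give
# a distribution of correlations per feature and group.

#' Epoch-sampled within-individual reliability
#'
#' Per iteration: draw two non-overlapping epochs of `duration_s` from the
#' combined timeline, compute each feature per participant in each epoch,
#' and Spearman-correlate across participants, separately within each
#' group. Reports the mean correlation per feature and group, a
#' sign-crossing bootstrap p for the correlation, FDR adjustment within
#' the table, and a group-comparison p from the distribution of
#' `rho_ASD - rho_TD` across iterations. Iterations where a feature is
#' constant across participants are skipped with a log entry.
#'
#' @param tl A `cohort_timeline`.
#' @param features Feature names.
#' @param duration_s Epoch duration (seconds).
#' @param n_iter Iterations.
#' @param seed Optional seed.
#' @return A list with `table` (data.frame: feature, group, rho, p, p_adj,
#'   epoch_minutes, n_iter) and `group_diff` (data.frame: feature,
#'   mean_diff, p).
#' @export
reliability_sampled <- function(tl, features = FOUR_FEATURES,
                                duration_s = 600, n_iter = 1000,
                                seed = NULL) {
  groups <- c("ASD", "TD")
  for (g in groups)
    if (sum(tl$groups == g) < 3)
      stop_gp("need >= 3 kept participants in group %s", g)
  with_seed_if(seed, {
    total_s <- timeline_duration(tl)
    rho <- array(NA_real_, c(n_iter, length(features), 2),
                 dimnames = list(NULL, features, groups))
    # group-comparison stream: correlations on participant bootstrap
    # resamples, so the difference distribution reflects participant
    # sampling uncertainty as well as epoch variability
    rho_boot <- rho
    skipped <- 0L
    for (it in seq_len(n_iter)) {
      se <- sample_epochs(total_s, duration_s, k = 2)
      m1 <- epoch_features(tl, se[1], duration_s)
      m2 <- epoch_features(tl, se[2], duration_s)
      for (g in groups) {
        gi <- which(tl$groups == g)
        bi <- sample(gi, length(gi), replace = TRUE)
        for (f in features) {
          v1 <- m1[gi, f]; v2 <- m2[gi, f]
          ok <- !is.na(v1) & !is.na(v2)
          if (sum(ok) < 3 || stats::sd(v1[ok]) == 0 ||
              stats::sd(v2[ok]) == 0) {
            skipped <- skipped + 1L
            next
          }
          rho[it, f, g] <- stats::cor(v1[ok], v2[ok], method = "spearman")
          b1 <- m1[bi, f]; b2 <- m2[bi, f]
          okb <- !is.na(b1) & !is.na(b2)
          if (sum(okb) >= 3 && stats::sd(b1[okb]) > 0 &&
              stats::sd(b2[okb]) > 0)
            rho_boot[it, f, g] <- stats::cor(b1[okb], b2[okb],
                                             method = "spearman")
        }
      }
    }
    if (skipped) gp_log("skipped %d degenerate correlation(s)", skipped)
    tab <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(features, function(f) {
        r <- rho[, f, g]; r <- r[!is.na(r)]
        data.frame(feature = f, group = g, rho = mean(r),
                   p = boot_sign_p(r, mean(r)),
                   epoch_minutes = duration_s / 60, n_iter = n_iter)
      }))
    }))
    tab$p_adj <- stats::ave(tab$p, tab$group,
                            FUN = function(p) fdr_adjust(p))
    gd <- do.call(rbind, lapply(features, function(f) {
      diffs <- rho_boot[, f, "ASD"] - rho_boot[, f, "TD"]
      diffs <- diffs[!is.na(diffs)]
      data.frame(feature = f, mean_diff = mean(diffs),
                 p = boot_sign_p(diffs, mean(diffs)))
    }))
    list(table = tab, group_diff = gd)
  })
}

#' Familiarity-split t-tests
#'
#' Splits participants into familiar (rating > 5) and unfamiliar
#' (rating < 5) with an episode - ratings of exactly 5 and missing ratings
#' are excluded - and compares each gaze feature between the strata with a
#' two-tailed pooled-variance t-test, within the ASD group, within the TD
#' group, and pooled. Strata with fewer than 2 members skip the test with
#' a log entry.
#'
#' @param features A [feature_table()]-style data.frame (one row per
#'   participant per episode).
#' @param meta A [participant_meta()] with `familiarity_A`/`familiarity_B`.
#' @param episode_id Episode to test.
#' @param feature_names Features to test.
#' @return A data.frame: feature, scope (ASD/TD/all), n_familiar,
#'   n_unfamiliar, t, df, p (NA when skipped).
#' @export
familiarity_split_tests <- function(features, meta, episode_id = "A",
                                    feature_names = FOUR_FEATURES) {
  fam_col <- paste0("familiarity_", episode_id)
  if (!fam_col %in% names(meta))
    stop_gp("metadata lacks column %s", fam_col)
  ft <- features[features$episode_id == episode_id, , drop = FALSE]
  rating <- meta[[fam_col]][match(ft$participant_id, meta$participant_id)]
  stratum <- ifelse(is.na(rating), NA,
                    ifelse(rating > 5, "familiar",
                           ifelse(rating < 5, "unfamiliar", NA)))
  out <- NULL
  for (scope in c("ASD", "TD", "all")) {
    sel <- if (scope == "all") rep(TRUE, nrow(ft)) else ft$group == scope
    for (f in feature_names) {
      va <- ft[[f]][sel & !is.na(stratum) & stratum == "familiar"]
      vb <- ft[[f]][sel & !is.na(stratum) & stratum == "unfamiliar"]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      row <- data.frame(feature = f, scope = scope, episode_id = episode_id,
                        n_familiar = length(va), n_unfamiliar = length(vb),
                        t = NA_real_, df = NA_real_, p = NA_real_)
      if (length(va) >= 2 && length(vb) >= 2) {
        tt <- tryCatch(two_sample_t(va, vb), error = function(e) NULL)
        if (!is.null(tt)) {
          row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
        }
      } else {
        gp_log("familiarity test skipped for %s/%s (stratum < 2)", f, scope)
      }
      out <- rbind(out, row)
    }
  }
  out
}

#' Severity-feature Spearman correlations (ASD group)
#'
#' Spearman correlation of each gaze feature with the calibrated symptom
#' severity score, per episode, within the ASD group; participants with
#' missing severity are dropped pairwise. P-values are uncorrected
#' (asymptotic, tie-tolerant).
#'
#' @param features A [feature_table()]-style data.frame.
#' @param meta A [participant_meta()] with `severity_css`.
#' @param feature_names Features to test.
#' @return A data.frame: feature, episode_id, n, rho, p.
#' @export
severity_correlation <- function(features, meta,
                                 feature_names = FOUR_FEATURES) {
  out <- NULL
  for (e in unique(features$episode_id)) {
    ft <- features[features$episode_id == e & features$group == "ASD", ,
                   drop = FALSE]
    css <- meta$severity_css[match(ft$participant_id, meta$participant_id)]
    for (f in feature_names) {
      ok <- !is.na(css) & !is.na(ft[[f]])
      if (sum(ok) < 3)
        stop_gp("need >= 3 ASD participants with severity for %s", f)
      if (stats::sd(css[ok]) == 0)
        stop_gp("severity scores are all tied; correlation undefined")
      ct <- suppressWarnings(
        stats::cor.test(ft[[f]][ok], css[ok], method = "spearman",
                        exact = FALSE))
      out <- rbind(out, data.frame(feature = f, episode_id = e, n = sum(ok),
                                   rho = unname(ct$estimate),
                                   p = ct$p.value))
    }
  }
  out
}
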