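# Cohort timeline: the precomputed per-frame coding of a whole cohort.
#
# Every resampling analysis (epoch-sampled effect sizes, reliability,
# fingerprinting, classification, clustering) recomputes gaze features
# within randomly drawn epochs thousands of times. The timeline makes this
# cheap: episodes are concatenated on a common frame axis, each
# participant's frames carry a final AOI code, per 1-s bin the
# reference-heatmap correlation is precomputed with the leave-one-out
# reference, and cumulative counts let any epoch's feature vector be
# assembled in O(1) per participant.

FEATURE_NAMES <- c("pct_onscreen", "pct_face", "pct_nonsocial", "pct_body",
                   "pct_hands", "pct_eyes", "pct_mouth", "mean_heatmap_corr")
FOUR_FEATURES <- c("pct_onscreen", "pct_face", "pct_eyes", "mean_heatmap_corr")

#' Names of the gaze feature sets
#'
#' The full eight-feature gaze vector (on-screen, faces, non-social,
#' non-head body, hands, eyes, mouth percentages and the mean
#' reference-heatmap correlation) or the reduced four-feature set
#' (on-screen, faces, eyes, heatmap correlation) used for classification,
#' clustering and the reduced fingerprinting variant.
#'
#' @param set `"eight"` or `"four"`.
#' @return Character vector of feature names.
#' @export
gaze_feature_names <- function(set = c("eight", "four")) {
  switch(match.arg(set), eight = FEATURE_NAMES, four = FOUR_FEATURES)
}

#' Build a cohort timeline from recordings, scenes and metadata
#'
#' Runs the full coding pipeline for every participant: downsampling to the
#' frame rate, disk-overlap AOI assignment per on-screen frame, per-bin
#' gaze heatmaps and leave-one-out reference correlations, the
#' missing-data exclusion rule, and the 4-SD mean-correlation outlier
#' exclusion; episodes are concatenated in the order given.
#'
#' @param recordings Named list of [gaze_recording()] (`participant.episode`).
#' @param scenes Named list of `scene_spec`, one per episode, in timeline
#'   order.
#' @param meta A [participant_meta()] data.frame.
#' @param config A [pipeline_config()].
#' @param reference_group Group whose pooled gaze defines the reference
#'   heatmaps (`"TD"` default; `"ASD"` runs the symmetric analysis).
#' @param apply_exclusions Apply the missing-data and outlier exclusions.
#' @return An object of class `cohort_timeline`.
#' @export
build_timeline <- function(recordings, scenes, meta,
                           config = pipeline_config(),
                           reference_group = "TD",
                           apply_exclusions = TRUE) {
  fps <- config$frame_rate_fps
  ep_ids <- names(scenes)
  n_frames_ep <- vapply(scenes, `[[`, numeric(1), "n_frames")
  offsets <- cumsum(c(0, n_frames_ep))[seq_along(ep_ids)]
  names(offsets) <- ep_ids
  F_total <- sum(n_frames_ep)
  ids <- unique(meta$participant_id)

  # -- per-participant per-episode frame reduction ------------------------
  # X/Y hold each participant's on-screen frame-mean gaze point on the
  # concatenated frame axis (NA when missing or off screen).
  X <- matrix(NA_real_, length(ids), F_total, dimnames = list(ids, NULL))
  Y <- X
  summaries <- NULL
  for (id in ids) {
    for (e in ep_ids) {
      rec <- recordings[[paste(id, e, sep = ".")]]
      if (is.null(rec)) next
      fg <- downsample_to_frames(rec, fps, scenes[[e]]$n_frames, config$screen)
      on <- fg$status == "on_screen"
      cols <- offsets[[e]] + fg$frame[on] + 1L
      X[id, cols] <- fg$x[on]
      Y[id, cols] <- fg$y[on]
      summaries <- rbind(summaries, data.frame(
        participant_id = id, episode_id = e,
        frac_missing = mean(!on)))
    }
  }
  if (apply_exclusions) {
    excl <- apply_exclusion_criteria(summaries,
                                     config$exclusion_missing_fraction,
                                     n_episodes = length(ep_ids))
    kept <- excl$kept
  } else {
    kept <- ids[vapply(ids, function(id)
      sum(summaries$participant_id == id) == length(ep_ids), logical(1))]
    excl <- list(kept = kept,
                 excluded = data.frame(participant_id = character(),
                                       reason = character()))
  }
  if (length(kept) < 2L) stop_gp("fewer than 2 participants survive exclusion")
  X <- X[kept, , drop = FALSE]
  Y <- Y[kept, , drop = FALSE]

  # -- AOI labels, batched per (episode, shot) ----------------------------
  n <- length(kept)
  L <- matrix(0L, nrow = n, ncol = F_total, dimnames = list(kept, NULL))
  for (e in ep_ids) {
    scene <- scenes[[e]]
    maps <- scene_aoi_maps(scene)
    off <- offsets[[e]]
    ep_cols <- off + seq_len(scene$n_frames)
    hit <- which(!is.na(X[, ep_cols, drop = FALSE]), arr.ind = TRUE)
    if (!nrow(hit)) next
    frame0 <- hit[, 2] - 1L
    shots <- shot_of_frame(scene, frame0)
    cols_global <- off + hit[, 2]
    for (s in unique(shots)) {
      sel <- shots == s
      rws <- hit[sel, 1]; cls <- cols_global[sel]
      res <- assign_disks_batch(X[cbind(rws, cls)], Y[cbind(rws, cls)],
                                maps[[s]], config,
                                raster = rasterize_aoi_map(maps[[s]]))
      code <- ifelse(as.character(res$coarse) == "face",
                     AOI_CODES[as.character(res$fine)],
                     AOI_CODES[as.character(res$coarse)])
      L[cbind(rws, cls)] <- as.integer(code)
    }
  }

  # -- per-bin reference-heatmap correlations -----------------------------
  bin_frames <- round(config$bin_seconds * fps)
  n_bins <- floor(F_total / bin_frames)
  groups <- meta$group[match(kept, meta$participant_id)]
  ref_ids <- kept[groups == reference_group]
  points_by_bin <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    cols <- ((b - 1L) * bin_frames + 1L):(b * bin_frames)
    pts <- list()
    for (i in seq_len(n)) {
      on <- which(!is.na(X[i, cols]))
      if (length(on))
        pts[[kept[i]]] <- cbind(X[i, cols[on]], Y[i, cols[on]])
    }
    points_by_bin[[b]] <- pts
  }
  bin_r <- bin_reference_correlations(points_by_bin, kept, ref_ids, config)

  # -- outlier exclusion on mean reference correlation --------------------
  mean_r <- rowMeans(bin_r, na.rm = TRUE)
  outliers <- character()
  if (apply_exclusions && n >= 3L) {
    fl <- flag_heatmap_outliers(mean_r, k = 4)
    outliers <- names(fl)[fl]
    if (length(outliers)) {
      gp_log("excluding %d mean-correlation outlier(s): %s", length(outliers),
             paste(outliers, collapse = ", "))
      keep_i <- !(kept %in% outliers)
      kept <- kept[keep_i]; groups <- groups[keep_i]
      L <- L[keep_i, , drop = FALSE]
      bin_r <- bin_r[keep_i, , drop = FALSE]
      n <- length(kept)
    }
  }

  # -- cumulative structures ---------------------------------------------
  cum_of <- function(logical_mat) {
    cbind(0, t(apply(logical_mat, 1L, cumsum)))
  }
  cums <- list(
    onscreen = cum_of(L > 0L),
    face = cum_of(L >= AOI_CODES[["other_face"]]),
    non_social = cum_of(L == AOI_CODES[["non_social"]]),
    other_body = cum_of(L == AOI_CODES[["other_body"]]),
    hands = cum_of(L == AOI_CODES[["hands"]]),
    eyes = cum_of(L == AOI_CODES[["eyes"]]),
    mouth = cum_of(L == AOI_CODES[["mouth"]]))
  r_filled <- ifelse(is.na(bin_r), 0, bin_r)
  cum_r <- cbind(0, t(apply(r_filled, 1L, cumsum)))
  cum_rn <- cbind(0, t(apply(!is.na(bin_r), 1L, cumsum)))

  structure(list(ids = kept, groups = groups,
                 meta = meta[match(kept, meta$participant_id), , drop = FALSE],
                 fps = fps, bin_seconds = config$bin_seconds,
                 n_frames = F_total, n_bins = n_bins,
                 episode_ids = ep_ids, episode_offsets = offsets,
                 episode_frames = n_frames_ep,
                 labels = L, bin_r = bin_r, cums = cums,
                 cum_r = cum_r, cum_rn = cum_rn,
                 reference_group = reference_group,
                 excluded = excl$excluded, outliers = outliers,
                 config = config),
            class = "cohort_timeline")
}

#' @export
print.cohort_timeline <- function(x, ...) {
  cat(sprintf(paste0("<cohort_timeline> %d participants (%d ASD / %d TD), ",
                     "%d frames (%.1f min) over episodes %s, %d bins, ref %s\n"),
              length(x$ids), sum(x$groups == "ASD"), sum(x$groups == "TD"),
              x$n_frames, x$n_frames / x$fps / 60,
              paste(x$episode_ids, collapse = "+"), x$n_bins,
              x$reference_group))
  if (nrow(x$excluded) || length(x$outliers))
    cat(sprintf("  excluded: %d by missing data, %d heatmap outlier(s)\n",
                nrow(x$excluded), length(x$outliers)))
  invisible(x)
}

#' Total timeline duration in seconds
#' @param tl A `cohort_timeline`.
#' @return Seconds.
#' @export
timeline_duration <- function(tl) tl$n_frames / tl$fps

#' Gaze feature vectors within an epoch
#'
#' Assembles the eight-feature gaze vector for each requested participant
#' over the frames of `[start_s, start_s + duration_s)`: on-screen
#' percentage (of the epoch's frames), AOI percentages (of the epoch's
#' on-screen frames) and the mean per-bin reference-heatmap correlation
#' over the 1-s bins fully inside the epoch. Rows may repeat (bootstrap
#' resampling). Participants with no on-screen frame in the epoch get NA
#' features.
#'
#' @param tl A `cohort_timeline`.
#' @param start_s,duration_s Epoch bounds in seconds (frame-aligned).
#' @param idx Participant row indices into `tl$ids` (default all).
#' @return A numeric matrix (length(idx) x 8) with `FEATURE_NAMES` columns.
#' @export
epoch_features <- function(tl, start_s = 0, duration_s = timeline_duration(tl),
                           idx = seq_along(tl$ids)) {
  f0 <- round(start_s * tl$fps)
  f1 <- round((start_s + duration_s) * tl$fps)
  if (f0 < 0 || f1 > tl$n_frames || f1 <= f0)
    stop_gp("epoch [%g, %g) s outside the timeline", start_s,
            start_s + duration_s)
  total <- f1 - f0
  cnt <- function(name) tl$cums[[name]][idx, f1 + 1L] -
    tl$cums[[name]][idx, f0 + 1L]
  on <- cnt("onscreen")
  safe_pct <- function(x) ifelse(on > 0, 100 * x / on, NA_real_)
  b0 <- ceiling(f0 / tl$fps / tl$bin_seconds)
  b1 <- floor(f1 / tl$fps / tl$bin_seconds)
  b1 <- min(b1, tl$n_bins)
  if (b1 > b0) {
    nr <- tl$cum_rn[idx, b1 + 1L] - tl$cum_rn[idx, b0 + 1L]
    sr <- tl$cum_r[idx, b1 + 1L] - tl$cum_r[idx, b0 + 1L]
    mr <- ifelse(nr > 0, sr / nr, NA_real_)
  } else mr <- rep(NA_real_, length(idx))
  m <- cbind(pct_onscreen = 100 * on / total,
             pct_face = safe_pct(cnt("face")),
             pct_nonsocial = safe_pct(cnt("non_social")),
             pct_body = safe_pct(cnt("other_body")),
             pct_hands = safe_pct(cnt("hands")),
             pct_eyes = safe_pct(cnt("eyes")),
             pct_mouth = safe_pct(cnt("mouth")),
             mean_heatmap_corr = mr)
  rownames(m) <- tl$ids[idx]
  m
}

#' Per-episode gaze feature table
#'
#' One row per kept participant per episode with the eight gaze features
#' computed over the whole episode, plus group and metadata columns.
#'
#' @param tl A `cohort_timeline`.
#' @return A data.frame.
#' @export
feature_table <- function(tl) {
  out <- NULL
  for (k in seq_along(tl$episode_ids)) {
    e <- tl$episode_ids[k]
    start_s <- tl$episode_offsets[[e]] / tl$fps
    dur_s <- tl$episode_frames[[k]] / tl$fps
    m <- epoch_features(tl, start_s, dur_s)
    out <- rbind(out, data.frame(participant_id = tl$ids, group = tl$groups,
                                 episode_id = e, m, row.names = NULL))
  }
  out
}
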