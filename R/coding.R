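# Coding raw gaze to frames and AOIs.
#
# Raw gaze (120-300 Hz) is reduced to one mean gaze point per video frame
# (24 fps), each point is represented as a disk of 1 degree visual angle
# diameter, and the frame is assigned to the AOI with the maximum rasterized
# disk overlap: first at the coarse level (face / hands / other body /
# non-social), then, within face frames, at the fine level (eyes / mouth /
# other face). The hierarchical pass keeps the nested eyes and mouth
# fractions well defined (each is necessarily no larger than the face
# fraction).

#' Downsample a gaze recording to the video frame rate
#'
#' Frame `f` (0-based) spans the half-open interval `[f/fps, (f+1)/fps)`;
#' a sample exactly on a boundary belongs to the later frame. Each frame's
#' gaze point is the mean of the valid samples in its span. A frame with no
#' valid sample has status `missing`; a mean point outside the screen bounds
#' has status `off_screen`; otherwise `on_screen`. The reduction depends
#' only on which samples fall in each span, so 300 Hz and 120 Hz recordings
#' of the same trajectory reduce identically.
#'
#' @param rec A [gaze_recording()]; `rec$rate_hz` must exceed `frame_rate`.
#' @param frame_rate Video frame rate in Hz (default 24).
#' @param n_frames Number of video frames in the episode.
#' @param screen A [screen_geometry()].
#' @return A data.frame with columns `frame` (0-based), `x`, `y` (NA when
#'   missing), `n_valid`, `status` (factor on_screen/off_screen/missing).
#' @export
downsample_to_frames <- function(rec, frame_rate = 24, n_frames,
                                 screen = screen_geometry()) {
  assert_scalar_num(n_frames, "n_frames", positive = TRUE, integerish = TRUE)
  if (rec$rate_hz <= frame_rate)
    stop_gp("recording rate (%g Hz) must exceed the frame rate (%g Hz)",
            rec$rate_hz, frame_rate)
  s <- rec$samples
  f <- floor(s$t * frame_rate + 1e-9)
  keep <- s$valid & f >= 0 & f < n_frames
  f_id <- factor(f[keep], levels = 0:(n_frames - 1))
  n_valid <- as.integer(table(f_id))
  sum_x <- as.numeric(tapply(s$x[keep], f_id, sum, default = 0))
  sum_y <- as.numeric(tapply(s$y[keep], f_id, sum, default = 0))
  x <- ifelse(n_valid > 0, sum_x / n_valid, NA_real_)
  y <- ifelse(n_valid > 0, sum_y / n_valid, NA_real_)
  on_screen <- n_valid > 0 & !is.na(x) &
    x >= 0 & x < screen$width_px & y >= 0 & y < screen$height_px
  status <- ifelse(n_valid == 0, "missing",
                   ifelse(on_screen, "on_screen", "off_screen"))
  data.frame(frame = 0:(n_frames - 1), x = x, y = y, n_valid = n_valid,
             status = factor(status,
                             levels = c("on_screen", "off_screen", "missing")))
}

# Batched disk-overlap assignment: one AOI map shared by many gaze centres
# (all frames of a shot, typically). Returns a data.frame of final labels
# and per-candidate overlap areas (px^2 = pixel counts). When a
# precomputed label raster for the map is supplied, disk pixels are
# labelled by lookup; otherwise by point-wise box tests (identical result).
assign_disks_batch <- function(cx, cy, aoi_map, config, raster = NULL) {
  radius <- config$disk_diameter_deg * config$screen$px_per_degree / 2
  n <- length(cx)
  span <- seq.int(-ceiling(radius) - 1L, ceiling(radius) + 1L)
  m <- length(span)^2
  dx <- rep(span, times = length(span))
  dy <- rep(span, each = length(span))
  out_counts <- matrix(0L, nrow = n, ncol = 6L)
  chunk <- max(1L, floor(4e6 / m))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    k <- length(idx)
    # pixel centres of the candidate square around each centre
    px <- rep(floor(cx[idx]), each = m) + rep(dx, times = k) + 0.5
    py <- rep(floor(cy[idx]), each = m) + rep(dy, times = k) + 0.5
    ccx <- rep(cx[idx], each = m); ccy <- rep(cy[idx], each = m)
    keep <- (px - ccx)^2 + (py - ccy)^2 <= radius^2 &
      px >= 0 & px < config$screen$width_px &
      py >= 0 & py < config$screen$height_px
    which_centre <- rep(seq_len(k), each = m)[keep]
    lab <- if (is.null(raster))
      label_points(px[keep], py[keep], aoi_map)
    else
      raster[cbind(py[keep] + 0.5, px[keep] + 0.5)]
    counts <- tabulate((which_centre - 1L) * 6L + lab, nbins = k * 6L)
    out_counts[idx, ] <- matrix(counts, nrow = k, ncol = 6L, byrow = TRUE)
  }
  colnames(out_counts) <- names(AOI_CODES)
  coarse_area <- cbind(
    face = out_counts[, "other_face"] + out_counts[, "eyes"] +
      out_counts[, "mouth"],
    hands = out_counts[, "hands"],
    other_body = out_counts[, "other_body"],
    non_social = out_counts[, "non_social"])
  coarse <- COARSE_LEVELS[max.col(coarse_area, ties.method = "first")]
  fine_area <- cbind(eyes = out_counts[, "eyes"],
                     mouth = out_counts[, "mouth"],
                     other_face = out_counts[, "other_face"])
  fine <- ifelse(coarse == "face",
                 FINE_LEVELS[max.col(fine_area, ties.method = "first")],
                 NA_character_)
  list(coarse = factor(coarse, levels = COARSE_LEVELS),
       fine = factor(fine, levels = FINE_LEVELS),
       overlap = cbind(coarse_area, eyes = fine_area[, "eyes"],
                       mouth = fine_area[, "mouth"],
                       other_face = fine_area[, "other_face"]))
}

#' Assign one frame's gaze to an AOI by maximum disk overlap
#'
#' The frame's mean gaze point is represented as a disk of
#' `disk_diameter_deg` degrees of visual angle (a pixel belongs to the disk
#' iff its centre lies within the radius); the coarse label is the AOI with
#' the maximum rasterized overlap area, with ties broken in the fixed order
#' face > hands > other body > non-social. For face frames, the fine label
#' is the maximum-overlap facial sub-region (ties: eyes > mouth > other
#' face).
#'
#' @param fg One row of [downsample_to_frames()] output with status
#'   `on_screen` (anything else is a contract violation).
#' @param aoi_map The frame's [build_frame_aoi_map()].
#' @param config A [pipeline_config()].
#' @return A list with `frame`, `coarse`, `fine`, and the named `overlap`
#'   area vector (px^2).
#' @export
assign_frame_aoi <- function(fg, aoi_map, config = pipeline_config()) {
  if (!identical(as.character(fg$status), "on_screen"))
    stop_gp("assign_frame_aoi called on a frame with status '%s'",
            as.character(fg$status))
  res <- assign_disks_batch(fg$x, fg$y, aoi_map, config)
  list(frame = fg$frame, coarse = as.character(res$coarse),
       fine = as.character(res$fine), overlap = res$overlap[1, ])
}

#' Compute gaze feature fractions for one participant-epoch
#'
#' On-screen percentage is the number of on-screen frames over the total
#' number of frames; every AOI percentage is the number of frames carrying
#' that label over the number of on-screen frames (controlling AOI fractions
#' for individual differences in on-screen time). Eyes and mouth are counted
#' from the fine labels and are therefore sub-fractions of the face
#' percentage.
#'
#' @param coarse,fine Factors of per-frame labels (length = frames on
#'   screen; as produced by the batch assignment).
#' @param n_frames_total Total number of frames in the epoch.
#' @return A named numeric vector `pct_onscreen`, `pct_face`,
#'   `pct_nonsocial`, `pct_body`, `pct_hands`, `pct_eyes`, `pct_mouth`
#'   (all NA, with attribute `flagged_missing`, when no frame is on screen).
#' @export
compute_feature_fractions <- function(coarse, fine, n_frames_total) {
  n_on <- length(coarse)
  if (n_on == 0L) {
    out <- c(pct_onscreen = 0, pct_face = NA_real_, pct_nonsocial = NA_real_,
             pct_body = NA_real_, pct_hands = NA_real_, pct_eyes = NA_real_,
             pct_mouth = NA_real_)
    attr(out, "flagged_missing") <- TRUE
    return(out)
  }
  tab <- table(factor(coarse, levels = COARSE_LEVELS))
  fine_tab <- table(factor(fine, levels = FINE_LEVELS))
  c(pct_onscreen = 100 * n_on / n_frames_total,
    pct_face = 100 * as.numeric(tab[["face"]]) / n_on,
    pct_nonsocial = 100 * as.numeric(tab[["non_social"]]) / n_on,
    pct_body = 100 * as.numeric(tab[["other_body"]]) / n_on,
    pct_hands = 100 * as.numeric(tab[["hands"]]) / n_on,
    pct_eyes = 100 * as.numeric(fine_tab[["eyes"]]) / n_on,
    pct_mouth = 100 * as.numeric(fine_tab[["mouth"]]) / n_on)
}

#' Apply participant exclusion criteria
#'
#' A participant is excluded when gaze is missing (tracker dropout or gaze
#' off the presentation monitor) for more than `threshold` of the frames in
#' one or both episodes ("more than half" is strict: exactly 50 percent is
#' kept), or when an episode is absent altogether.
#'
#' @param summaries A data.frame with columns `participant_id`,
#'   `episode_id`, `frac_missing` (fraction of frames not on screen).
#' @param threshold Missing-fraction threshold (default 0.5).
#' @param n_episodes Number of episodes each participant must have.
#' @return A list with `kept` (character vector of participant ids) and
#'   `excluded` (data.frame of ids and reasons).
#' @export
apply_exclusion_criteria <- function(summaries, threshold = 0.5,
                                     n_episodes = 2L) {
  stopifnot(all(c("participant_id", "episode_id", "frac_missing") %in%
                  names(summaries)))
  ids <- unique(summaries$participant_id)
  excluded <- data.frame(participant_id = character(), reason = character())
  kept <- character()
  for (id in ids) {
    rows <- summaries[summaries$participant_id == id, , drop = FALSE]
    if (length(unique(rows$episode_id)) < n_episodes) {
      excluded <- rbind(excluded, data.frame(
        participant_id = id, reason = "incomplete sessions"))
    } else if (any(rows$frac_missing > threshold)) {
      bad <- rows$episode_id[rows$frac_missing > threshold]
      excluded <- rbind(excluded, data.frame(
        participant_id = id,
        reason = sprintf("missing fraction > %g in episode(s) %s", threshold,
                         paste(bad, collapse = ","))))
    } else kept <- c(kept, id)
  }
  if (nrow(excluded))
    gp_log("excluded %d participant(s): %s", nrow(excluded),
           paste(sprintf("%s (%s)", excluded$participant_id, excluded$reason),
                 collapse = "; "))
  list(kept = kept, excluded = excluded)
}
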