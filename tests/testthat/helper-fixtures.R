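# Shared fixtures: all synthetic, built in code at test time.

gaze_quiet(TRUE)

tiny_config <- function(...) {
  pipeline_config(heatmap_downsample = 4, n_boot = 500, n_perm = 500, ...)
}

# A small pipeline-built timeline, cached across test files via options().
demo_timeline <- function() {
  tl <- getOption("gazepheno.test.demo_tl")
  if (!is.null(tl)) return(tl)
  cfg <- tiny_config()
  spec <- cohort_spec(
    n_asd = 6, n_td = 8,
    episodes = list(list(episode_id = "A", duration_s = 60),
                    list(episode_id = "B", duration_s = 60)),
    seed = 404)
  co <- simulate_cohort(spec, cfg)
  tl <- build_timeline(co$recordings, co$scenes, co$meta, co$config)
  options(gazepheno.test.demo_tl = tl)
  tl
}

# Fabricated timeline: per-frame labels drawn from per-participant AOI
# probabilities and per-bin correlations from a participant mean plus
# noise. Gives full control over the generative structure at trivial cost
# for the resampling-statistics tests. `p_eyes_within`, `p_on` and
# `corr_mean` recycle to one value per participant (stable traits).
fake_timeline <- function(p_face, p_eyes_within = 0.6, p_on = 0.95,
                          groups = NULL, minutes = 4, corr_mean = NULL,
                          corr_noise_sd = 0.02, fps = 24, seed = 1) {
  set.seed(seed)
  n <- length(p_face)
  if (is.null(groups)) groups <- rep(c("ASD", "TD"), length.out = n)
  if (is.null(corr_mean)) corr_mean <- 0.3 + 0.4 * p_face
  p_eyes_within <- rep(p_eyes_within, length.out = n)
  p_on <- rep(p_on, length.out = n)
  corr_mean <- rep(corr_mean, length.out = n)
  F_total <- round(minutes * 60 * fps)
  n_bins <- floor(F_total / fps)
  ids <- sprintf("p%02d", seq_len(n))
  codes <- c(non_social = 1L, other_body = 2L, hands = 3L,
             other_face = 4L, eyes = 5L, mouth = 6L)
  L <- matrix(0L, n, F_total, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    on <- stats::runif(F_total) < p_on[i]
    pf <- p_face[i]; pe <- p_eyes_within[i]
    probs <- c(non_social = (1 - pf) * 0.55, other_body = (1 - pf) * 0.30,
               hands = (1 - pf) * 0.15,
               other_face = pf * (1 - pe - 0.2),
               eyes = pf * pe, mouth = pf * 0.2)
    lab <- sample(codes, F_total, replace = TRUE, prob = probs)
    L[i, on] <- lab[on]
  }
  bin_r <- matrix(stats::rnorm(n * n_bins, corr_mean, corr_noise_sd),
                  n, n_bins, dimnames = list(ids, NULL))
  bin_r <- pmin(pmax(bin_r, -1), 1)
  cum_of <- function(lm) cbind(0, t(apply(lm, 1, cumsum)))
  meta <- participant_meta(data.frame(participant_id = ids, group = groups))
  structure(list(ids = ids, groups = groups, meta = meta, fps = fps,
                 bin_seconds = 1, n_frames = F_total, n_bins = n_bins,
                 episode_ids = "A",
                 episode_offsets = c(A = 0), episode_frames = F_total,
                 labels = L, bin_r = bin_r,
                 cums = list(onscreen = cum_of(L > 0L),
                             face = cum_of(L >= 4L),
                             non_social = cum_of(L == 1L),
                             other_body = cum_of(L == 2L),
                             hands = cum_of(L == 3L),
                             eyes = cum_of(L == 5L),
                             mouth = cum_of(L == 6L)),
                 cum_r = cbind(0, t(apply(bin_r, 1, cumsum))),
                 cum_rn = cbind(0, t(apply(!is.na(bin_r), 1, cumsum))),
                 reference_group = "TD",
                 excluded = data.frame(participant_id = character(),
                                       reason = character()),
                 outliers = character(),
                 config = tiny_config()),
            class = "cohort_timeline")
}

# Brute-force disk-overlap oracle: enumerate every pixel of the bounding
# square, test disk membership and box memberships with plain loops.
oracle_disk_assignment <- function(cx, cy, aoi_map, config) {
  r <- config$disk_diameter_deg * config$screen$px_per_degree / 2
  counts <- stats::setNames(numeric(6), c("non_social", "other_body",
                                          "hands", "other_face", "eyes",
                                          "mouth"))
  in_b <- function(px, py, b)
    px >= b[["x0"]] && px < b[["x1"]] && py >= b[["y0"]] && py < b[["y1"]]
  for (ix in floor(cx - r - 1):ceiling(cx + r + 1)) {
    for (iy in floor(cy - r - 1):ceiling(cy + r + 1)) {
      px <- ix + 0.5; py <- iy + 0.5
      if ((px - cx)^2 + (py - cy)^2 > r^2) next
      if (px < 0 || px >= config$screen$width_px ||
          py < 0 || py >= config$screen$height_px) next
      lab <- "non_social"
      for (b in aoi_map$body) if (in_b(px, py, b)) lab <- "other_body"
      for (b in aoi_map$hands) if (in_b(px, py, b)) lab <- "hands"
      face_hit <- FALSE
      for (f in aoi_map$faces) if (in_b(px, py, f$face)) face_hit <- TRUE
      if (face_hit) {
        lab <- "other_face"
        for (f in aoi_map$faces)
          if (in_b(px, py, f$face) && !gazepheno:::box_is_empty(f$mouth) &&
              in_b(px, py, f$mouth)) lab <- "mouth"
        for (f in aoi_map$faces)
          if (in_b(px, py, f$face) && !gazepheno:::box_is_empty(f$eyes) &&
              in_b(px, py, f$eyes)) lab <- "eyes"
      }
      counts[lab] <- counts[lab] + 1
    }
  }
  coarse_area <- c(face = counts[["other_face"]] + counts[["eyes"]] +
                     counts[["mouth"]],
                   hands = counts[["hands"]],
                   other_body = counts[["other_body"]],
                   non_social = counts[["non_social"]])
  coarse <- names(coarse_area)[which.max(coarse_area)]
  fine <- if (coarse == "face") {
    fa <- counts[c("eyes", "mouth", "other_face")]
    names(fa)[which.max(fa)]
  } else NA_character_
  list(coarse = coarse, fine = fine, counts = counts)
}

# A one-shot scene with a single person whose regions are known boxes.
single_person_scene <- function(duration_s = 10, screen = screen_geometry(),
                                fps = 24) {
  person <- list(
    face_box = c(800, 200, 1100, 600),
    keypoints = list(left_eye = c(890, 360), right_eye = c(1010, 360),
                     nose = c(950, 420), mouth_left = c(905, 490),
                     mouth_right = c(995, 490)),
    hands = list(c(600, 800, 700, 900)),
    body = list(c(700, 560, 1200, 1080)))
  n_frames <- round(duration_s * fps)
  structure(list(episode_id = "A", duration_s = duration_s,
                 frame_rate_fps = fps, n_frames = n_frames,
                 shot_start = 0L, shot_end = n_frames,
                 persons_by_shot = list(list(person)), screen = screen),
            class = "scene_spec")
}
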