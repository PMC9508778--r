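# Synthetic cohort generator.
#
# The analysis pipeline assumes a particular statistical structure in its
# inputs: stable per-participant gaze preferences, group-level mean shifts,
# between-participant heterogeneity, a per-session perturbation, spatial
# noise and missingness. This module defines an explicit generative model
# with exactly that structure so every downstream stage can be exercised
# and calibrated without raw eye-tracking data.
#
# Generative model, in brief:
#   * A scene is a sequence of shots (lognormal durations, median ~4 s);
#     each shot shows 0-3 persons (>= 1 person in ~96% of frames by
#     default), each with a face box, five deterministic facial keypoints,
#     hand boxes and a body box.
#   * Each participant owns latent gaze traits on the logit scale
#     (probability of on-screen gaze; of face-directed gaze when on screen;
#     of eyes / mouth within a face), drawn once from their group's
#     distribution, then perturbed per episode by session jitter.
#   * Gaze follows a dwell process: per dwell, a target AOI is drawn from
#     the trait-weighted categorical over the AOIs present in the shot
#     (renormalized when a category is absent), an anchor point is placed at
#     the target centroid blended toward screen centre, Gaussian scatter is
#     added, and raw samples are emitted at the tracker rate with small
#     per-sample noise. With probability 1 - p_onscreen a dwell is
#     off-screen (invalid samples). Dwells are frame-aligned and never cross
#     shot boundaries, so realized AOI fractions converge to the trait
#     probabilities.
#
# Traits use logit-normal distributions (not Beta) so that the group mean
# shift and the between-participant heterogeneity are independent knobs.

TRAIT_NAMES <- c("p_onscreen", "p_face", "p_eyes", "q_mouth")

# How non-face on-screen gaze splits over the remaining coarse AOIs.
NONFACE_WEIGHTS <- c(non_social = 0.55, other_body = 0.30, hands = 0.15)

#' Per-participant, per-episode gaze trait vector
#'
#' @param p_onscreen Probability a dwell produces on-screen gaze.
#' @param p_face Probability on-screen gaze targets a face (when present).
#' @param p_eyes,p_mouth Probabilities, within face-directed gaze, of the
#'   eyes and mouth sub-regions (`p_eyes + p_mouth <= 1`).
#' @param sigma_spatial_deg Within-dwell spatial scatter (degrees).
#' @param center_bias Weight pulling anchors toward the screen centre.
#' @param dwell_mean_s Mean dwell duration (seconds).
#' @return An object of class `trait_vector`.
#' @export
trait_vector <- function(p_onscreen, p_face, p_eyes, p_mouth,
                         sigma_spatial_deg = 0.25, center_bias = 0.02,
                         dwell_mean_s = 0.5) {
  pr <- c(p_onscreen = p_onscreen, p_face = p_face, p_eyes = p_eyes,
          p_mouth = p_mouth)
  if (any(pr < 0 | pr > 1)) stop_gp("trait probabilities must lie in [0, 1]")
  if (p_eyes + p_mouth > 1 + 1e-12)
    stop_gp("p_eyes + p_mouth must not exceed 1")
  if (sigma_spatial_deg < 0) stop_gp("sigma_spatial_deg must be >= 0")
  structure(list(p_onscreen = p_onscreen, p_face = p_face, p_eyes = p_eyes,
                 p_mouth = p_mouth, sigma_spatial_deg = sigma_spatial_deg,
                 center_bias = center_bias, dwell_mean_s = dwell_mean_s),
            class = "trait_vector")
}

default_trait_means <- function() {
  # Group means on the logit scale, calibrated so that realized cohort
  # fractions land near the face/eyes looking-time magnitudes typical of
  # adults watching a sitcom (faces ~77-81%, eyes ~52-60% of on-screen gaze
  # in the first episode; lower face time in the second).
  list(TD = c(p_onscreen = stats::qlogis(0.93),
              p_face = stats::qlogis(0.807),
              p_eyes = stats::qlogis(0.746),
              q_mouth = 0.85),
       ASD = c(p_onscreen = stats::qlogis(0.90),
               p_face = stats::qlogis(0.774),
               p_eyes = stats::qlogis(0.672),
               q_mouth = 0.85))
}

default_trait_sds <- function() {
  list(TD = c(p_onscreen = 0.40, p_face = 0.24, p_eyes = 0.80, q_mouth = 0.40),
       ASD = c(p_onscreen = 0.40, p_face = 0.33, p_eyes = 0.80, q_mouth = 0.40))
}

#' Synthetic cohort specification
#'
#' Describes a cohort for the generator: group sizes, episode lengths,
#' group trait distributions (mean and between-participant SD on the logit
#' scale, per trait, per group), per-episode mean offsets (the second
#' episode draws less face gaze), the session-jitter SD, and scene/gaze
#' nuisance parameters. Defaults are sized for desk scale (two 2-minute
#' episodes, 20 + 20 participants); study scale (48 + 105, ~43 min) is a
#' matter of arguments.
#'
#' @param n_asd,n_td Group sizes (>= 2 each for group statistics).
#' @param episodes List of `list(episode_id =, duration_s =)`.
#' @param trait_means,trait_sds Named lists (`TD`, `ASD`) of named numeric
#'   vectors over `p_onscreen`, `p_face`, `p_eyes`, `q_mouth` (logit scale;
#'   `q_mouth` is the mouth share of non-eyes face gaze).
#' @param episode_offsets Named list (episode id -> named numeric of logit
#'   offsets) applied on top of the participant's latent traits.
#' @param session_jitter_sd SD of the per-episode logit perturbation.
#' @param mixture Optional named list (`TD`, `ASD`) of
#'   `list(fraction =, shift =, within_sd =, truncate =)` planting a
#'   shifted trait subgroup: `fraction` of the group has `shift` (named
#'   logit offsets) added to its latent means; when `within_sd`/`truncate`
#'   are given, latent deviations are drawn with that SD truncated at
#'   `truncate` SDs so planted subgroup membership is unambiguous.
#' @param person_prob Probability a shot contains at least one person.
#' @param sigma_spatial_deg,center_bias,dwell_mean_s Gaze nuisance
#'   parameters shared by the cohort.
#' @param frame_rate_fps,rate_hz Video frame rate and tracker rate.
#' @param screen A [screen_geometry()].
#' @param seed Integer seed driving all cohort randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 20, n_td = 20,
                        episodes = list(list(episode_id = "A", duration_s = 120),
                                        list(episode_id = "B", duration_s = 120)),
                        trait_means = default_trait_means(),
                        trait_sds = default_trait_sds(),
                        episode_offsets = list(B = c(p_face = -0.39)),
                        session_jitter_sd = 0.15,
                        mixture = NULL,
                        person_prob = 0.96,
                        sigma_spatial_deg = 0.25, center_bias = 0.02,
                        dwell_mean_s = 0.5,
                        frame_rate_fps = 24, rate_hz = 300,
                        screen = screen_geometry(), seed = 1L) {
  assert_scalar_num(n_asd, "n_asd", positive = TRUE, integerish = TRUE)
  assert_scalar_num(n_td, "n_td", positive = TRUE, integerish = TRUE)
  if (n_asd < 2 || n_td < 2) stop_gp("need >= 2 participants per group")
  if (session_jitter_sd < 0) stop_gp("session_jitter_sd must be >= 0")
  for (g in c("TD", "ASD")) {
    if (any(trait_sds[[g]] < 0)) stop_gp("trait SDs must be >= 0")
    if (!all(TRAIT_NAMES %in% names(trait_means[[g]])))
      stop_gp("trait_means$%s must name all of: %s", g,
              paste(TRAIT_NAMES, collapse = ", "))
  }
  structure(list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
                 episodes = episodes, trait_means = trait_means,
                 trait_sds = trait_sds, episode_offsets = episode_offsets,
                 session_jitter_sd = session_jitter_sd, mixture = mixture,
                 person_prob = person_prob,
                 sigma_spatial_deg = sigma_spatial_deg,
                 center_bias = center_bias, dwell_mean_s = dwell_mean_s,
                 frame_rate_fps = frame_rate_fps, rate_hz = rate_hz,
                 screen = screen, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort with a planted heterogeneous (mixture) structure
#'
#' Convenience builder for the heterogeneity scenario: the ASD group is a
#' 50/50 mixture of typical-like and shifted gaze traits (reduced face and
#' eyes preference), and a minority of the control group shares the shifted
#' mode, mirroring the observation that unsupervised gaze clusters split
#' off atypical controls together with atypical autistic individuals.
#' Within-mode trait spread is truncated so that planted subgroup
#' membership is unambiguous, which is what makes planted-recovery checks
#' well defined.
#'
#' @param n_asd,n_td Group sizes.
#' @param shift Named logit offsets defining the shifted mode.
#' @param asd_fraction,td_fraction Shifted fractions per group.
#' @param ... Passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
heterogeneous_cohort_spec <- function(n_asd = 20, n_td = 36,
                                      shift = c(p_onscreen = -0.5, p_face = -1.2, p_eyes = -1.0),
                                      asd_fraction = 0.5, td_fraction = 0.25,
                                      ...) {
  means <- default_trait_means()
  # small global atypicality on top of the mixture structure
  means$ASD[c("p_face", "p_eyes")] <- means$TD[c("p_face", "p_eyes")] - 0.08
  # modes stay unambiguous on the shifted axes (tight, truncated spread)
  # while unshifted axes keep realistic between-participant heterogeneity
  wsd <- c(p_onscreen = 0.4, p_face = 0.15, p_eyes = 0.15, q_mouth = 0.3)
  cohort_spec(n_asd = n_asd, n_td = n_td,
              trait_means = means,
              mixture = list(
                ASD = list(fraction = asd_fraction, shift = shift,
                           within_sd = wsd, truncate = 2),
                TD = list(fraction = td_fraction, shift = shift,
                          within_sd = wsd, truncate = 2)),
              dwell_mean_s = 0.35,
              ...)
}

rtruncnorm1 <- function(n, sd, trunc) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  for (k in 1:20) {
    bad <- abs(x) > trunc * sd
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  pmin(pmax(x, -trunc * sd), trunc * sd)
}

#' Sample participant traits and metadata for a cohort
#'
#' Each participant's latent logit traits are drawn once from their group
#' distribution (optionally with a planted shifted-mode mixture), then each
#' episode's effective traits are the latent values plus the episode offset
#' plus independent session jitter, mapped through the logistic function.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional seed override (defaults to `spec$seed`).
#' @return A list with `traits` (participant id -> episode id ->
#'   [trait_vector()]), `latent` (participant x trait logit matrix), and
#'   `meta` (a [participant_meta()] data.frame including the planted-mode
#'   label and per-episode familiarity ratings).
#' @export
sample_cohort_traits <- function(spec, seed = NULL) {
  with_seed_if(seed %||% spec$seed, {
    groups <- c(rep("ASD", spec$n_asd), rep("TD", spec$n_td))
    ids <- sprintf("%s%02d", ifelse(groups == "ASD", "a", "t"),
                   c(seq_len(spec$n_asd), seq_len(spec$n_td)))
    n <- length(ids)
    latent <- matrix(NA_real_, n, length(TRAIT_NAMES),
                     dimnames = list(ids, TRAIT_NAMES))
    planted <- rep("typical", n)
    for (g in c("ASD", "TD")) {
      gi <- which(groups == g)
      mu <- spec$trait_means[[g]][TRAIT_NAMES]
      sd_g <- spec$trait_sds[[g]][TRAIT_NAMES]
      mix <- spec$mixture[[g]]
      if (!is.null(mix)) {
        n_shift <- round(mix$fraction * length(gi))
        shifted <- gi[seq_len(n_shift)]
        planted[shifted] <- "shifted"
        wsd <- mix$within_sd %||% sd_g
        trunc <- mix$truncate %||% Inf
        for (j in seq_along(TRAIT_NAMES)) {
          tn <- TRAIT_NAMES[j]
          dev <- if (is.finite(trunc))
            rtruncnorm1(length(gi), if (length(wsd) > 1) wsd[[tn]] else wsd, trunc)
          else stats::rnorm(length(gi), 0, sd_g[[tn]])
          sh <- if (tn %in% names(mix$shift)) mix$shift[[tn]] else 0
          latent[gi, j] <- mu[[tn]] + dev +
            ifelse(gi %in% shifted, sh, 0)
        }
      } else {
        for (j in seq_along(TRAIT_NAMES))
          latent[gi, j] <- stats::rnorm(length(gi), mu[[TRAIT_NAMES[j]]],
                                        sd_g[[TRAIT_NAMES[j]]])
      }
    }
    ep_ids <- vapply(spec$episodes, `[[`, "", "episode_id")
    traits <- stats::setNames(vector("list", n), ids)
    for (i in seq_len(n)) {
      per_ep <- stats::setNames(vector("list", length(ep_ids)), ep_ids)
      for (e in ep_ids) {
        off <- rep(0, length(TRAIT_NAMES)); names(off) <- TRAIT_NAMES
        eo <- spec$episode_offsets[[e]]
        if (!is.null(eo)) off[names(eo)] <- eo
        jit <- stats::rnorm(length(TRAIT_NAMES), 0, spec$session_jitter_sd)
        l <- latent[i, ] + off + jit
        p_eyes <- stats::plogis(l[["p_eyes"]])
        per_ep[[e]] <- trait_vector(
          p_onscreen = stats::plogis(l[["p_onscreen"]]),
          p_face = stats::plogis(l[["p_face"]]),
          p_eyes = p_eyes,
          p_mouth = (1 - p_eyes) * stats::plogis(l[["q_mouth"]]),
          sigma_spatial_deg = spec$sigma_spatial_deg,
          center_bias = spec$center_bias,
          dwell_mean_s = spec$dwell_mean_s)
      }
      traits[[i]] <- per_ep
    }
    fam <- function() sample(1:9, n, replace = TRUE)
    meta <- participant_meta(data.frame(
      participant_id = ids, group = groups,
      site = sample(c("site1", "site2"), n, replace = TRUE, prob = c(1/3, 2/3)),
      planted = planted,
      familiarity_A = fam(), familiarity_B = fam(),
      severity_css = ifelse(groups == "ASD", sample(3:10, n, replace = TRUE),
                            NA_integer_),
      aq = round(ifelse(groups == "ASD", stats::rnorm(n, 28.1, 7.7),
                        stats::rnorm(n, 15.7, 6.4))),
      age_years = round(stats::runif(n, 18, 55)),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.73, 0.27)),
      fsiq = round(stats::rnorm(n, 110, 12))))
    list(traits = traits, latent = latent, meta = meta)
  })
}

#' Generate a synthetic shot-structured scene
#'
#' Shot durations are lognormal (median ~4 s); each shot contains 0-3
#' persons (at least one with probability `person_prob`). Every person gets
#' a face box, five facial keypoints placed deterministically inside the
#' face box (eyes at 40% of box height, nose at 55%, mouth corners at 72%),
#' a body box and up to two hand boxes.
#'
#' @param duration_s Episode duration in seconds (>= one frame).
#' @param frame_rate_fps Frame rate (default 24).
#' @param person_prob Probability a shot has >= 1 person.
#' @param screen A [screen_geometry()].
#' @param episode_id Identifier stored with the scene.
#' @param seed Optional seed.
#' @return An object of class `scene_spec`: shots (`start_frame`,
#'   `end_frame` half-open, 0-based), per-shot person annotations, frame
#'   count and geometry.
#' @export
generate_scene <- function(duration_s, frame_rate_fps = 24,
                           person_prob = 0.96, screen = screen_geometry(),
                           episode_id = "A", seed = NULL) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  n_frames <- floor(duration_s * frame_rate_fps + 1e-9)
  if (n_frames < 1L) stop_gp("duration shorter than one frame")
  with_seed_if(seed, {
    starts <- integer(); f <- 0L
    while (f < n_frames) {
      starts <- c(starts, f)
      len <- max(1L, round(stats::rlnorm(1, log(4), 0.6) * frame_rate_fps))
      f <- f + len
    }
    ends <- c(starts[-1], n_frames)
    shots <- vector("list", length(starts))
    for (s in seq_along(starts)) {
      n_persons <- if (stats::runif(1) < person_prob)
        sample(1:3, 1, prob = c(0.6, 0.3, 0.1)) else 0L
      persons <- vector("list", n_persons)
      for (p in seq_len(n_persons)) {
        # person geometry scales with the screen (faces ~11-24% of height)
        fh <- stats::runif(1, 0.11, 0.24) * screen$height_px
        fw <- 0.75 * fh
        fx0 <- stats::runif(1, 0.005 * screen$width_px,
                            screen$width_px - fw - 0.005 * screen$width_px)
        fy0 <- stats::runif(1, 0.028 * screen$height_px,
                            max(0.029 * screen$height_px,
                                screen$height_px * 0.45 - fh))
        face <- c(fx0, fy0, fx0 + fw, fy0 + fh)
        kp <- list(left_eye = c(fx0 + 0.32 * fw, fy0 + 0.40 * fh),
                   right_eye = c(fx0 + 0.68 * fw, fy0 + 0.40 * fh),
                   nose = c(fx0 + 0.50 * fw, fy0 + 0.55 * fh),
                   mouth_left = c(fx0 + 0.36 * fw, fy0 + 0.72 * fh),
                   mouth_right = c(fx0 + 0.64 * fw, fy0 + 0.72 * fh))
        bw <- 2.2 * fw
        bx0 <- max(0, fx0 + fw / 2 - bw / 2)
        by0 <- fy0 + fh * 0.9
        body <- c(bx0, by0, min(screen$width_px, bx0 + bw),
                  min(screen$height_px, by0 + 3.2 * fh))
        hands <- list()
        for (k in seq_len(sample(0:2, 1, prob = c(0.3, 0.4, 0.3)))) {
          hw <- 0.055 * screen$height_px
          hx0 <- min(max(0, bx0 + stats::runif(1, 0, max(1, bw - hw))),
                     screen$width_px - hw)
          hy0 <- min(by0 + stats::runif(1, 0.5, 2.5) * fh,
                     screen$height_px - hw)
          hands <- c(hands, list(c(hx0, hy0, hx0 + hw, hy0 + hw)))
        }
        persons[[p]] <- list(face_box = face, keypoints = kp,
                             hands = hands, body = list(body))
      }
      shots[[s]] <- persons
    }
    structure(list(episode_id = episode_id, duration_s = duration_s,
                   frame_rate_fps = frame_rate_fps, n_frames = n_frames,
                   shot_start = starts, shot_end = ends,
                   persons_by_shot = shots, screen = screen),
              class = "scene_spec")
  })
}

#' @export
print.scene_spec <- function(x, ...) {
  with_person <- scene_person_frame_fraction(x)
  cat(sprintf("<scene_spec> %s: %.0f s @ %g fps, %d shots, %.1f%% frames with a person\n",
              x$episode_id, x$duration_s, x$frame_rate_fps,
              length(x$shot_start), 100 * with_person))
  invisible(x)
}

#' Fraction of frames depicting at least one person
#' @param scene A `scene_spec`.
#' @return A fraction in `[0, 1]`.
#' @export
scene_person_frame_fraction <- function(scene) {
  lens <- scene$shot_end - scene$shot_start
  has <- vapply(scene$persons_by_shot, length, integer(1)) > 0
  sum(lens[has]) / scene$n_frames
}

shot_of_frame <- function(scene, frames) {
  findInterval(frames, scene$shot_start)
}

# Build (and cache on the scene) per-shot AOI maps.
scene_aoi_maps <- function(scene) {
  if (!is.null(attr(scene, "aoi_maps"))) return(attr(scene, "aoi_maps"))
  lapply(seq_along(scene$persons_by_shot), function(s)
    build_frame_aoi_map(list(frame = scene$shot_start[s],
                             persons = scene$persons_by_shot[[s]]),
                        scene$screen))
}

# Centroid of the target region for the dwell process.
target_anchor <- function(target, persons, aoi_map, screen) {
  centre <- function(b) c((b[["x0"]] + b[["x1"]]) / 2,
                          (b[["y0"]] + b[["y1"]]) / 2)
  pick <- function(boxes) centre(boxes[[sample.int(length(boxes), 1)]])
  switch(target,
    eyes = , mouth = , other_face = {
      faces <- aoi_map$faces
      f <- faces[[sample.int(length(faces), 1)]]
      if (target == "other_face") {
        # forehead: inside the face box but above the eyes region (the
        # face centre itself lies inside the eyes box)
        if (!box_is_empty(f$eyes))
          c((f$face[["x0"]] + f$face[["x1"]]) / 2,
            (f$face[["y0"]] + f$eyes[["y0"]]) / 2)
        else centre(f$face)
      } else {
        b <- switch(target, eyes = f$eyes, mouth = f$mouth)
        if (box_is_empty(b)) b <- f$face
        centre(b)
      }
    },
    hands = pick(aoi_map$hands),
    other_body = pick(aoi_map$body),
    non_social = {
      for (k in 1:30) {
        pt <- c(stats::runif(1, 0, screen$width_px),
                stats::runif(1, 0, screen$height_px))
        boxes <- c(lapply(aoi_map$faces, `[[`, "face"), aoi_map$hands,
                   aoi_map$body)
        if (!length(boxes) || !any(in_any_box(pt[1], pt[2], boxes)))
          return(pt)
      }
      pt
    })
}

#' Simulate one participant-episode gaze recording
#'
#' Implements the dwell process described in the module header. The target
#' categorical over AOIs is renormalized over the categories present in the
#' current shot (with absent-face probability redistributed to the other
#' coarse AOIs in the fixed non-face proportions); dwell lengths are
#' exponential, rounded to whole frames and capped at shot boundaries.
#'
#' @param traits A [trait_vector()].
#' @param scene A [generate_scene()] result.
#' @param config A [pipeline_config()] sharing the scene's frame rate.
#' @param participant_id Identifier for the output recording.
#' @param rate_hz Tracker sampling rate.
#' @param sample_noise_px SD of the per-sample coordinate noise.
#' @param seed Optional seed.
#' @return A [gaze_recording()].
#' @export
simulate_gaze <- function(traits, scene, config = pipeline_config(),
                          participant_id = "p01", rate_hz = 300,
                          sample_noise_px = 2, seed = NULL) {
  if (abs(scene$frame_rate_fps - config$frame_rate_fps) > 1e-9)
    stop_gp("scene and config disagree on the frame rate")
  if (!length(scene$shot_start)) stop_gp("scene has no shots")
  with_seed_if(seed, {
    fps <- scene$frame_rate_fps
    maps <- scene_aoi_maps(scene)
    screen <- scene$screen
    centre_pt <- c(screen$width_px / 2, screen$height_px / 2)
    sigma_px <- traits$sigma_spatial_deg * screen$px_per_degree
    n_frames <- scene$n_frames
    t_list <- list(); x_list <- list(); y_list <- list(); v_list <- list()
    f <- 0L
    while (f < n_frames) {
      shot <- shot_of_frame(scene, f)
      shot_end <- scene$shot_end[shot]
      n_dwell <- max(1L, round(stats::rexp(1, 1 / traits$dwell_mean_s) * fps))
      f_end <- min(f + n_dwell, shot_end, n_frames)
      t0 <- f / fps; t1 <- f_end / fps
      k <- seq.int(ceiling(t0 * rate_hz - 1e-9), ceiling(t1 * rate_hz - 1e-9) - 1L)
      ts <- k / rate_hz
      if (length(ts)) {
        if (stats::runif(1) >= traits$p_onscreen) {
          t_list <- c(t_list, list(ts))
          x_list <- c(x_list, list(rep(NA_real_, length(ts))))
          y_list <- c(y_list, list(rep(NA_real_, length(ts))))
          v_list <- c(v_list, list(rep(FALSE, length(ts))))
        } else {
          aoi_map <- maps[[shot]]
          has_face <- length(aoi_map$faces) > 0
          has_hands <- length(aoi_map$hands) > 0
          has_body <- length(aoi_map$body) > 0
          w <- c(face = if (has_face) traits$p_face else 0,
                 non_social = NONFACE_WEIGHTS[["non_social"]],
                 other_body = if (has_body) NONFACE_WEIGHTS[["other_body"]] else 0,
                 hands = if (has_hands) NONFACE_WEIGHTS[["hands"]] else 0)
          w[c("non_social", "other_body", "hands")] <-
            w[c("non_social", "other_body", "hands")] /
            sum(w[c("non_social", "other_body", "hands")]) *
            (1 - w[["face"]])
          target <- sample(names(w), 1, prob = w)
          if (target == "face") {
            u <- stats::runif(1)
            target <- if (u < traits$p_eyes) "eyes"
            else if (u < traits$p_eyes + traits$p_mouth) "mouth"
            else "other_face"
          }
          anchor <- target_anchor(target, scene$persons_by_shot[[shot]],
                                  aoi_map, screen)
          anchor <- (1 - traits$center_bias) * anchor +
            traits$center_bias * centre_pt
          anchor <- anchor + stats::rnorm(2, 0, sigma_px)
          t_list <- c(t_list, list(ts))
          x_list <- c(x_list, list(anchor[1] +
                                     stats::rnorm(length(ts), 0, sample_noise_px)))
          y_list <- c(y_list, list(anchor[2] +
                                     stats::rnorm(length(ts), 0, sample_noise_px)))
          v_list <- c(v_list, list(rep(TRUE, length(ts))))
        }
      }
      f <- f_end
    }
    gaze_recording(participant_id, scene$episode_id, rate_hz,
                   data.frame(t = unlist(t_list), x = unlist(x_list),
                              y = unlist(y_list), valid = unlist(v_list)))
  })
}

#' Simulate a full cohort in memory
#'
#' Generates one scene per episode and one gaze recording per participant
#' per episode, all deterministically from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param config A [pipeline_config()] (frame rate taken from the spec).
#' @return A list with `recordings` (named `participant.episode`), `scenes`
#'   (named by episode), `meta`, `traits`, `latent` and the `spec`.
#' @export
simulate_cohort <- function(spec, config = pipeline_config()) {
  config$frame_rate_fps <- spec$frame_rate_fps
  config$screen <- spec$screen
  scenes <- list()
  for (k in seq_along(spec$episodes)) {
    ep <- spec$episodes[[k]]
    scenes[[ep$episode_id]] <- generate_scene(
      ep$duration_s, spec$frame_rate_fps, spec$person_prob, spec$screen,
      ep$episode_id, seed = child_seed(spec$seed, k))
  }
  tr <- sample_cohort_traits(spec)
  recordings <- list()
  ids <- names(tr$traits)
  for (i in seq_along(ids)) {
    for (k in seq_along(spec$episodes)) {
      e <- spec$episodes[[k]]$episode_id
      rec <- simulate_gaze(tr$traits[[ids[i]]][[e]], scenes[[e]], config,
                           participant_id = ids[i], rate_hz = spec$rate_hz,
                           seed = child_seed(spec$seed, 1000L + i * 10L + k))
      recordings[[paste(ids[i], e, sep = ".")]] <- rec
    }
  }
  list(recordings = recordings, scenes = scenes, meta = tr$meta,
       traits = tr$traits, latent = tr$latent, spec = spec, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Writes the gaze table (TSV), one annotation JSON-Lines file per episode,
#' and the participant metadata CSV; logs the realized group means of the
#' face trait. Output is byte-identical for a fixed spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The in-memory cohort, invisibly.
#' @export
make_cohort <- function(spec, config = pipeline_config(), out_dir) {
  cohort <- simulate_cohort(spec, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gaze_table(cohort$recordings, file.path(out_dir, "gaze.tsv"))
  for (e in names(cohort$scenes))
    write_annotations(cohort$scenes[[e]],
                      file.path(out_dir, sprintf("annotations_%s.jsonl", e)))
  utils::write.csv(cohort$meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  for (g in c("TD", "ASD")) {
    ids <- cohort$meta$participant_id[cohort$meta$group == g]
    pf <- vapply(ids, function(id)
      cohort$traits[[id]][[1]]$p_face, numeric(1))
    gp_log("realized %s p_face: mean %.3f sd %.3f", g, mean(pf), stats::sd(pf))
  }
  invisible(cohort)
}

#' Write per-frame annotations as JSON Lines
#'
#' One JSON object per frame: `{"frame": f, "persons": [{"face_box":
#' [x0,y0,x1,y1], "keypoints": {...}, "hands": [...], "body": [...]}]}`.
#'
#' @param scene A `scene_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(scene, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in seq_along(scene$shot_start)) {
    persons <- scene$persons_by_shot[[s]]
    body <- jsonlite::toJSON(list(persons = persons), auto_unbox = FALSE,
                             digits = NA)
    for (f in scene$shot_start[s]:(scene$shot_end[s] - 1L))
      writeLines(sprintf("{\"frame\":%d,%s", f, substring(body, 2L)), con)
  }
  invisible(path)
}

#' Read per-frame annotations from JSON Lines
#'
#' Consecutive frames with identical person sets are merged back into
#' shots, reconstructing a `scene_spec` (without generator metadata).
#'
#' @param path Annotation file.
#' @param frame_rate_fps,screen Geometry of the source video.
#' @param episode_id Identifier for the scene.
#' @return A `scene_spec`.
#' @export
read_annotations <- function(path, frame_rate_fps = 24,
                             screen = screen_geometry(), episode_id = "A") {
  lines <- readLines(path)
  if (!length(lines)) stop_gp("annotation file %s is empty", path)
  frames <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  ord <- order(vapply(frames, function(f) as.integer(f$frame), integer(1)))
  frames <- frames[ord]
  starts <- integer(); persons_by_shot <- list(); prev <- NULL
  for (f in frames) {
    if (is.null(prev) || !identical(prev, f$persons)) {
      starts <- c(starts, as.integer(f$frame))
      persons_by_shot <- c(persons_by_shot, list(f$persons))
      prev <- f$persons
    }
  }
  n_frames <- length(frames)
  structure(list(episode_id = episode_id,
                 duration_s = n_frames / frame_rate_fps,
                 frame_rate_fps = frame_rate_fps, n_frames = n_frames,
                 shot_start = starts,
                 shot_end = c(starts[-1], n_frames),
                 persons_by_shot = persons_by_shot, screen = screen),
            class = "scene_spec")
}

#' Deterministic expected feature vector implied by a trait vector
#'
#' Maps effective traits to the gaze feature values they imply on a scene
#' where every frame shows at least one face: the large-sample limit of the
#' coding pipeline with no spatial leakage. Used for feature-level
#' calibration checks of the resampling statistics, where gaze-simulation
#' noise would only blur the property under test.
#'
#' @param tv A [trait_vector()].
#' @return Named numeric vector over the eight gaze features (the heatmap
#'   correlation slot is a monotone proxy of the face preference).
#' @export
trait_expected_features <- function(tv) {
  nf <- (1 - tv$p_face) * NONFACE_WEIGHTS / sum(NONFACE_WEIGHTS)
  c(pct_onscreen = 100 * tv$p_onscreen,
    pct_face = 100 * tv$p_face,
    pct_nonsocial = 100 * nf[["non_social"]],
    pct_body = 100 * nf[["other_body"]],
    pct_hands = 100 * nf[["hands"]],
    pct_eyes = 100 * tv$p_face * tv$p_eyes,
    pct_mouth = 100 * tv$p_face * tv$p_mouth,
    mean_heatmap_corr = 0.3 + 0.5 * tv$p_face)
}
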