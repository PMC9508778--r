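test_that("scene generation honours person probability and determinism", {
  sc_all <- generate_scene(10, 24, person_prob = 1, seed = 1)
  expect_equal(scene_person_frame_fraction(sc_all), 1)
  sc_a <- generate_scene(30, 24, person_prob = 0.96, seed = 2)
  sc_b <- generate_scene(30, 24, person_prob = 0.96, seed = 2)
  expect_identical(sc_a, sc_b)
  # fraction of frames with a person near the target on a longer episode
  fr <- scene_person_frame_fraction(generate_scene(600, 24,
                                                   person_prob = 0.96,
                                                   seed = 3))
  expect_lt(abs(fr - 0.96), 0.02)
  expect_error(generate_scene(0.01, 24), "shorter than one frame")
  # keypoints sit inside the face box at the stated heights
  p <- sc_all$persons_by_shot[[1]][[1]]
  fb <- p$face_box
  expect_equal(p$keypoints$left_eye[2], fb[2] + 0.40 * (fb[4] - fb[2]))
  expect_equal(p$keypoints$nose[2], fb[2] + 0.55 * (fb[4] - fb[2]))
  expect_equal(p$keypoints$mouth_left[2], fb[2] + 0.72 * (fb[4] - fb[2]))
})

test_that("trait sampling: jitter and heterogeneity are separate knobs", {
  # zero session jitter: both episodes share the participant's traits
  spec0 <- cohort_spec(n_asd = 3, n_td = 3, session_jitter_sd = 0, seed = 5)
  tr0 <- sample_cohort_traits(spec0)
  for (id in names(tr0$traits))
    expect_equal(tr0$traits[[id]]$A$p_onscreen,
                 tr0$traits[[id]]$B$p_onscreen)
  # zero between-participant SD: all same-group participants share traits
  sds <- default_trait_sds()
  sds$TD[] <- 0; sds$ASD[] <- 0
  spec1 <- cohort_spec(n_asd = 3, n_td = 3, trait_sds = sds,
                       session_jitter_sd = 0, seed = 6)
  tr1 <- sample_cohort_traits(spec1)
  td_ids <- tr1$meta$participant_id[tr1$meta$group == "TD"]
  pf <- vapply(td_ids, function(id) tr1$traits[[id]]$A$p_face, numeric(1))
  expect_equal(max(pf) - min(pf), 0)
  expect_error(cohort_spec(n_asd = 3, n_td = 3, session_jitter_sd = -1),
               ">= 0")
})

test_that("realized trait means track the group calibration target", {
  spec <- cohort_spec(n_asd = 2, n_td = 200, session_jitter_sd = 0,
                      seed = 8)
  tr <- sample_cohort_traits(spec)
  td_ids <- tr$meta$participant_id[tr$meta$group == "TD"]
  pf <- vapply(td_ids, function(id) tr$traits[[id]]$A$p_face, numeric(1))
  expect_gt(mean(pf), 0.79)
  expect_lt(mean(pf), 0.82)
  # TD face trait mean exceeds ASD's by construction of the defaults
  spec2 <- cohort_spec(n_asd = 100, n_td = 100, session_jitter_sd = 0,
                       seed = 9)
  tr2 <- sample_cohort_traits(spec2)
  g <- tr2$meta$group
  pf2 <- vapply(tr2$meta$participant_id,
                function(id) tr2$traits[[id]]$A$p_face, numeric(1))
  expect_gt(mean(pf2[g == "TD"]), mean(pf2[g == "ASD"]))
})

test_that("a forced trait chain codes every on-screen frame to the eyes", {
  cfg <- tiny_config()
  scene <- single_person_scene(duration_s = 10)
  tv <- trait_vector(p_onscreen = 1, p_face = 1, p_eyes = 1, p_mouth = 0,
                     sigma_spatial_deg = 0, center_bias = 0)
  rec <- simulate_gaze(tv, scene, cfg, sample_noise_px = 0.5, seed = 3)
  fg <- downsample_to_frames(rec, 24, scene$n_frames, cfg$screen)
  expect_true(all(fg$status == "on_screen"))
  amap <- gazepheno:::scene_aoi_maps(scene)[[1]]
  res <- gazepheno:::assign_disks_batch(fg$x, fg$y, amap, cfg)
  expect_true(all(res$coarse == "face"))
  expect_true(all(res$fine == "eyes"))
})

test_that("p_onscreen = 0 produces a fully missing recording that gets excluded", {
  cfg <- tiny_config()
  scene <- single_person_scene(duration_s = 5)
  tv <- trait_vector(p_onscreen = 0, p_face = 1, p_eyes = 1, p_mouth = 0)
  rec <- simulate_gaze(tv, scene, cfg, seed = 4)
  fg <- downsample_to_frames(rec, 24, scene$n_frames, cfg$screen)
  expect_true(all(fg$status != "on_screen"))
  s <- data.frame(participant_id = "p", episode_id = c("A", "B"),
                  frac_missing = c(mean(fg$status != "on_screen"), 0))
  expect_true("p" %in% apply_exclusion_criteria(s)$excluded$participant_id)
})

test_that("realized AOI fractions converge to the trait probabilities", {
  # generator honesty: faces always present, no scatter, ample duration
  cfg <- tiny_config()
  scene <- generate_scene(600, 24, person_prob = 1, seed = 12)
  tv <- trait_vector(p_onscreen = 1, p_face = 0.8, p_eyes = 0.6,
                     p_mouth = 0.25, sigma_spatial_deg = 0, center_bias = 0)
  rec <- simulate_gaze(tv, scene, cfg, sample_noise_px = 0.5, seed = 13)
  fg <- downsample_to_frames(rec, 24, scene$n_frames, cfg$screen)
  on <- fg$status == "on_screen"
  maps <- gazepheno:::scene_aoi_maps(scene)
  shots <- gazepheno:::shot_of_frame(scene, fg$frame[on])
  coarse <- character(sum(on)); fine <- character(sum(on))
  for (s in unique(shots)) {
    sel <- shots == s
    res <- gazepheno:::assign_disks_batch(fg$x[on][sel], fg$y[on][sel],
                                          maps[[s]], cfg,
                                          raster = rasterize_aoi_map(maps[[s]]))
    coarse[sel] <- as.character(res$coarse)
    fine[sel] <- as.character(res$fine)
  }
  pct_face <- 100 * mean(coarse == "face")
  pct_eyes <- 100 * sum(fine == "eyes", na.rm = TRUE) / length(fine)
  expect_lt(abs(pct_face - 80), 2)
  expect_lt(abs(pct_eyes - 48), 2)
})

test_that("cohorts write deterministically with the expected file inventory", {
  cfg <- tiny_config()
  spec <- cohort_spec(n_asd = 2, n_td = 2,
                      episodes = list(list(episode_id = "A", duration_s = 8),
                                      list(episode_id = "B", duration_s = 8)),
                      seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co <- make_cohort(spec, cfg, d1)
  expect_length(co$recordings, 8L)   # 4 participants x 2 episodes
  expect_setequal(list.files(d1), c("gaze.tsv", "annotations_A.jsonl",
                                    "annotations_B.jsonl", "metadata.csv"))
  make_cohort(spec, cfg, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # annotations round-trip to an equivalent scene structure
  sc <- read_annotations(file.path(d1, "annotations_A.jsonl"),
                         frame_rate_fps = 24, episode_id = "A")
  expect_equal(sc$n_frames, co$scenes$A$n_frames)
  expect_equal(length(sc$shot_start), length(co$scenes$A$shot_start))
  r1 <- rasterize_aoi_map(gazepheno:::scene_aoi_maps(sc)[[1]])
  r2 <- rasterize_aoi_map(gazepheno:::scene_aoi_maps(co$scenes$A)[[1]])
  expect_equal(r1, r2)
})

test_that("trait-implied feature vectors respect composition identities", {
  tv <- trait_vector(0.9, 0.8, 0.6, 0.25)
  fv <- trait_expected_features(tv)
  expect_equal(fv[["pct_eyes"]], 100 * 0.8 * 0.6)
  expect_equal(fv[["pct_face"]] + fv[["pct_nonsocial"]] + fv[["pct_body"]] +
                 fv[["pct_hands"]], 100)
  expect_error(trait_vector(0.9, 0.8, 0.7, 0.4), "exceed")
})
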