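test_that("downsampling averages valid samples per frame with the half-open span", {
  scr <- screen_geometry()
  rec <- gaze_recording("p", "A", 300, data.frame(
    t = c(0.001, 0.020, 0.043, 0.045, 0.085),
    x = c(10, 20, 7, 7, 5000), y = c(100, 100, 7, 7, 100),
    valid = c(TRUE, TRUE, FALSE, FALSE, TRUE)))
  fg <- downsample_to_frames(rec, 24, 3, scr)
  expect_equal(fg$x[1], 15)                      # mean of two valid samples
  expect_equal(as.character(fg$status[2]), "missing")   # all invalid
  expect_equal(as.character(fg$status[3]), "off_screen") # mean outside bounds
  expect_error(downsample_to_frames(rec, 24, 0, scr), "> 0")
  expect_error(downsample_to_frames(
    gaze_recording("p", "A", 20, data.frame(t = 0, x = 1, y = 1,
                                            valid = TRUE)), 24, 2, scr),
    "exceed")
})

test_that("300 Hz and 120 Hz samplings of a per-frame-constant signal reduce identically", {
  fps <- 24
  n_frames <- 20
  # trajectory constant within each frame
  frame_vals_x <- runif(n_frames, 0, 1900)
  frame_vals_y <- runif(n_frames, 0, 1000)
  mk <- function(rate) {
    t <- seq(0, n_frames / fps - 1e-9, by = 1 / rate)
    f <- floor(t * fps + 1e-9) + 1
    gaze_recording("p", "A", rate,
                   data.frame(t = t, x = frame_vals_x[f], y = frame_vals_y[f],
                              valid = TRUE))
  }
  f300 <- downsample_to_frames(mk(300), fps, n_frames)
  f120 <- downsample_to_frames(mk(120), fps, n_frames)
  expect_equal(f300$x, f120$x, tolerance = 1e-9)
  expect_equal(f300$y, f120$y, tolerance = 1e-9)
})

test_that("disk-overlap assignment follows the maximum-overlap rule", {
  cfg <- pipeline_config()
  scene <- single_person_scene()
  amap <- gazepheno:::scene_aoi_maps(scene)[[1]]
  mk_fg <- function(x, y) data.frame(frame = 0L, x = x, y = y, n_valid = 10L,
                                     status = factor("on_screen",
                                                     levels = c("on_screen",
                                                                "off_screen",
                                                                "missing")))
  # centre of the face but below the mouth region -> (face, other_face)
  a1 <- assign_frame_aoi(mk_fg(950, 580), amap, cfg)
  expect_equal(a1$coarse, "face")
  expect_equal(a1$fine, "other_face")
  # straddling the eyes/mouth split with more overlap on the eyes side
  em <- derive_eyes_mouth_regions(
    box(800, 200, 1100, 600),
    do.call(facial_keypoints, scene$persons_by_shot[[1]][[1]]$keypoints))
  split_y <- em$eyes[["y1"]]
  a2 <- assign_frame_aoi(mk_fg(950, split_y - 5), amap, cfg)
  expect_equal(a2$fine, "eyes")
  expect_gt(a2$overlap[["eyes"]], a2$overlap[["mouth"]])
  # person-free area -> non-social
  a3 <- assign_frame_aoi(mk_fg(300, 150), amap, cfg)
  expect_equal(a3$coarse, "non_social")
  expect_equal(a3$fine, NA_character_)
  # contract violation on a missing frame
  fg_bad <- mk_fg(100, 100); fg_bad$status[1] <- "missing"
  expect_error(assign_frame_aoi(fg_bad, amap, cfg), "status")
})

test_that("fast assignment equals brute-force pixel enumeration exactly", {
  cfg <- pipeline_config()
  set.seed(11)
  scenes <- lapply(1:3, function(k)
    generate_scene(4, 24, person_prob = 1, seed = 30 + k))
  for (sc in scenes) {
    amap <- gazepheno:::scene_aoi_maps(sc)[[1]]
    raster <- rasterize_aoi_map(amap)
    cx <- runif(25, 30, 1890); cy <- runif(25, 30, 1050)
    fast <- gazepheno:::assign_disks_batch(cx, cy, amap, cfg, raster = raster)
    for (i in seq_along(cx)) {
      oracle <- oracle_disk_assignment(cx[i], cy[i], amap, cfg)
      expect_identical(as.character(fast$coarse[i]), oracle$coarse)
      if (oracle$coarse == "face")
        expect_identical(as.character(fast$fine[i]), oracle$fine)
      # exact overlap areas, not just labels
      expect_equal(unname(fast$overlap[i, c("eyes", "mouth", "other_face",
                                            "hands", "other_body",
                                            "non_social")]),
                   unname(oracle$counts[c("eyes", "mouth", "other_face",
                                          "hands", "other_body",
                                          "non_social")]))
    }
  }
})

test_that("feature fractions use on-screen frames as the AOI denominator", {
  coarse <- factor(c(rep("face", 60), rep("non_social", 15),
                     rep("hands", 5)),
                   levels = c("face", "hands", "other_body", "non_social"))
  fine <- factor(c(rep("eyes", 40), rep("mouth", 10), rep("other_face", 10),
                   rep(NA, 20)), levels = c("eyes", "mouth", "other_face"))
  v <- compute_feature_fractions(coarse, fine, n_frames_total = 100)
  expect_equal(v[["pct_onscreen"]], 80)
  expect_equal(v[["pct_face"]], 75)
  expect_equal(v[["pct_eyes"]], 50)
  expect_equal(v[["pct_face"]] + v[["pct_hands"]] + v[["pct_body"]] +
                 v[["pct_nonsocial"]], 100, tolerance = 1e-9)

  all_eyes <- compute_feature_fractions(
    factor(rep("face", 10), levels = levels(coarse)),
    factor(rep("eyes", 10), levels = levels(fine)), 10)
  expect_equal(all_eyes[["pct_face"]], 100)
  expect_equal(all_eyes[["pct_eyes"]], 100)

  none <- compute_feature_fractions(coarse[0], fine[0], 10)
  expect_true(isTRUE(attr(none, "flagged_missing")))
  expect_true(is.na(none[["pct_face"]]))
})

test_that("exclusion rule is strict at the 50% boundary and needs both episodes", {
  s <- data.frame(
    participant_id = c("a", "a", "b", "b", "c", "c", "d"),
    episode_id = c("A", "B", "A", "B", "A", "B", "A"),
    frac_missing = c(0.55, 0.10, 0.45, 0.45, 0.50, 0.50, 0.10))
  res <- apply_exclusion_criteria(s, threshold = 0.5)
  expect_setequal(res$kept, c("b", "c"))   # exactly 50% is kept
  expect_true("a" %in% res$excluded$participant_id)
  expect_match(res$excluded$reason[res$excluded$participant_id == "d"],
               "incomplete")
})
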