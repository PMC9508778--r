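test_that("eyes/mouth construction reproduces the hand-built example", {
  fb <- box(0, 0, 100, 100)
  kp <- facial_keypoints(c(30, 40), c(70, 40), c(50, 55),
                         c(35, 70), c(65, 70))
  em <- derive_eyes_mouth_regions(fb, kp)
  expect_equal(unclass(em$small), c(x0 = 30, y0 = 40, x1 = 70, y1 = 70))
  expect_equal(unclass(em$medium), c(x0 = 15, y0 = 20, x1 = 85, y1 = 85))
  expect_equal(unclass(em$eyes), c(x0 = 15, y0 = 20, x1 = 85, y1 = 55))
  expect_equal(unclass(em$mouth), c(x0 = 15, y0 = 55, x1 = 85, y1 = 85))
})

test_that("eyes/mouth construction handles degenerate keypoints and is equivariant", {
  fb <- box(0, 0, 100, 100)
  # coincident keypoints: small box degenerate, medium box still well formed
  kp0 <- facial_keypoints(c(50, 50), c(50, 50), c(50, 50),
                          c(50, 50), c(50, 50))
  em0 <- derive_eyes_mouth_regions(fb, kp0)
  expect_equal(unclass(em0$medium), c(x0 = 25, y0 = 25, x1 = 75, y1 = 75))
  expect_equal(em0$eyes[["y1"]], 50)   # split at nose y
  expect_equal(em0$mouth[["y0"]], 50)

  # translation equivariance
  kp <- facial_keypoints(c(30, 40), c(70, 40), c(50, 55),
                         c(35, 70), c(65, 70))
  em <- derive_eyes_mouth_regions(fb, kp)
  shift <- function(p) p + c(10, 10)
  em_t <- derive_eyes_mouth_regions(
    box(10, 10, 110, 110),
    facial_keypoints(shift(c(30, 40)), shift(c(70, 40)), shift(c(50, 55)),
                     shift(c(35, 70)), shift(c(65, 70))))
  expect_equal(unclass(em_t$eyes), unclass(em$eyes) + 10)
  expect_equal(unclass(em_t$mouth), unclass(em$mouth) + 10)

  # uniform scaling equivariance
  em_s <- derive_eyes_mouth_regions(
    box(0, 0, 200, 200),
    facial_keypoints(c(60, 80), c(140, 80), c(100, 110),
                     c(70, 140), c(130, 140)))
  expect_equal(unclass(em_s$eyes), unclass(em$eyes) * 2)
  expect_equal(unclass(em_s$mouth), unclass(em$mouth) * 2)

  # nose on the medium-box boundary (lowest keypoint at the face-box
  # bottom) -> degenerate split, empty sub-regions
  kp_bad <- facial_keypoints(c(30, 40), c(70, 40), c(50, 100),
                             c(35, 70), c(65, 70))
  em_bad <- derive_eyes_mouth_regions(fb, kp_bad)
  expect_true(isTRUE(attr(em_bad$eyes, "degenerate")))
})

test_that("body-part merging maps categories and unions boxes", {
  # hands only
  det <- data.frame(category = c("hand_left", "hand_right"),
                    x0 = c(0, 50), y0 = c(0, 0), x1 = c(10, 60),
                    y1 = c(10, 10))
  m <- merge_body_parts(det)
  expect_length(m$hands, 2L)
  expect_length(m$face, 0L)
  expect_length(m$other_body, 0L)

  # overlapping persons' body boxes: union at rasterization
  det2 <- data.frame(category = c("body", "body"),
                     x0 = c(0, 5), y0 = c(0, 0), x1 = c(10, 15), y1 = c(10, 10))
  m2 <- merge_body_parts(det2)
  scr <- screen_geometry(20, 10, 40)
  amap <- build_frame_aoi_map(list(frame = 0, persons = list(
    list(body = m2$other_body))), scr)
  r <- rasterize_aoi_map(amap)
  expect_equal(sum(r == 2), 150)  # union of [0,10)x[0,10) and [5,15)x[0,10)

  # the 24-part taxonomy covers exactly three groups
  det24 <- data.frame(category = as.character(1:24), x0 = 0, y0 = 0,
                      x1 = 5, y1 = 5)
  m24 <- merge_body_parts(det24)
  expect_length(m24$face, 2L)        # two head parts
  expect_length(m24$hands, 2L)       # two hand parts
  expect_length(m24$other_body, 20L)

  expect_error(merge_body_parts(data.frame(category = "antenna", x0 = 0,
                                           y0 = 0, x1 = 1, y1 = 1)),
               "antenna")
})

test_that("frame AOI maps partition the screen with stated precedence", {
  scr <- screen_geometry(120, 80, 40)
  # no persons -> everything non-social
  empty <- build_frame_aoi_map(list(frame = 0, persons = list()), scr)
  expect_equal(sum(rasterize_aoi_map(empty) == 1), 120 * 80)

  # face over body where they overlap
  amap <- build_frame_aoi_map(list(frame = 0, persons = list(list(
    face_box = c(10, 10, 50, 50), body = list(c(30, 30, 100, 70))))), scr)
  r <- rasterize_aoi_map(amap)
  expect_equal(r[41, 41], 4L)  # pixel (40.5, 40.5): face wins over body

  # partition: coarse areas sum exactly to screen area on random frames
  set.seed(7)
  for (k in 1:5) {
    sc <- generate_scene(4, 24, person_prob = 1, screen = scr, seed = k)
    am <- gazepheno:::scene_aoi_maps(sc)[[1]]
    rr <- rasterize_aoi_map(am)
    expect_equal(length(rr), 120 * 80)
    expect_true(all(rr %in% 1:6))
  }
})

test_that("rasterized maps agree with point-wise labeling (oracle)", {
  set.seed(21)
  scr <- screen_geometry(320, 240, 40)
  sc <- generate_scene(4, 24, person_prob = 1, screen = scr, seed = 5)
  am <- gazepheno:::scene_aoi_maps(sc)[[1]]
  r <- rasterize_aoi_map(am)
  px <- runif(500, 0, 320); py <- runif(500, 0, 240)
  lab_pt <- gazepheno:::label_points(floor(px) + 0.5, floor(py) + 0.5, am)
  lab_raster <- r[cbind(floor(py) + 1L, floor(px) + 1L)]
  expect_equal(unname(lab_pt), unname(lab_raster))
})

test_that("eyes and mouth are disjoint and contained in the medium box", {
  set.seed(3)
  for (k in 1:10) {
    x0 <- runif(1, 0, 400); y0 <- runif(1, 0, 300)
    w <- runif(1, 60, 200); h <- runif(1, 80, 240)
    fb <- box(x0, y0, x0 + w, y0 + h)
    kp <- facial_keypoints(
      c(x0 + 0.3 * w, y0 + 0.4 * h), c(x0 + 0.7 * w, y0 + 0.4 * h),
      c(x0 + 0.5 * w, y0 + 0.55 * h),
      c(x0 + 0.35 * w, y0 + 0.7 * h), c(x0 + 0.65 * w, y0 + 0.7 * h))
    em <- derive_eyes_mouth_regions(fb, kp)
    expect_equal(em$eyes[["y1"]], em$mouth[["y0"]])  # split line, disjoint
    expect_true(em$eyes[["y0"]] >= em$medium[["y0"]])
    expect_true(em$mouth[["y1"]] <= em$medium[["y1"]])
    expect_true(em$eyes[["x0"]] == em$medium[["x0"]] &&
                  em$eyes[["x1"]] == em$medium[["x1"]])
  }
})
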