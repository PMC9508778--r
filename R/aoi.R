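# Per-frame area-of-interest (AOI) construction from detector outputs.
#
# AOIs are organised at two levels. Coarse: face (head), hands, other body,
# non-social (the complement of every detected person region). Fine, within
# a face: eyes, mouth, other-face. Where coarse regions overlap, the
# precedence is face > hands > other body; the socially informative and
# typically smaller region wins. All area computations are rasterized on the
# 1-pixel grid with the pixel-centre rule, so box-set and mask inputs agree.

AOI_CODES <- c(non_social = 1L, other_body = 2L, hands = 3L,
               other_face = 4L, eyes = 5L, mouth = 6L)
COARSE_LEVELS <- c("face", "hands", "other_body", "non_social")
FINE_LEVELS <- c("eyes", "mouth", "other_face")

#' Facial keypoints
#'
#' The five facial keypoints produced by standard face detectors: the two
#' eyes, the nose and the two corners of the mouth, each as an (x, y) pixel
#' location. For a well-formed face the nose lies vertically strictly
#' between the highest and lowest keypoints.
#'
#' @param left_eye,right_eye,nose,mouth_left,mouth_right Numeric length-2
#'   vectors `(x, y)`.
#' @return An object of class `facial_keypoints`.
#' @export
facial_keypoints <- function(left_eye, right_eye, nose, mouth_left,
                             mouth_right) {
  kp <- list(left_eye = left_eye, right_eye = right_eye, nose = nose,
             mouth_left = mouth_left, mouth_right = mouth_right)
  for (nm in names(kp)) {
    p <- as.numeric(kp[[nm]])
    if (length(p) != 2L || any(!is.finite(p)))
      stop_gp("keypoint '%s' must be a finite (x, y) pair", nm)
    kp[[nm]] <- p
  }
  structure(kp, class = "facial_keypoints")
}

#' Derive eyes and mouth boxes from a face box and five keypoints
#'
#' Constructs the two facial sub-regions in three steps: (i) the smallest
#' bounding box enclosing the five keypoints; (ii) a medium box whose
#' corners are the midpoints between the corresponding corners of the small
#' box and of the (larger) detector face box; (iii) the medium box is split
#' by the horizontal line through the nose keypoint, the upper part (smaller
#' y) becoming the eyes region and the lower part the mouth region. The
#' split row at the nose y itself belongs to the mouth (half-open
#' convention). The construction is equivariant under translation and
#' uniform scaling of its inputs.
#'
#' @param face_box An [box()] for the whole face (from the face detector).
#' @param kp A [facial_keypoints()] whose points lie inside `face_box`.
#' @return A list with elements `eyes` and `mouth` (each an [box()], empty
#'   boxes with a `degenerate` attribute when the nose falls outside the
#'   medium box) and `medium`, `small` for inspection.
#' @examples
#' fb <- box(0, 0, 100, 100)
#' kp <- facial_keypoints(c(30, 40), c(70, 40), c(50, 55), c(35, 70), c(65, 70))
#' derive_eyes_mouth_regions(fb, kp)
#' @export
derive_eyes_mouth_regions <- function(face_box, kp) {
  stopifnot(inherits(kp, "facial_keypoints"))
  pts <- do.call(rbind, unclass(kp))
  inside <- pts[, 1] >= face_box[["x0"]] & pts[, 1] <= face_box[["x1"]] &
    pts[, 2] >= face_box[["y0"]] & pts[, 2] <= face_box[["y1"]]
  if (!all(inside)) stop_gp("keypoints must lie inside the face box")
  small <- box(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]),
               allow_empty = TRUE)
  medium <- box((small[["x0"]] + face_box[["x0"]]) / 2,
                (small[["y0"]] + face_box[["y0"]]) / 2,
                (small[["x1"]] + face_box[["x1"]]) / 2,
                (small[["y1"]] + face_box[["y1"]]) / 2)
  ny <- kp$nose[2]
  if (ny <= medium[["y0"]] || ny >= medium[["y1"]]) {
    gp_log("nose keypoint outside medium box; face coded with empty eyes/mouth",
           level = "WARN")
    empty <- box(0, 0, 0, 0, allow_empty = TRUE)
    attr(empty, "degenerate") <- TRUE
    return(list(eyes = empty, mouth = empty, medium = medium, small = small))
  }
  list(eyes = box(medium[["x0"]], medium[["y0"]], medium[["x1"]], ny),
       mouth = box(medium[["x0"]], ny, medium[["x1"]], medium[["y1"]]),
       medium = medium, small = small)
}

# DensePose-style 24-part taxonomy -> three coarse body groups.
densepose_part_groups <- function() {
  g <- rep("other_body", 24L)
  g[c(3L, 4L)] <- "hands"   # right hand, left hand
  g[c(23L, 24L)] <- "face"  # head (left, right)
  names(g) <- as.character(1:24)
  g
}

#' Merge labelled body-part detections into three coarse groups
#'
#' Maps per-detection part categories onto the three coarse person regions
#' (head/face, hands, other body) and takes the union of boxes within each
#' group. Accepts either textual categories (`"face"`/`"head"`, `"hands"`/
#' `"hand_left"`/`"hand_right"`, `"body"`/any other-body synonym already in
#' the three-group scheme) or integer ids from the 24-part dense-pose
#' taxonomy (ids 23-24 are the head, 3-4 the hands, all else other body).
#'
#' @param detections A data.frame with columns `category`, `x0`, `y0`, `x1`,
#'   `y1` (one row per detection box).
#' @return A list of box lists: `face`, `hands`, `other_body`.
#' @export
merge_body_parts <- function(detections) {
  stopifnot(is.data.frame(detections),
            all(c("category", "x0", "y0", "x1", "y1") %in% names(detections)))
  out <- list(face = list(), hands = list(), other_body = list())
  if (!nrow(detections)) return(out)
  cat_raw <- as.character(detections$category)
  dp <- densepose_part_groups()
  text_map <- c(face = "face", head = "face",
                hands = "hands", hand = "hands",
                hand_left = "hands", hand_right = "hands",
                body = "other_body", other_body = "other_body",
                torso = "other_body", legs = "other_body", arms = "other_body",
                feet = "other_body")
  grp <- character(length(cat_raw))
  for (i in seq_along(cat_raw)) {
    key <- tolower(cat_raw[i])
    if (key %in% names(text_map)) grp[i] <- text_map[[key]]
    else if (key %in% names(dp)) grp[i] <- dp[[key]]
    else stop_gp("unknown body-part category: '%s'", cat_raw[i])
  }
  for (i in seq_along(grp)) {
    b <- box(detections$x0[i], detections$y0[i],
             detections$x1[i], detections$y1[i])
    out[[grp[i]]] <- c(out[[grp[i]]], list(b))
  }
  out
}

#' Build the labelled AOI map for one frame
#'
#' Combines a frame annotation (persons with face boxes, facial keypoints,
#' hand boxes and body boxes) into the frame's AOI map. Face boxes carve
#' eyes/mouth/other-face sub-regions via [derive_eyes_mouth_regions()];
#' overlap precedence is face over hands over other body, and everything
#' outside detected person regions is non-social content. Annotation boxes
#' reaching beyond the screen are clipped with a logged warning.
#'
#' @param frame_annotation A list with elements `frame` (index) and
#'   `persons`, each person a list with optional `face_box` (x0,y0,x1,y1),
#'   `keypoints` (named list of 5 points), `hands` (list of boxes), `body`
#'   (list of boxes).
#' @param screen A [screen_geometry()].
#' @return An object of class `frame_aoi_map` holding per-label box sets.
#' @export
build_frame_aoi_map <- function(frame_annotation, screen = screen_geometry()) {
  persons <- frame_annotation$persons %||% list()
  faces <- list(); hands <- list(); body <- list()
  clipped <- FALSE
  as_box <- function(v) {
    b <- box(v[[1]], v[[2]], v[[3]], v[[4]])
    cb <- clip_box(b, screen)
    if (!isTRUE(all.equal(unclass(b), unclass(cb)))) clipped <<- TRUE
    cb
  }
  for (p in persons) {
    if (!is.null(p$face_box)) {
      fb <- as_box(p$face_box)
      eyes <- mouth <- box(0, 0, 0, 0, allow_empty = TRUE)
      if (!is.null(p$keypoints) && !box_is_empty(fb)) {
        kp <- do.call(facial_keypoints, lapply(
          p$keypoints[c("left_eye", "right_eye", "nose",
                        "mouth_left", "mouth_right")], as.numeric))
        em <- tryCatch(derive_eyes_mouth_regions(fb, kp),
                       error = function(e) NULL)
        if (!is.null(em)) {
          eyes <- clip_box(em$eyes, screen)
          mouth <- clip_box(em$mouth, screen)
        }
      }
      faces <- c(faces, list(list(face = fb, eyes = eyes, mouth = mouth)))
    }
    for (hb in p$hands %||% list()) hands <- c(hands, list(as_box(hb)))
    for (bb in p$body %||% list()) body <- c(body, list(as_box(bb)))
  }
  if (clipped) gp_log("frame %s: annotation boxes clipped to screen",
                      frame_annotation$frame %||% "?", level = "WARN")
  structure(list(frame = frame_annotation$frame %||% NA_integer_,
                 faces = faces, hands = hands, body = body, screen = screen),
            class = "frame_aoi_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label points (pixel centres) against a frame AOI map with the stated
# precedence. Returns integer codes from AOI_CODES.
label_points <- function(px, py, aoi_map) {
  n <- length(px)
  lab <- rep(AOI_CODES[["non_social"]], n)
  if (length(aoi_map$body)) {
    hit <- in_any_box(px, py, aoi_map$body)
    lab[hit] <- AOI_CODES[["other_body"]]
  }
  if (length(aoi_map$hands)) {
    hit <- in_any_box(px, py, aoi_map$hands)
    lab[hit] <- AOI_CODES[["hands"]]
  }
  if (length(aoi_map$faces)) {
    face_hit <- in_any_box(px, py, lapply(aoi_map$faces, `[[`, "face"))
    lab[face_hit] <- AOI_CODES[["other_face"]]
    mouth_hit <- face_hit & in_any_box(px, py, lapply(aoi_map$faces, `[[`, "mouth"))
    lab[mouth_hit] <- AOI_CODES[["mouth"]]
    eyes_hit <- face_hit & in_any_box(px, py, lapply(aoi_map$faces, `[[`, "eyes"))
    lab[eyes_hit] <- AOI_CODES[["eyes"]]
  }
  lab
}

#' Rasterize a frame AOI map onto the full pixel grid
#'
#' Labels every screen pixel (by its centre) with its AOI code by painting
#' the label boxes in precedence order (other body, hands, faces, then
#' mouth and eyes within faces); used for the partition property (coarse
#' label areas sum exactly to the screen area), for fast batched disk
#' labeling, and as an inspection tool. Agrees pixel-for-pixel with
#' [label_points()] evaluated at every pixel centre.
#'
#' @param aoi_map A [build_frame_aoi_map()] result.
#' @return An integer matrix (height x width) of AOI codes; the code-name
#'   mapping is in `attr(, "codes")`.
#' @export
rasterize_aoi_map <- function(aoi_map) {
  w <- aoi_map$screen$width_px; h <- aoi_map$screen$height_px
  m <- matrix(AOI_CODES[["non_social"]], nrow = h, ncol = w)
  paint <- function(b, code) {
    if (box_is_empty(b)) return(invisible())
    c_lo <- max(1L, ceiling(b[["x0"]] + 0.5))
    c_hi <- min(w, ceiling(b[["x1"]] - 0.5))
    r_lo <- max(1L, ceiling(b[["y0"]] + 0.5))
    r_hi <- min(h, ceiling(b[["y1"]] - 0.5))
    if (c_lo <= c_hi && r_lo <= r_hi) m[r_lo:r_hi, c_lo:c_hi] <<- code
    invisible()
  }
  for (b in aoi_map$body) paint(b, AOI_CODES[["other_body"]])
  for (b in aoi_map$hands) paint(b, AOI_CODES[["hands"]])
  for (f in aoi_map$faces) paint(f$face, AOI_CODES[["other_face"]])
  for (f in aoi_map$faces) paint(f$mouth, AOI_CODES[["mouth"]])
  for (f in aoi_map$faces) paint(f$eyes, AOI_CODES[["eyes"]])
  attr(m, "codes") <- AOI_CODES
  m
}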