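# Screen geometry and axis-aligned pixel boxes.
#
# Coordinate convention used throughout: pixel units, origin at the top-left
# corner of the screen, x increases rightward, y increases downward. Boxes
# and the screen itself are half-open: [x0, x1) x [y0, y1). A pixel with
# integer corner (i, j) has its centre at (i + 0.5, j + 0.5); rasterization
# everywhere uses the pixel-centre rule.

#' Screen geometry
#'
#' Describes the stimulus presentation monitor: its pixel dimensions and the
#' conversion between pixels and degrees of visual angle. The default matches
#' a 23-inch 1920 x 1080 monitor viewed at about 65 cm, where one degree of
#' visual angle spans 41 linear pixels.
#'
#' @param width_px,height_px Screen size in pixels.
#' @param px_per_degree Linear pixels per degree of visual angle.
#' @return An object of class `screen_geometry`.
#' @examples
#' screen_geometry()
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            px_per_degree = 41) {
  assert_scalar_num(width_px, "width_px", positive = TRUE, integerish = TRUE)
  assert_scalar_num(height_px, "height_px", positive = TRUE, integerish = TRUE)
  assert_scalar_num(px_per_degree, "px_per_degree", positive = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 px_per_degree = px_per_degree),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f px/degree\n",
              x$width_px, x$height_px, x$px_per_degree))
  invisible(x)
}

#' Axis-aligned box
#'
#' Half-open axis-aligned rectangle `[x0, x1) x [y0, y1)` in pixel
#' coordinates (origin top-left, y downward).
#'
#' @param x0,y0,x1,y1 Corner coordinates; `x0 < x1` and `y0 < y1` is required
#'   unless `allow_empty = TRUE` (used for degenerate keypoint boxes).
#' @param allow_empty Permit zero-width/height boxes.
#' @return A named numeric vector of class `aoi_box`.
#' @export
box <- function(x0, y0, x1, y1, allow_empty = FALSE) {
  v <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (any(!is.finite(v))) stop_gp("box coordinates must be finite")
  if (!allow_empty && (v[["x0"]] >= v[["x1"]] || v[["y0"]] >= v[["y1"]]))
    stop_gp("box requires x0 < x1 and y0 < y1 (got [%g,%g) x [%g,%g))",
            v[["x0"]], v[["x1"]], v[["y0"]], v[["y1"]])
  structure(v, class = "aoi_box")
}

box_is_empty <- function(b) b[["x0"]] >= b[["x1"]] || b[["y0"]] >= b[["y1"]]

# Pixel-centre membership test for a set of points against one box.
in_box <- function(px, py, b) {
  px >= b[["x0"]] & px < b[["x1"]] & py >= b[["y0"]] & py < b[["y1"]]
}

# Membership against a list of boxes (union).
in_any_box <- function(px, py, boxes) {
  hit <- rep(FALSE, length(px))
  for (b in boxes) if (!box_is_empty(b)) hit <- hit | in_box(px, py, b)
  hit
}

clip_box <- function(b, screen) {
  box(max(b[["x0"]], 0), max(b[["y0"]], 0),
      min(b[["x1"]], screen$width_px), min(b[["y1"]], screen$height_px),
      allow_empty = TRUE)
}

# Integer pixel offsets (relative to the pixel containing the disk centre's
# pixel origin) whose centres lie within `radius_px` of a disk centred at a
# fractional offset. Precomputed on a generic grid and shifted per centre:
# membership depends on the centre's fractional part, so we evaluate exactly
# per call but reuse the candidate square.
disk_pixels <- function(cx, cy, radius_px) {
  ix <- seq.int(floor(cx - radius_px), ceiling(cx + radius_px))
  iy <- seq.int(floor(cy - radius_px), ceiling(cy + radius_px))
  px <- rep(ix, times = length(iy)) + 0.5
  py <- rep(iy, each = length(ix)) + 0.5
  keep <- (px - cx)^2 + (py - cy)^2 <= radius_px^2
  cbind(x = px[keep], y = py[keep])
}
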