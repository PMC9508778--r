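# Gaze heatmaps and reference-heatmap correlations.
#
# A heatmap for a 1-s time bin places an isotropic 2-D Gaussian (sigma =
# 0.5 degrees of visual angle) at each of the bin's gaze points and sums
# them on the screen grid, optionally downsampled by an integer factor. The
# kernel is truncated at 4 sigma (omitting < 3e-4 of its mass) so cost is
# linear in the number of points, and it is separable, so each point costs
# two 1-D Gaussian evaluations plus an outer product. A group's reference
# heatmap for a bin is the heatmap of the group's pooled points - by
# linearity, the sum of the members' heatmaps - always computed
# leave-one-out when the compared participant belongs to the group.

#' Rasterize a Gaussian gaze heatmap for one time bin
#'
#' @param x,y Gaze point coordinates in screen pixels (on-screen points).
#' @param config A [pipeline_config()]; uses `heatmap_sigma_deg`, the screen
#'   geometry and `heatmap_downsample`.
#' @return An object of class `gaze_heatmap`: list with `grid` (height x
#'   width matrix, row = y), `downsample`, `sigma_px`, `empty` flag.
#' @examples
#' h <- rasterize_heatmap(960.5, 540.5, pipeline_config())
#' @export
rasterize_heatmap <- function(x, y, config = pipeline_config()) {
  ds <- config$heatmap_downsample
  w <- ceiling(config$screen$width_px / ds)
  h <- ceiling(config$screen$height_px / ds)
  sigma <- config$heatmap_sigma_deg * config$screen$px_per_degree
  grid <- matrix(0, nrow = h, ncol = w)
  pts <- cbind(x, y)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts)) {
    sg <- sigma / ds            # sigma in grid units
    half <- ceiling(4 * sg)
    for (i in seq_len(nrow(pts))) {
      cx <- pts[i, 1] / ds      # grid-unit coordinates
      cy <- pts[i, 2] / ds
      jx <- max(1L, floor(cx - half)):min(w, ceiling(cx + half) + 1L)
      jy <- max(1L, floor(cy - half)):min(h, ceiling(cy + half) + 1L)
      gx <- exp(-0.5 * ((jx - 0.5 - cx) / sg)^2)
      gy <- exp(-0.5 * ((jy - 0.5 - cy) / sg)^2)
      gx[abs(jx - 0.5 - cx) > 4 * sg] <- 0
      gy[abs(jy - 0.5 - cy) > 4 * sg] <- 0
      grid[jy, jx] <- grid[jy, jx] + gy %o% gx
    }
  }
  structure(list(grid = grid, downsample = ds, sigma_px = sigma,
                 empty = nrow(pts) == 0L),
            class = "gaze_heatmap")
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat(sprintf("<gaze_heatmap> %d x %d grid (downsample %d), sigma %.1f px%s\n",
              nrow(x$grid), ncol(x$grid), x$downsample, x$sigma_px,
              if (x$empty) ", EMPTY" else ""))
  invisible(x)
}

#' Reference heatmap for a group of participants in one time bin
#'
#' Pools the bin's gaze points from all group members (optionally leaving
#' one participant out) and rasterizes the pooled set. Leaving out an id not
#' in the group is a no-op; an empty group after leave-out is an error.
#'
#' @param bin_points Named list, one element per group member, each a
#'   two-column matrix (x, y) of the member's on-screen points in the bin.
#' @param leave_out Participant id to exclude, or `NULL`.
#' @param config A [pipeline_config()].
#' @return A `gaze_heatmap`.
#' @export
reference_heatmap <- function(bin_points, leave_out = NULL,
                              config = pipeline_config()) {
  if (!is.null(leave_out))
    bin_points <- bin_points[setdiff(names(bin_points), leave_out)]
  if (!length(bin_points))
    stop_gp("reference group is empty after leave-one-out")
  pooled <- do.call(rbind, lapply(bin_points, function(p) {
    p <- as.matrix(p); if (!nrow(p)) return(NULL); p[, 1:2, drop = FALSE]
  }))
  if (is.null(pooled)) pooled <- matrix(numeric(), ncol = 2)
  rasterize_heatmap(pooled[, 1], pooled[, 2], config)
}

#' Pearson correlation between two heatmaps
#'
#' Flattens both grids and computes the Pearson correlation. Undefined
#' (returns `NA`) when either heatmap is empty or constant.
#'
#' @param h1,h2 `gaze_heatmap` objects (or bare matrices) of equal shape.
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
correlate_heatmaps <- function(h1, h2) {
  g1 <- if (inherits(h1, "gaze_heatmap")) h1$grid else h1
  g2 <- if (inherits(h2, "gaze_heatmap")) h2$grid else h2
  if (!identical(dim(g1), dim(g2)))
    stop_gp("heatmap grids differ in shape (%s vs %s)",
            paste(dim(g1), collapse = "x"), paste(dim(g2), collapse = "x"))
  if ((inherits(h1, "gaze_heatmap") && h1$empty) ||
      (inherits(h2, "gaze_heatmap") && h2$empty)) return(NA_real_)
  v1 <- as.numeric(g1); v2 <- as.numeric(g2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

# Fast per-bin reference correlations for a whole cohort.
#
# points_by_bin: list over bins; each element a named list (participant id
# -> 2-col matrix of on-screen points in the bin, possibly 0 rows).
# Returns a participants x bins matrix of Pearson r against the
# leave-one-out reference of `reference_ids` (leave-out applied iff the
# participant is a member). Bins where a participant has no points, or the
# reference is empty/constant, are NA.
bin_reference_correlations <- function(points_by_bin, participant_ids,
                                       reference_ids, config) {
  n <- length(participant_ids)
  nb <- length(points_by_bin)
  out <- matrix(NA_real_, nrow = n, ncol = nb,
                dimnames = list(participant_ids, NULL))
  for (b in seq_len(nb)) {
    pts <- points_by_bin[[b]]
    hms <- vector("list", n)
    for (i in seq_len(n)) {
      p <- pts[[participant_ids[i]]]
      if (!is.null(p) && nrow(p))
        hms[[i]] <- rasterize_heatmap(p[, 1], p[, 2], config)$grid
    }
    ref_members <- which(participant_ids %in% reference_ids &
                           !vapply(hms, is.null, logical(1)))
    if (!length(ref_members)) next
    S <- Reduce(`+`, hms[ref_members])
    s_tot <- sum(S); ss_tot <- sum(S * S); npx <- length(S)
    for (i in seq_len(n)) {
      if (is.null(hms[[i]])) next
      Hi <- hms[[i]]
      if (i %in% ref_members) {
        if (length(ref_members) == 1L) next   # empty after leave-out
        R <- S - Hi
        sum_r <- s_tot - sum(Hi)
        ss_r <- sum(R * R)
        cross <- sum(Hi * R)
      } else {
        R <- NULL
        sum_r <- s_tot
        ss_r <- ss_tot
        cross <- sum(Hi * S)
      }
      sum_h <- sum(Hi); ss_h <- sum(Hi * Hi)
      var_h <- ss_h - sum_h^2 / npx
      var_r <- ss_r - sum_r^2 / npx
      if (var_h <= 0 || var_r <= 0) next
      out[i, b] <- (cross - sum_h * sum_r / npx) / sqrt(var_h * var_r)
    }
  }
  out
}

#' Per-bin reference correlations for one participant
#'
#' Computes, for each time bin, the Pearson correlation between the
#' participant's gaze heatmap and the reference-group heatmap for that bin
#' (leave-one-out when the participant belongs to the reference group), and
#' the mean over bins where the correlation is defined. Bins where the
#' participant has no on-screen gaze are skipped, not zero-filled.
#'
#' @param participant_id Participant to correlate.
#' @param points_by_bin List over bins of named lists (participant id ->
#'   two-column point matrix), covering the participant and all reference
#'   members.
#' @param reference_ids Ids of the reference group members.
#' @param config A [pipeline_config()].
#' @return A list with `participant_id`, `per_bin` (numeric vector, NA where
#'   undefined), `mean_r`, `n_defined`, `reference_group` size.
#' @export
participant_reference_correlation <- function(participant_id, points_by_bin,
                                              reference_ids,
                                              config = pipeline_config()) {
  ids <- unique(c(participant_id, reference_ids))
  rmat <- bin_reference_correlations(points_by_bin, ids, reference_ids, config)
  per_bin <- rmat[participant_id, ]
  n_def <- sum(!is.na(per_bin))
  if (n_def == 0L)
    gp_log("participant %s has no bin with a defined reference correlation",
           participant_id, level = "WARN")
  list(participant_id = participant_id, per_bin = per_bin,
       mean_r = if (n_def) mean(per_bin, na.rm = TRUE) else NA_real_,
       n_defined = n_def, reference_group = length(reference_ids))
}

#' Flag outlying mean reference correlations
#'
#' A participant is flagged when its mean reference-heatmap correlation
#' deviates from the mean of all other participants by more than `k`
#' standard deviations of those others (leave-one-out, so an extreme value
#' cannot mask itself).
#'
#' @param mean_r Named numeric vector of per-participant mean correlations.
#' @param k SD multiplier (default 4).
#' @return A named logical vector of flags.
#' @export
flag_heatmap_outliers <- function(mean_r, k = 4) {
  n <- length(mean_r)
  if (n < 3L) {
    gp_log("fewer than 3 participants; outlier flagging skipped",
           level = "WARN")
    return(stats::setNames(rep(FALSE, n), names(mean_r)))
  }
  flags <- vapply(seq_len(n), function(i) {
    others <- mean_r[-i]
    s <- stats::sd(others)
    if (!is.finite(s) || s == 0) return(FALSE)
    abs(mean_r[i] - mean(others)) > k * s
  }, logical(1))
  stats::setNames(flags, names(mean_r))
}
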