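# Gaze recordings and their tabular on-disk format.
#
# A gaze table is a TSV/CSV with header columns participant_id, episode_id,
# t (seconds), x (px), y (px), valid (0/1); one row per raw tracker sample.

#' Gaze recording
#'
#' One participant's raw gaze stream for one episode: sample times (seconds
#' from episode start, strictly increasing), screen coordinates in pixels
#' (origin top-left, y downward) and the tracker validity flag. A sample is
#' on-screen iff it is valid and falls inside the half-open screen bounds.
#'
#' @param participant_id,episode_id Identifiers.
#' @param rate_hz Nominal tracker sampling rate (300 or 120 Hz typical);
#'   must exceed the video frame rate.
#' @param samples A data.frame with columns `t`, `x`, `y`, `valid`.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, episode_id, rate_hz, samples) {
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "valid") %in% names(samples)))
  assert_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  t <- samples$t
  if (anyNA(t) || any(t < 0)) stop_gp("sample times must be finite and >= 0")
  if (is.unsorted(t, strictly = TRUE))
    stop_gp("sample times must be strictly increasing (participant %s, episode %s)",
            participant_id, episode_id)
  samples$valid <- as.logical(samples$valid) &
    is.finite(samples$x) & is.finite(samples$y)
  samples$x <- as.numeric(samples$x)
  samples$y <- as.numeric(samples$y)
  structure(list(participant_id = as.character(participant_id),
                 episode_id = as.character(episode_id),
                 rate_hz = rate_hz,
                 samples = samples[c("t", "x", "y", "valid")]),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s / %s: %d samples @ %g Hz, %.1f s\n",
              x$participant_id, x$episode_id, nrow(x$samples), x$rate_hz,
              if (nrow(x$samples)) max(x$samples$t) else 0))
  invisible(x)
}

#' Read gaze recordings from a delimited table
#'
#' Accepts tab- or comma-separated files with header columns
#' `participant_id`, `episode_id`, `t`, `x`, `y`, `valid` and an optional
#' `rate_hz` column (constant within a recording; defaults to 300). Rows with
#' non-numeric coordinates are kept as invalid samples with a logged warning;
#' rows with an unparseable time are rejected with their line numbers logged.
#'
#' @param path File path.
#' @param screen A [screen_geometry()] (retained for callers; bounds are not
#'   enforced at read time since off-screen samples are meaningful).
#' @param default_rate_hz Sampling rate assumed when the file has no
#'   `rate_hz` column.
#' @return A named list of [gaze_recording()] objects
#'   (`participant_id.episode_id`).
#' @export
read_gaze_table <- function(path, screen = screen_geometry(),
                            default_rate_hz = 300) {
  if (!file.exists(path)) stop_gp("gaze table not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("participant_id", "episode_id", "t", "x", "y", "valid")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_gp("gaze table %s is missing column(s): %s", path,
            paste(missing_cols, collapse = ", "))
  t <- suppressWarnings(as.numeric(df$t))
  bad_t <- which(!is.finite(t))
  if (length(bad_t)) {
    gp_log("dropping %d row(s) with unparseable time (lines %s)",
           length(bad_t), paste(utils::head(bad_t + 1L, 10L), collapse = ","),
           level = "WARN")
    df <- df[-bad_t, , drop = FALSE]
    t <- t[-bad_t]
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  valid <- suppressWarnings(as.numeric(df$valid)) != 0
  valid[is.na(valid)] <- FALSE
  coerced <- valid & (!is.finite(x) | !is.finite(y))
  if (any(coerced))
    gp_log("%d row(s) with non-numeric coordinates treated as invalid samples",
           sum(coerced), level = "WARN")
  valid[coerced] <- FALSE
  x[!is.finite(x)] <- NA_real_
  y[!is.finite(y)] <- NA_real_
  rate <- if ("rate_hz" %in% names(df))
    suppressWarnings(as.numeric(df$rate_hz)) else rep(default_rate_hz, nrow(df))
  key <- paste(df$participant_id, df$episode_id, sep = ".")
  out <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    i <- i[order(t[i])]
    if (anyDuplicated(t[i]))
      stop_gp("non-monotone or duplicated times within recording %s", k)
    out[[k]] <- gaze_recording(df$participant_id[i[1]], df$episode_id[i[1]],
                               rate[i[1]],
                               data.frame(t = t[i], x = x[i], y = y[i],
                                          valid = valid[i]))
  }
  out
}

#' Write gaze recordings to a TSV gaze table
#'
#' Output is byte-stable for a fixed input ordering; times and coordinates
#' are written with enough digits to round-trip through [read_gaze_table()]
#' (times to at least 1e-6 s).
#'
#' @param recordings A list of [gaze_recording()] objects (may be empty:
#'   a header-only file is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recordings, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("participant_id", "episode_id", "t", "x", "y", "valid",
                     "rate_hz"), collapse = "\t"), con)
  for (rec in recordings) {
    s <- rec$samples
    lines <- paste(rec$participant_id, rec$episode_id,
                   sprintf("%.17g", s$t),
                   ifelse(is.na(s$x), "NA", sprintf("%.17g", s$x)),
                   ifelse(is.na(s$y), "NA", sprintf("%.17g", s$y)),
                   as.integer(s$valid),
                   sprintf("%.10g", rec$rate_hz),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Participant metadata table
#'
#' Validates and normalizes a participant metadata data.frame: diagnosis
#' group (`ASD`/`TD`), testing site, per-episode stimulus familiarity rating
#' (1-9, may be missing), autism symptom severity (ADOS-derived calibrated
#' severity score, ASD group only, may be missing) and optional descriptives.
#'
#' @param df A data.frame with at least `participant_id` and `group`;
#'   optional columns `site`, `familiarity_A`, `familiarity_B`,
#'   `severity_css`, `aq`, `age_years`, `sex`, `fsiq`.
#' @return The validated data.frame (class `participant_meta`).
#' @export
participant_meta <- function(df) {
  stopifnot(is.data.frame(df), all(c("participant_id", "group") %in% names(df)))
  if (!all(df$group %in% c("ASD", "TD")))
    stop_gp("group must be 'ASD' or 'TD'")
  for (col in intersect(c("familiarity_A", "familiarity_B"), names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 1 | v > 9)))
      stop_gp("%s ratings must lie in [1, 9]", col)
  }
  df$participant_id <- as.character(df$participant_id)
  class(df) <- c("participant_meta", "data.frame")
  df
}
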