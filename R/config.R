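# Pipeline configuration: constants shared by every analysis stage.

config_defaults <- function() {
  list(
    screen = screen_geometry(),
    frame_rate_fps = 24,
    bin_seconds = 1,
    heatmap_sigma_deg = 0.5,
    disk_diameter_deg = 1.0,
    n_boot = 10000L,
    n_perm = 10000L,
    epoch_minutes = 10,
    rng_seed = 1L,
    exclusion_missing_fraction = 0.5,
    fdr_method = "BH",
    heatmap_downsample = 1L
  )
}

#' Pipeline configuration
#'
#' Bundles the constants used across the pipeline: screen geometry, video
#' frame rate (24 fps), heatmap time-bin duration (1 s), heatmap kernel width
#' (0.5 degrees of visual angle), gaze-disk diameter (1 degree), resampling
#' iteration counts (10,000 bootstrap / permutation draws), the epoch length
#' for sampling analyses, the participant exclusion threshold (more than half
#' of a session missing), the FDR method, and an integer heatmap grid
#' downsampling factor that trades heatmap fidelity for speed.
#'
#' @param ... Named overrides of the defaults (see Details). Unknown names
#'   are an error so that config typos never pass silently.
#' @return An object of class `pipeline_config`.
#' @examples
#' pipeline_config(n_boot = 500, heatmap_downsample = 4)
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop_gp("all config overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_gp("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg$screen, "screen_geometry")) {
    if (is.list(cfg$screen)) {
      cfg$screen <- do.call(screen_geometry, cfg$screen)
    } else stop_gp("'screen' must be a screen_geometry or a named list")
  }
  for (k in c("frame_rate_fps", "bin_seconds", "heatmap_sigma_deg",
              "disk_diameter_deg", "epoch_minutes"))
    assert_scalar_num(cfg[[k]], k, positive = TRUE)
  for (k in c("n_boot", "n_perm", "heatmap_downsample"))
    assert_scalar_num(cfg[[k]], k, positive = TRUE, integerish = TRUE)
  assert_scalar_num(cfg$rng_seed, "rng_seed", integerish = TRUE)
  f <- cfg$exclusion_missing_fraction
  assert_scalar_num(f, "exclusion_missing_fraction")
  if (f <= 0 || f >= 1)
    stop_gp("'exclusion_missing_fraction' must lie in (0, 1)")
  if (!is.character(cfg$fdr_method) ||
      !cfg$fdr_method %in% stats::p.adjust.methods)
    stop_gp("'fdr_method' must be one of stats::p.adjust.methods")
  cfg$n_boot <- as.integer(cfg$n_boot)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$heatmap_downsample <- as.integer(cfg$heatmap_downsample)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take their defaults; unknown keys raise an
#' error. The effective configuration is echoed to the log. The `screen`
#' section may be given as a nested mapping with `width_px`, `height_px` and
#' `px_per_degree`.
#'
#' @param path Path to a YAML (or empty) file.
#' @return A [pipeline_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_gp("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_gp("config file must contain a mapping")
  cfg <- do.call(pipeline_config, raw)
  gp_log("config: %s", paste(sprintf("%s=%s", names(summ <- config_summary(cfg)),
                                     unlist(summ)), collapse = " "))
  cfg
}

config_summary <- function(cfg) {
  list(screen = sprintf("%dx%d@%.3gpx/deg", cfg$screen$width_px,
                        cfg$screen$height_px, cfg$screen$px_per_degree),
       fps = cfg$frame_rate_fps, bin_s = cfg$bin_seconds,
       sigma_deg = cfg$heatmap_sigma_deg, disk_deg = cfg$disk_diameter_deg,
       n_boot = cfg$n_boot, n_perm = cfg$n_perm,
       epoch_min = cfg$epoch_minutes, seed = cfg$rng_seed,
       excl = cfg$exclusion_missing_fraction, fdr = cfg$fdr_method,
       downsample = cfg$heatmap_downsample)
}

#' @export
print.pipeline_config <- function(x, ...) {
  s <- config_summary(x)
  cat("<pipeline_config>\n")
  for (k in names(s)) cat(sprintf("  %-12s %s\n", k, s[[k]]))
  invisible(x)
}
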