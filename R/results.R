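# Serialization of analysis results and run manifests.

#' Write an analysis result as a JSON document
#'
#' Every command-level result serializes to a single JSON file for machine
#' reading (estimates, intervals, p-values, per-participant tables), with
#' data.frames as column-wise records and resampling draw vectors omitted.
#'
#' @param x A result object (effect table, fingerprint/classifier/cluster
#'   result, or any list of scalars and data.frames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  strip <- function(v) {
    if (is.list(v) && !is.data.frame(v))
      v <- lapply(v[setdiff(names(v), c("boot", "acc", "null", "nn",
                                        "per_bin"))], strip)
    v
  }
  jsonlite::write_json(strip(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest alongside command outputs
#'
#' Records the command, configuration snapshot, seed, input file digests,
#' output paths, timestamp and package version, so any result can be
#' reproduced from its manifest alone.
#'
#' @param command Command name.
#' @param config A [pipeline_config()].
#' @param seed Integer seed used.
#' @param inputs,outputs Character vectors of file paths.
#' @param dir Directory receiving `manifest_<command>.json`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(command, config, seed, inputs, outputs, dir) {
  digest_of <- function(p) if (file.exists(p))
    unname(tools::md5sum(p)) else NA_character_
  manifest <- list(
    command = command,
    config = config_summary(config),
    seed = seed,
    inputs = stats::setNames(lapply(inputs, digest_of), basename(inputs)),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("gazepheno")))
  path <- file.path(dir, sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a cohort directory and build its timeline
#'
#' Reads the gaze table, per-episode annotation files and metadata CSV
#' written by [make_cohort()] (or assembled by hand in the same layout)
#' and runs [build_timeline()].
#'
#' @param data_dir Directory with `gaze.tsv`, `annotations_<ep>.jsonl`,
#'   `metadata.csv`.
#' @param config A [pipeline_config()].
#' @param reference_group Reference group for heatmaps.
#' @return A `cohort_timeline`.
#' @export
load_cohort_timeline <- function(data_dir, config = pipeline_config(),
                                 reference_group = "TD") {
  recs <- read_gaze_table(file.path(data_dir, "gaze.tsv"), config$screen)
  ann_files <- sort(list.files(data_dir, "^annotations_.*\\.jsonl$",
                               full.names = TRUE))
  if (!length(ann_files)) stop_gp("no annotation files in %s", data_dir)
  scenes <- list()
  for (f in ann_files) {
    ep <- sub("^annotations_(.*)\\.jsonl$", "\\1", basename(f))
    scenes[[ep]] <- read_annotations(f, config$frame_rate_fps,
                                     config$screen, episode_id = ep)
  }
  meta <- participant_meta(utils::read.csv(file.path(data_dir,
                                                     "metadata.csv")))
  build_timeline(recs, scenes, meta, config,
                 reference_group = reference_group)
}
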