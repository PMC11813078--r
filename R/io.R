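# File formats: HDF5 pose layout, ethogram CSVs, YAML pipeline config, and
# content hashing for run manifests.
#
# Pose HDF5 layout (a minimal dialect of common pose-track exports):
#   /tracks          frames x nodes x 2 float64, NaN = missing
#   /node_names      string vector
#   /meta/fps, /meta/px_per_mm, /meta/t0_clock, /meta/fly_id,
#   /meta/frames_per_hour

#' Save and load pose sequences (HDF5)
#'
#' Lossless round trip of coordinates, missing mask and metadata; missing
#' keypoints are stored as NaN and converted back to the mask on load.
#'
#' @param pose A [pose_sequence()].
#' @param path Output file (overwritten).
#' @return `save_pose()` the path invisibly; `load_pose()` the pose.
#' @export
save_pose <- function(pose, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  tracks <- pose$coords
  tracks[, , 1][pose$missing] <- NaN
  tracks[, , 2][pose$missing] <- NaN
  rhdf5::h5write(tracks, path, "tracks")
  rhdf5::h5write(pose$node_names, path, "node_names")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(pose$fps, path, "meta/fps")
  rhdf5::h5write(pose$px_per_mm, path, "meta/px_per_mm")
  rhdf5::h5write(pose$t0_clock, path, "meta/t0_clock")
  rhdf5::h5write(pose$fly_id, path, "meta/fly_id")
  rhdf5::h5write(pose$frames_per_hour, path, "meta/frames_per_hour")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_pose
#' @export
load_pose <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)$name
  for (required in c("tracks", "node_names")) {
    if (!required %in% contents) {
      stop(sprintf("pose file %s lacks required dataset '%s'", path, required))
    }
  }
  tracks <- rhdf5::h5read(path, "tracks")
  tracks[is.nan(tracks)] <- NA_real_
  node_names <- as.character(rhdf5::h5read(path, "node_names"))
  meta <- function(name, default) {
    if (name %in% contents) as.vector(rhdf5::h5read(path, paste0("meta/", name)))
    else default
  }
  fps <- meta("fps", 100)
  out <- pose_sequence(
    coords = tracks,
    missing = is.na(tracks[, , 1]) | is.na(tracks[, , 2]),
    node_names = node_names, fps = fps,
    px_per_mm = meta("px_per_mm", 28.25), t0_clock = meta("t0_clock", 8),
    fly_id = meta("fly_id", "fly1"),
    frames_per_hour = meta("frames_per_hour", fps * 3600))
  rhdf5::h5closeAll()
  out
}

#' Save and load ethograms (CSV)
#'
#' Plain `frame,label` CSV with metadata in `#key=value` comment lines;
#' `write_bouts_csv()` writes the compact run-length form.
#'
#' @param etho An [ethogram()].
#' @param path File path.
#' @return Path invisibly / the `ethogram`.
#' @export
write_ethogram_csv <- function(etho, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", c("fps", "t0_clock", "fly_id", "frames_per_hour"),
                     c(etho$fps, etho$t0_clock, etho$fly_id,
                       etho$frames_per_hour)), con)
  writeLines("frame,label", con)
  writeLines(paste(seq_along(etho$labels) - 1L, etho$labels, sep = ","), con)
  invisible(path)
}

#' @rdname write_ethogram_csv
#' @export
read_ethogram_csv <- function(path) {
  lines <- readLines(path)
  metas <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", metas), "=")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.csv(text = lines[!grepl("^#", lines)])
  ethogram(df$label, fps = as.numeric(meta[["fps"]]),
           t0_clock = as.numeric(meta[["t0_clock"]]),
           fly_id = meta[["fly_id"]],
           frames_per_hour = as.numeric(meta[["frames_per_hour"]]))
}

#' @rdname write_ethogram_csv
#' @export
write_bouts_csv <- function(etho, path) {
  bouts <- extract_bouts(etho)
  bouts$duration_s <- bouts$duration_frames / etho$fps
  write.csv(bouts, path, row.names = FALSE)
  invisible(path)
}

# Content hash of a plain R object (stable across sessions for data objects).
obj_hash <- function(x) {
  raw <- serialize(x, NULL, version = 3)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}

#' Default pipeline configuration
#'
#' Nested stage-parameter list with an explicit seed per stochastic stage.
#' The default synthetic world is 2 flies for 48 ZT hours with each hour
#' compressed to 60 recorded seconds (desk-scale validation cohort).
#'
#' @param seed Base seed; stage seeds derive from it deterministically.
#' @return Named list of stage blocks.
#' @export
default_pipeline_config <- function(seed = 1) {
  seed <- as.integer(seed)
  list(
    synth = list(fps = 100, px_per_mm = 28.25, arena_diameter_mm = 25,
                 n_flies = 2, n_hours = 48, seconds_per_hour = 60,
                 seed = seed, missing_rate = 0.05, edge_bout_rate = 0.025,
                 edge_bout_duration_s = 2, noise_sd_mm = 0.02,
                 heading_sd = 1.2),
    preprocess = list(gap_limit = 5, median_window = 5, gauss_window = 5,
                      gauss_sd = 1),
    spectral = list(n_freqs = 25, f_min = 0.5, f_max = 25,
                    window_periods = 5, stride = 20, min_occupancy = 0.5,
                    amplitude_threshold = 0.5012),
    edge = list(n_per_class = 500, lambda = 1e-3, seed = seed + 101L),
    map = list(cap = 36000, quota = 454, n_neighbors = 15, min_dist = 0.1,
               grid_size = 512, kde_factor = 1, low_density_quantile = 0.05,
               adaptive_block = 32, adaptive_offset = 0.2,
               seed = seed + 202L),
    ethogram = list(min_bout_frames = 5),
    composition = list(lights_on_clock = 8, min_frames_frac = 0.1,
                       robust = TRUE, support_fraction = 0.75,
                       seed = seed + 303L),
    kinematics = list(speed_window = 5, n_radial_bins = 10)
  )
}

#' Validate a pipeline configuration
#'
#' Checks that all stage blocks exist and every stochastic stage carries an
#' explicit integer seed; errors before any stage runs.
#'
#' @param config Nested config list.
#' @return The config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  blocks <- c("synth", "preprocess", "spectral", "edge", "map", "ethogram",
              "composition", "kinematics")
  missing_blocks <- setdiff(blocks, names(config))
  if (length(missing_blocks)) {
    stop("config lacks stage block(s): ", paste(missing_blocks, collapse = ", "))
  }
  for (blk in c("synth", "edge", "map", "composition")) {
    s <- config[[blk]]$seed
    if (is.null(s) || !is.finite(s)) {
      stop(sprintf("stage '%s' has no seed; every stochastic stage needs one",
                   blk))
    }
  }
  invisible(config)
}

#' @rdname default_pipeline_config
#' @param path YAML file.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = cfg$seed %||% 1L)
  for (blk in names(base)) {
    for (key in names(cfg[[blk]])) base[[blk]][[key]] <- cfg[[blk]][[key]]
  }
  validate_pipeline_config(base)
  base
}

#' @rdname default_pipeline_config
#' @param config Config list.
#' @export
config_hash <- function(config) {
  canonical <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  obj_hash(as.character(canonical))
}
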