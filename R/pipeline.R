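# Orchestration: the full synthetic-validation pipeline (simulate ->
# preprocess -> featurize -> edge -> map -> assign -> boutfix -> compose ->
# statistics), a labeled wall-frame fixture for edge-classifier training,
# and the run manifest.

#' Labeled edge-detection fixture
#'
#' Renders a clean locomotion sequence and translates the first half of its
#' frames to the arena wall (thorax at 96% of the radius), yielding
#' complete feature rows with known on/off-edge labels -- the synthetic
#' stand-in for manually labeled training points.
#'
#' @param config A [synth_config()].
#' @param n_per_class Frames per class (default 500).
#' @param seed RNG seed.
#' @return List: `features` (2 n_per_class x 104), `labels` (logical),
#'   `pose`, `arena`.
#' @export
make_edge_fixture <- function(config, n_per_class = 500, seed = 7) {
  n <- 2L * n_per_class
  states <- rep("locomotion", n)
  pose <- render_pose(states, default_archetypes(), config, seed = seed,
                      fly_id = "edge_fixture")
  arena <- arena_from_config(config)
  on_edge <- c(rep(TRUE, n_per_class), rep(FALSE, n_per_class))
  wall_r <- 0.96 * arena$radius_px
  th <- match("thorax", pose$node_names)
  coords <- pose$coords
  ang <- atan2(coords[seq_len(n_per_class), th, 2],
               coords[seq_len(n_per_class), th, 1])
  dx <- wall_r * cos(ang) - coords[seq_len(n_per_class), th, 1]
  dy <- wall_r * sin(ang) - coords[seq_len(n_per_class), th, 2]
  coords[seq_len(n_per_class), , 1] <- coords[seq_len(n_per_class), , 1] + dx
  coords[seq_len(n_per_class), , 2] <- coords[seq_len(n_per_class), , 2] + dy
  pose <- pose_sequence(coords, pose$missing, node_names = pose$node_names,
                        fps = pose$fps, px_per_mm = pose$px_per_mm,
                        t0_clock = pose$t0_clock, fly_id = pose$fly_id,
                        frames_per_hour = pose$frames_per_hour)
  pose <- interpolate_pose(pose)
  features <- build_edge_features(pose, arena)
  list(features = features, labels = on_edge, pose = pose, arena = arena)
}

# Split per-fly spectral output into fly-hour groups for training assembly.
fly_hour_groups <- function(sf, amplitude, edge_eval, fly_id) {
  fph_eval <- sf$frames_per_hour / sf$stride
  hour <- floor((seq_along(sf$eval_frames) - 1) / fph_eval)
  lapply(unique(hour), function(h) {
    sel <- hour == h
    list(power = sf$power[sel, , drop = FALSE], valid = sf$valid[sel],
         edge = edge_eval[sel], amplitude = amplitude[sel],
         fly_id = fly_id, hour = h, frames = sf$eval_frames[sel])
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage on the cohort described by `config` and returns all
#' intermediate and final results together with a run manifest (config
#' hash, per-stage output hashes, timestamps, package version). Region
#' naming uses the generator's ground truth by majority vote, standing in
#' for manual clip review.
#'
#' @param config Pipeline configuration (see [default_pipeline_config()]).
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @param verbose Print stage progress.
#' @return List with elements `cohort`, `edge_model`, `map`, `regions`,
#'   `ethograms` (full-rate, bout-corrected), `compositions`, `pca`,
#'   `day_night`, `speed_by_hour`, `proboscis_bouts`, `radial`, `accuracy`
#'   (per-fly frame accuracy vs ground truth at feature resolution),
#'   `unstereotyped_fraction`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL, verbose = TRUE) {
  validate_pipeline_config(config)
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  stage_hash <- list()
  scfg <- do.call(synth_config, config$synth)
  schedule <- diurnal_schedule()
  arena <- arena_from_config(scfg)
  thr <- config$spectral$amplitude_threshold
  stride <- config$spectral$stride
  grid <- frequency_grid(config$spectral$n_freqs, config$spectral$f_min,
                         config$spectral$f_max, fps = scfg$fps)

  say("simulate: %d flies x %d h (%g s/hour)", scfg$n_flies, scfg$n_hours,
      scfg$seconds_per_hour)
  cohort <- simulate_cohort(scfg, schedule)
  stage_hash$simulate <- obj_hash(lapply(cohort, function(f) f$truth))

  say("edge: training classifier on labeled wall fixture")
  fixture <- make_edge_fixture(scfg, config$edge$n_per_class,
                               seed = config$edge$seed)
  edge_model <- train_edge_classifier(fixture$features, fixture$labels,
                                      seed = config$edge$seed,
                                      lambda = config$edge$lambda)
  stage_hash$edge_train <- obj_hash(edge_model[c("w", "b")])

  flies <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    say("fly %d: preprocess + featurize", i)
    pp <- config$preprocess
    pose <- interpolate_pose(cohort[[i]]$pose, gap_limit = pp$gap_limit)
    pose <- smooth_pose(pose, pp$median_window, pp$gauss_window, pp$gauss_sd)
    edge_flags <- predict_edge(edge_model, build_edge_features(pose, arena))
    ego <- egocentrize(pose)
    sf <- rolling_spectral_features(ego, grid, config$spectral$window_periods,
                                    stride, config$spectral$min_occupancy)
    flies[[i]] <- list(pose = pose, sf = sf,
                       amplitude = total_spectral_amplitude(sf),
                       edge_flags = edge_flags,
                       edge_eval = edge_flags[sf$eval_frames],
                       truth = cohort[[i]]$truth)
  }
  stage_hash$features <- obj_hash(lapply(flies, function(f) f$amplitude))

  say("map: assembling training set")
  groups <- do.call(c, lapply(flies, function(f) {
    fly_hour_groups(f$sf, f$amplitude, f$edge_eval, f$pose$fly_id)
  }))
  train <- assemble_training_set(groups, amplitude_threshold = thr,
                                 cap = config$map$cap, quota = config$map$quota,
                                 seed = config$map$seed)
  say("map: embedding %d training points", nrow(train$features))
  emb <- fit_embedding(train, config$map$n_neighbors, config$map$min_dist,
                       seed = config$map$seed)
  regions <- segment_density(emb, config$map$grid_size, config$map$kde_factor,
                             config$map$low_density_quantile,
                             config$map$adaptive_block,
                             config$map$adaptive_offset)
  fly_ids <- vapply(flies, function(f) f$pose$fly_id, "")
  train_truth <- mapply(function(fid, fr) {
    flies[[match(fid, fly_ids)]]$truth$true_ethogram[fr]
  }, train$provenance$fly_id, train$provenance$frame)
  regions <- label_regions(regions, emb$train_coords, train_truth)
  stage_hash$map <- obj_hash(list(emb$train_coords, regions$labels,
                                  regions$behavior_names))
  say("map: %d regions -> {%s}", regions$n_regions,
      paste(unique(regions$behavior_names), collapse = ", "))

  ethos <- vector("list", length(flies))
  accuracy <- numeric(length(flies))
  unst <- numeric(length(flies))
  for (i in seq_along(flies)) {
    say("fly %d: assigning behaviors", i)
    f <- flies[[i]]
    labels <- assign_behaviors(f$sf$power, f$sf$valid, f$edge_eval,
                               f$amplitude, emb, regions,
                               amplitude_threshold = thr)
    truth_eval <- f$truth$true_ethogram[f$sf$eval_frames]
    edge_eval_true <- f$truth$true_edge_mask[f$sf$eval_frames]
    scored <- !(labels %in% c("edge", "unstereotyped")) & !edge_eval_true
    accuracy[i] <- mean(labels[scored] == truth_eval[scored])
    unst[i] <- mean(labels == "unstereotyped")
    etho_strided <- ethogram(labels, fps = f$sf$fps / stride,
                             t0_clock = f$pose$t0_clock,
                             fly_id = f$pose$fly_id,
                             frames_per_hour = f$pose$frames_per_hour / stride)
    etho_full <- expand_ethogram(etho_strided, stride, n_out = n_frames(f$pose))
    ethos[[i]] <- enforce_min_bout(etho_full, config$ethogram$min_bout_frames)
  }
  stage_hash$assign <- obj_hash(lapply(ethos, `[[`, "labels"))

  say("compose: hourly compositions + robust PCA")
  comp_cfg <- config$composition
  comp_list <- lapply(ethos, hourly_compositions,
                      lights_on_clock = comp_cfg$lights_on_clock,
                      min_frames_frac = comp_cfg$min_frames_frac)
  parts <- do.call(rbind, lapply(comp_list, `[[`, "parts"))
  meta <- do.call(rbind, lapply(comp_list, `[[`, "meta"))
  comps <- composition_table(parts, meta)
  pca <- robust_composition_pca(comps, robust = comp_cfg$robust,
                                support_fraction = comp_cfg$support_fraction,
                                seed = comp_cfg$seed)
  day_night <- day_night_difference(pca$scores[, 1], meta$zt_hour,
                                    meta$day_index, meta$fly_id)
  stage_hash$compose <- obj_hash(list(comps$parts, pca$clr_loadings))

  say("stats: speed, bouts, radial occupancy")
  speeds <- do.call(rbind, lapply(seq_along(flies), function(i) {
    locomotion_speed(flies[[i]]$pose, ethos[[i]],
                     window = config$kinematics$speed_window,
                     lights_on_clock = comp_cfg$lights_on_clock)
  }))
  speed_by_hour <- speed_by_group(speeds, "zt_hour")
  prob_bouts <- bout_duration_stats(ethos[[1]], "proboscis", "zt_hour",
                                    lights_on_clock = comp_cfg$lights_on_clock)
  radial <- radial_occupancy(flies[[1]]$pose, arena, ethos[[1]],
                             n_bins = config$kinematics$n_radial_bins)
  stage_hash$stats <- obj_hash(list(speed_by_hour, prob_bouts))

  manifest <- list(config_hash = as.character(config_hash(config)),
                   stages = lapply(stage_hash, as.character),
                   package_version = as.character(utils::packageVersion("ethospan")),
                   started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- list(cohort = cohort, edge_model = edge_model, map = emb,
                 regions = regions, ethograms = ethos, compositions = comps,
                 pca = pca, day_night = day_night,
                 speed_by_hour = speed_by_hour, proboscis_bouts = prob_bouts,
                 radial = radial, accuracy = accuracy,
                 unstereotyped_fraction = unst, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cbind(meta, comps$parts),
              file.path(output_dir, "compositions.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(clr_loadings = pca$clr_loadings,
           variance_explained = pca$variance_explained),
      file.path(output_dir, "pca.json"), digits = 10)
    for (i in seq_along(ethos)) {
      write_ethogram_csv(ethos[[i]], file.path(
        output_dir, sprintf("ethogram_%s.csv", ethos[[i]]$fly_id)))
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  say("done: mean frame accuracy %.3f, unstereotyped %.3f",
      mean(accuracy), mean(unst))
  result
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write synthetic poses + ground truth),
#' `run` (full pipeline from a YAML config), `boutfix` (minimum-bout
#' correction of an ethogram CSV). Called by the installed `ethospan`
#' script; exposed as a function for testing.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
ethospan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ethospan <command> [options]",
    "  simulate --out DIR [--seed N] [--hours N] [--flies N] [--config FILE]",
    "  run      --out DIR [--seed N] [--config FILE]",
    "  boutfix  --in FILE --out FILE [--min-frames N]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    key <- sub("^--", "", rest[1])
    opts[[key]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  if (cmd == "simulate") {
    cfg <- if (!is.null(opts$config)) load_pipeline_config(opts$config)
    else default_pipeline_config(seed = as.integer(opts$seed %||% 1))
    if (!is.null(opts$hours)) cfg$synth$n_hours <- as.integer(opts$hours)
    if (!is.null(opts$flies)) cfg$synth$n_flies <- as.integer(opts$flies)
    if (!is.null(opts$seed)) cfg$synth$seed <- as.integer(opts$seed)
    scfg <- do.call(synth_config, cfg$synth)
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    cohort <- simulate_cohort(scfg)
    for (i in seq_along(cohort)) {
      save_pose(cohort[[i]]$pose,
                file.path(opts$out, sprintf("pose_fly%02d.h5", i)))
      truth <- ethogram(cohort[[i]]$truth$true_ethogram, fps = scfg$fps,
                        fly_id = sprintf("fly%02d", i),
                        frames_per_hour = scfg$fps * scfg$seconds_per_hour)
      write_ethogram_csv(truth, file.path(
        opts$out, sprintf("truth_fly%02d.csv", i)))
    }
    message("wrote ", length(cohort), " flies to ", opts$out)
  } else if (cmd == "run") {
    cfg <- if (!is.null(opts$config)) load_pipeline_config(opts$config)
    else default_pipeline_config(seed = as.integer(opts$seed %||% 1))
    run_pipeline(cfg, output_dir = opts$out)
  } else if (cmd == "boutfix") {
    etho <- read_ethogram_csv(opts[["in"]])
    fixed <- enforce_min_bout(etho, as.integer(opts[["min-frames"]] %||% 5))
    write_ethogram_csv(fixed, opts$out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
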