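# Non-compositional behavior statistics: Zeitgeber time, locomotion speed
# within locomotion bouts, per-group bout durations, and radial occupancy.

#' Zeitgeber time of a wall-clock timestamp
#'
#' ZT 0 is lights-on, ZT 12 lights-off; time wraps modulo 24 h and the day
#' index counts lights-on events since the experiment start (the first
#' lights-on at or before the first observation).
#'
#' @param clock Decimal hours since midnight of the first experimental day
#'   (may exceed 24 for later days).
#' @param lights_on_clock Lights-on wall-clock hour (default 8).
#' @return Data frame: `zt_hours` in [0, 24), `day_index` >= 1.
#' @export
zeitgeber_time <- function(clock, lights_on_clock = 8) {
  rel <- clock - lights_on_clock
  if (any(rel < 0)) stop("timestamp precedes the experiment's first lights-on")
  data.frame(zt_hours = rel %% 24, day_index = floor(rel / 24) + 1)
}

# Continuous ZT and day index per frame of a recording.
frame_zt <- function(n, t0_clock, frames_per_hour, lights_on_clock = 8) {
  rel <- (t0_clock - lights_on_clock) + (seq_len(n) - 1) / frames_per_hour
  list(zt = rel %% 24, day = floor(rel / 24) + 1)
}

# Expand a stride-resolution ethogram back to full frame rate.
expand_ethogram <- function(etho, factor, n_out = NULL) {
  labels <- rep(etho$labels, each = factor)
  if (!is.null(n_out)) labels <- labels[seq_len(min(n_out, length(labels)))]
  ethogram(labels, fps = etho$fps * factor, t0_clock = etho$t0_clock,
           fly_id = etho$fly_id, frames_per_hour = etho$frames_per_hour * factor)
}

#' Locomotion speed series
#'
#' Thorax speed (mm/s, displacement between consecutive frames times the
#' frame rate), averaged over a centered rolling window computed within
#' each locomotion bout -- windows never cross bout boundaries, and bouts
#' shorter than the window get their plain mean. Only frames labeled
#' `locomotion` are reported.
#'
#' @param pose A [pose_sequence()] aligned with `etho`.
#' @param etho An [ethogram()] of the same length.
#' @param window Rolling-mean window in frames (default 5).
#' @param lights_on_clock Lights-on hour, for ZT annotation.
#' @return Data frame: `frame`, `speed_mm_s`, `zt_hour` (integer hour),
#'   `day_index`.
#' @export
locomotion_speed <- function(pose, etho, window = 5, lights_on_clock = 8) {
  n <- n_frames(pose)
  stopifnot(length(etho$labels) == n)
  tj <- match("thorax", pose$node_names)
  x <- pose$coords[, tj, 1]; y <- pose$coords[, tj, 2]
  step <- c(0, sqrt(diff(x)^2 + diff(y)^2)) * pose$fps / pose$px_per_mm
  bouts <- extract_bouts(etho)
  loco <- bouts[bouts$behavior == "locomotion", , drop = FALSE]
  k <- (window - 1) %/% 2
  frames <- integer(0); speeds <- numeric(0)
  for (i in seq_len(nrow(loco))) {
    idx <- (loco$start[i] + 1L):loco$end[i]
    # displacements within the bout only: the step into the bout's first
    # frame references a non-locomotion frame and is discarded
    v <- step[idx]
    v[1] <- if (length(v) > 1L) v[2] else 0
    sm <- if (length(v) < window) rep(mean(v), length(v))
    else moving_gaussian_box(v, k)
    frames <- c(frames, idx)
    speeds <- c(speeds, sm)
  }
  zt <- frame_zt(n, etho$t0_clock, etho$frames_per_hour, lights_on_clock)
  data.frame(frame = frames, speed_mm_s = speeds,
             zt_hour = floor(zt$zt[frames]), day_index = zt$day[frames])
}

# Centered boxcar mean with shrinking windows at the ends.
moving_gaussian_box <- function(v, k) {
  m <- lag_matrix(v, k)
  rowMeans(m, na.rm = TRUE)
}

#' Grouped summary of a speed series
#'
#' @param speed Data frame from [locomotion_speed()].
#' @param by `"zt_hour"` or `"day_index"`.
#' @return Data frame: group, `mean_mm_s`, `se`, `n`.
#' @export
speed_by_group <- function(speed, by = c("zt_hour", "day_index")) {
  by <- match.arg(by)
  out <- do.call(rbind, lapply(split(speed$speed_mm_s, speed[[by]]), function(v) {
    data.frame(mean_mm_s = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  out[[by]] <- as.numeric(rownames(out))
  rownames(out) <- NULL
  out[, c(by, "mean_mm_s", "se", "n")]
}

#' Bout-duration statistics by hour or day
#'
#' Mean and standard error of bout durations (seconds) for one behavior,
#' grouped by the ZT hour (or day) containing the bout's start frame.
#'
#' @param etho An [ethogram()] (after [enforce_min_bout()]).
#' @param behavior Behavior label.
#' @param group_by `"zt_hour"` or `"day_index"`.
#' @param lights_on_clock Lights-on hour.
#' @return Data frame: group value, `mean_s`, `se_s`, `n_bouts`; groups
#'   without bouts are absent.
#' @export
bout_duration_stats <- function(etho, behavior,
                                group_by = c("zt_hour", "day_index"),
                                lights_on_clock = 8) {
  group_by <- match.arg(group_by)
  bouts <- extract_bouts(etho)
  bouts <- bouts[bouts$behavior == behavior, , drop = FALSE]
  if (nrow(bouts) == 0L) {
    return(data.frame(group = numeric(0), mean_s = numeric(0),
                      se_s = numeric(0), n_bouts = integer(0)))
  }
  zt <- frame_zt(length(etho$labels), etho$t0_clock, etho$frames_per_hour,
                 lights_on_clock)
  g <- if (group_by == "zt_hour") floor(zt$zt[bouts$start + 1L])
  else zt$day[bouts$start + 1L]
  dur_s <- bouts$duration_frames / etho$fps
  out <- do.call(rbind, lapply(split(dur_s, g), function(v) {
    data.frame(mean_s = mean(v),
               se_s = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n_bouts = length(v))
  }))
  out$group <- as.numeric(rownames(out))
  rownames(out) <- NULL
  out[, c("group", "mean_s", "se_s", "n_bouts")]
}

#' Radial occupancy and per-bin behavior composition
#'
#' Thorax radial position, normalized by the arena radius, binned into
#' `n_bins` equal-area annuli; returns per-bin frame counts and, when an
#' ethogram is supplied, the per-bin fraction of each label.
#'
#' @param pose A [pose_sequence()].
#' @param arena An [arena_geometry()].
#' @param etho Optional aligned [ethogram()].
#' @param n_bins Number of equal-area annuli (default 10).
#' @return List: `bin_outer_r` (outer relative radius per bin), `counts`,
#'   and `behavior_fractions` (bins x labels, or NULL).
#' @export
radial_occupancy <- function(pose, arena, etho = NULL, n_bins = 10) {
  r <- node_radius_px(pose, arena, "thorax") / arena$radius_px
  if (any(r > 1.05, na.rm = TRUE)) {
    warning("thorax outside arena by > 5%; clamping")
  }
  r <- pmin(r, 1)
  edges <- sqrt(seq_len(n_bins) / n_bins)
  bin <- findInterval(r, c(0, head(edges, -1)), rightmost.closed = FALSE)
  bin[is.na(r)] <- NA
  counts <- tabulate(bin, nbins = n_bins)
  fractions <- NULL
  if (!is.null(etho)) {
    stopifnot(length(etho$labels) == length(r))
    labs <- ethogram_alphabet()
    fractions <- matrix(0, n_bins, length(labs), dimnames = list(NULL, labs))
    for (b in seq_len(n_bins)) {
      sel <- !is.na(bin) & bin == b
      if (any(sel)) {
        fractions[b, ] <- as.numeric(
          table(factor(etho$labels[sel], levels = labs))) / sum(sel)
      }
    }
  }
  list(bin_outer_r = edges, counts = counts, behavior_fractions = fractions)
}
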