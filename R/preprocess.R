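# Pose cleaning: gap interpolation, median + Gaussian smoothing, and
# egocentric alignment. The stage order (interpolate -> smooth ->
# egocentrize) and all window parameters follow the pipeline's reference
# protocol for 100 Hz fly tracking.

# PCHIP (monotone piecewise-cubic Hermite) fill of one trace.
# limit = Inf fills all interior gaps; finite limit fills only runs of
# <= limit consecutive missing values flanked by observations.
# extend_ends holds leading/trailing missing runs at the nearest value.
pchip_fill <- function(y, limit = Inf, extend_ends = FALSE) {
  obs <- which(!is.na(y))
  if (length(obs) == 0L || length(obs) == length(y)) return(y)
  out <- y
  if (length(obs) >= 2L) {
    n <- length(y)
    miss <- is.na(y)
    # gap id and length per missing frame, vectorized over maximal NA runs
    r <- rle(miss)
    gap_len_by_frame <- rep(r$lengths, r$lengths)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    interior <- rep(r$values & run_start > 1L & run_end < n, r$lengths)
    fill <- miss & interior & gap_len_by_frame <= limit
    fill[seq_len(obs[1])] <- FALSE
    if (obs[length(obs)] < n) fill[obs[length(obs)]:n] <- FALSE
    if (any(fill)) {
      f <- stats::splinefun(obs, y[obs], method = "monoH.FC")
      out[fill] <- f(which(fill))
    }
  }
  if (extend_ends) {
    first <- obs[1]; last <- obs[length(obs)]
    if (first > 1L) out[seq_len(first - 1L)] <- y[first]
    if (last < length(y)) out[(last + 1L):length(y)] <- y[last]
  }
  out
}

#' Interpolate missing keypoints
#'
#' Head and thorax are fully interpolated with a monotone piecewise cubic
#' Hermite polynomial (PCHIP), with leading/trailing gaps held at the
#' nearest observed value (they anchor the egocentric transform and must be
#' complete). All other nodes except the proboscis are PCHIP-interpolated
#' only across interior gaps of at most `gap_limit` consecutive missing
#' frames; longer gaps stay missing. Proboscis gaps are filled with the
#' same-frame (post-interpolation) head location, representing a retracted
#' proboscis. Observed values are never modified.
#'
#' @param pose A [pose_sequence()].
#' @param gap_limit Maximum interior gap length filled on non-anchor nodes
#'   (default 5 frames).
#' @return The interpolated `pose_sequence`.
#' @export
interpolate_pose <- function(pose, gap_limit = 5) {
  coords <- pose$coords
  missing <- pose$missing
  nodes <- pose$node_names
  n <- n_frames(pose)
  if (n == 0L) return(pose)

  for (nd in c("head", "thorax")) {
    j <- match(nd, nodes)
    if (all(missing[, j])) {
      stop(sprintf("node '%s' has no observed frames; cannot egocentrize", nd))
    }
    for (d in 1:2) {
      coords[, j, d] <- pchip_fill(coords[, j, d], limit = Inf,
                                   extend_ends = TRUE)
    }
    missing[, j] <- FALSE
  }

  other <- setdiff(nodes, c("head", "thorax", "proboscis"))
  for (nd in other) {
    j <- match(nd, nodes)
    if (all(missing[, j])) {
      warning(sprintf("node '%s' has no observed frames; left missing", nd))
      next
    }
    filled_x <- pchip_fill(coords[, j, 1], limit = gap_limit)
    filled_y <- pchip_fill(coords[, j, 2], limit = gap_limit)
    newly <- missing[, j] & !is.na(filled_x) & !is.na(filled_y)
    coords[, j, 1] <- filled_x
    coords[, j, 2] <- filled_y
    missing[newly, j] <- FALSE
  }

  pj <- match("proboscis", nodes)
  hj <- match("head", nodes)
  fill <- missing[, pj]
  coords[fill, pj, 1] <- coords[fill, hj, 1]
  coords[fill, pj, 2] <- coords[fill, hj, 2]
  missing[fill, pj] <- FALSE

  pose_sequence(coords, missing, node_names = nodes, fps = pose$fps,
                px_per_mm = pose$px_per_mm, t0_clock = pose$t0_clock,
                fly_id = pose$fly_id, frames_per_hour = pose$frames_per_hour)
}

# n x (2k+1) matrix of lagged copies of y (NA outside the series).
lag_matrix <- function(y, k) {
  n <- length(y)
  m <- matrix(NA_real_, n, 2 * k + 1)
  for (s in -k:k) {
    src <- seq_len(n) + s
    ok <- src >= 1 & src <= n
    m[ok, s + k + 1] <- y[src[ok]]
  }
  m
}

# Centered moving median, window 2k+1, NA-tolerant, shrink at boundaries.
# Runs the fast C implementation (stats::runmed) per contiguous observed
# segment so that missing frames never enter a window.
moving_median <- function(y, k = 2) {
  out <- rep(NA_real_, length(y))
  segs <- true_runs(!is.na(y))
  win <- 2 * k + 1
  for (s in seq_len(nrow(segs))) {
    idx <- (segs$start[s] + 1L):segs$end[s]
    v <- y[idx]
    out[idx] <- if (length(v) >= win) {
      as.numeric(stats::runmed(v, win, endrule = "median"))
    } else {
      vapply(seq_along(v), function(i) {
        median(v[max(1, i - k):min(length(v), i + k)])
      }, 0)
    }
  }
  out
}

# Centered Gaussian filter, kernel renormalized over present samples
# (missing frames and series boundaries contribute zero weight).
moving_gaussian <- function(y, k = 2, sd = 1) {
  w <- dnorm(-k:k, 0, sd)
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0)
  pad <- rep(0, k)
  num <- stats::filter(c(pad, y0, pad), w, sides = 2)
  den <- stats::filter(c(pad, as.numeric(obs), pad), w, sides = 2)
  idx <- (k + 1):(k + length(y))
  out <- as.numeric(num[idx] / den[idx])
  out[den[idx] <= 0] <- NA_real_
  out
}

#' Smooth a pose sequence
#'
#' Per node and coordinate: a centered median filter (window 5) followed by
#' a centered Gaussian filter (sd 1 sample, window 5, kernel renormalized at
#' boundaries and around missing samples). Missing frames stay missing and
#' never contribute to a window.
#'
#' @param pose An interpolated [pose_sequence()].
#' @param median_window,gauss_window Window sizes (odd; default 5).
#' @param gauss_sd Gaussian kernel SD in samples (default 1).
#' @return The smoothed `pose_sequence`.
#' @export
smooth_pose <- function(pose, median_window = 5, gauss_window = 5,
                        gauss_sd = 1) {
  stopifnot(median_window %% 2 == 1, gauss_window %% 2 == 1)
  km <- (median_window - 1) %/% 2
  kg <- (gauss_window - 1) %/% 2
  coords <- pose$coords
  for (j in seq_along(pose$node_names)) {
    miss <- pose$missing[, j]
    for (d in 1:2) {
      y <- coords[, j, d]
      y[miss] <- NA_real_
      y <- moving_gaussian(moving_median(y, km), kg, gauss_sd)
      y[miss] <- NA_real_
      coords[, j, d] <- y
    }
  }
  pose_sequence(coords, pose$missing, node_names = pose$node_names,
                fps = pose$fps, px_per_mm = pose$px_per_mm,
                t0_clock = pose$t0_clock, fly_id = pose$fly_id,
                frames_per_hour = pose$frames_per_hour)
}

#' Egocentrize a pose sequence
#'
#' Per frame: translate so the thorax sits at (0, 0), rotate so the
#' thorax-to-head axis falls along the positive x-axis, and convert to mm.
#' The applied heading and origin are recorded, making the transform
#' invertible via [egocentrize_inverse()]. A frame where head and thorax
#' coincide reuses the previous frame's heading (an error on frame 1).
#'
#' @param pose An interpolated [pose_sequence()] (head and thorax complete).
#' @return An object of class `egocentric_pose`: `coords` (frames x 14 x 2,
#'   mm, body frame), `heading` (radians), `origin` (thorax px), plus the
#'   pose metadata and missing mask.
#' @export
egocentrize <- function(pose) {
  nodes <- pose$node_names
  hj <- match("head", nodes)
  tj <- match("thorax", nodes)
  if (any(pose$missing[, hj]) || any(pose$missing[, tj])) {
    stop("head and thorax must be fully observed; run interpolate_pose first")
  }
  n <- n_frames(pose)
  dx <- pose$coords[, hj, 1] - pose$coords[, tj, 1]
  dy <- pose$coords[, hj, 2] - pose$coords[, tj, 2]
  zero <- dx == 0 & dy == 0
  heading <- atan2(dy, dx)
  if (any(zero)) {
    if (zero[1]) stop("head coincides with thorax on frame 1; heading undefined")
    for (i in which(zero)) heading[i] <- heading[i - 1]
  }
  ch <- cos(-heading); sh <- sin(-heading)
  origin <- pose$coords[, tj, , drop = TRUE]
  if (n == 1L) origin <- matrix(origin, 1, 2)
  coords <- array(NA_real_, dim(pose$coords))
  for (j in seq_along(nodes)) {
    x <- pose$coords[, j, 1] - origin[, 1]
    y <- pose$coords[, j, 2] - origin[, 2]
    coords[, j, 1] <- (ch * x - sh * y) / pose$px_per_mm
    coords[, j, 2] <- (sh * x + ch * y) / pose$px_per_mm
  }
  dimnames(coords) <- list(NULL, nodes, c("x", "y"))
  structure(list(coords = coords, heading = heading, origin = origin,
                 missing = pose$missing, node_names = nodes, fps = pose$fps,
                 px_per_mm = pose$px_per_mm, t0_clock = pose$t0_clock,
                 fly_id = pose$fly_id, frames_per_hour = pose$frames_per_hour),
            class = "egocentric_pose")
}

#' @rdname egocentrize
#' @param ego An `egocentric_pose`.
#' @return `egocentrize_inverse()`: the reconstructed world-frame
#'   `pose_sequence` (px).
#' @export
egocentrize_inverse <- function(ego) {
  ch <- cos(ego$heading); sh <- sin(ego$heading)
  coords <- array(NA_real_, dim(ego$coords))
  for (j in seq_along(ego$node_names)) {
    x <- ego$coords[, j, 1] * ego$px_per_mm
    y <- ego$coords[, j, 2] * ego$px_per_mm
    coords[, j, 1] <- ch * x - sh * y + ego$origin[, 1]
    coords[, j, 2] <- sh * x + ch * y + ego$origin[, 2]
  }
  pose_sequence(coords, ego$missing, node_names = ego$node_names,
                fps = ego$fps, px_per_mm = ego$px_per_mm,
                t0_clock = ego$t0_clock, fly_id = ego$fly_id,
                frames_per_hour = ego$frames_per_hour)
}
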