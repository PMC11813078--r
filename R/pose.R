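# Pose containers and arena geometry.

#' Construct a pose sequence
#'
#' The central raw-data container: pixel coordinates of the 14-node skeleton
#' over time plus a missingness mask and recording calibration. Coordinates
#' at masked entries are `NA`; unmasked entries must be finite.
#'
#' @param coords Numeric array, frames x 14 nodes x 2 (px).
#' @param missing Logical matrix, frames x 14; `TRUE` = keypoint not tracked.
#' @param node_names Ordered node names; defaults to [skeleton_nodes()].
#' @param fps Frame rate (Hz).
#' @param px_per_mm Spatial calibration.
#' @param t0_clock Wall-clock of frame 0, decimal hours since midnight of the
#'   first experimental day.
#' @param fly_id Identifier string.
#' @param frames_per_hour Frames representing one ZT hour (equals
#'   `fps * 3600` for real-time recordings; smaller for compressed synthetic
#'   fixtures).
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, missing = NULL, node_names = skeleton_nodes(),
                          fps = 100, px_per_mm = 28.25, t0_clock = 8,
                          fly_id = "fly1", frames_per_hour = fps * 3600) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 2, fps > 0,
            px_per_mm > 0)
  n_nodes <- dim(coords)[2]
  if (length(node_names) != n_nodes || anyDuplicated(node_names)) {
    stop("node_names must be unique and match the coordinate array")
  }
  if (!all(c("head", "thorax", "proboscis") %in% node_names)) {
    stop("skeleton must include head, thorax and proboscis nodes")
  }
  if (is.null(missing)) {
    missing <- is.na(coords[, , 1, drop = FALSE])[, , 1] |
      is.na(coords[, , 2, drop = FALSE])[, , 1]
    dim(missing) <- dim(coords)[1:2]
  }
  stopifnot(identical(dim(missing), dim(coords)[1:2]))
  obs <- !missing
  if (any(!is.finite(coords[, , 1][obs])) || any(!is.finite(coords[, , 2][obs]))) {
    stop("coords must be finite wherever missing is FALSE")
  }
  dimnames(coords) <- list(NULL, node_names, c("x", "y"))
  colnames(missing) <- node_names
  structure(list(coords = coords, missing = missing, node_names = node_names,
                 fps = fps, px_per_mm = px_per_mm, t0_clock = t0_clock,
                 fly_id = fly_id, frames_per_hour = frames_per_hour),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  n <- dim(x$coords)[1]
  cat(sprintf(
    "<pose_sequence> %s: %d frames (%.1f s at %g fps), %d nodes, %.1f%% missing\n",
    x$fly_id, n, n / x$fps, x$fps, length(x$node_names),
    100 * mean(x$missing)))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param pose A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(pose) dim(pose$coords)[1]

#' Arena geometry
#'
#' @param center_px Arena center (x, y) in px.
#' @param radius_px Arena radius in px.
#' @param px_per_mm Calibration.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(center_px = c(0, 0), radius_px = 12.5 * 28.25,
                           px_per_mm = 28.25) {
  if (radius_px <= 0) stop("arena radius must be > 0")
  structure(list(center_px = center_px, radius_px = radius_px,
                 px_per_mm = px_per_mm), class = "arena_geometry")
}

#' @rdname arena_geometry
#' @param config A `synth_config`; builds the matching geometry.
#' @export
arena_from_config <- function(config) {
  arena_geometry(center_px = c(0, 0),
                 radius_px = config$arena_diameter_mm / 2 * config$px_per_mm,
                 px_per_mm = config$px_per_mm)
}

# Radial distance of one node from the arena center, px.
node_radius_px <- function(pose, arena, node = "thorax") {
  xy <- pose$coords[, node, , drop = FALSE]
  sqrt((xy[, 1, 1] - arena$center_px[1])^2 + (xy[, 1, 2] - arena$center_px[2])^2)
}
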