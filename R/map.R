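# The stereotyped-behavior map: assemble a filtered, coverage-balanced
# training set of spectral feature vectors; embed it in 2-D with UMAP;
# segment the training-point density into regions; and assign every frame
# of a dataset to a behavior, idle, edge, or unstereotyped.

#' Assemble the behavior-map training set
#'
#' Each group (one fly-hour) contributes points in three stages: frames
#' flagged on-edge or with total spectral amplitude below the idle
#' threshold are removed; at most `cap` of the remaining frames are drawn
#' uniformly (seeded); from these, `quota` points are importance-sampled to
#' equalize coverage of postural-dynamics space. Groups left empty after
#' filtering contribute nothing.
#'
#' @param groups List; each element needs `power` (frames x channels
#'   matrix), `valid`, `edge` (logical per frame), `amplitude` (mm^2 per
#'   frame), and optionally `fly_id` and `hour`.
#' @param amplitude_threshold Idle cut in mm^2 (default 0.5012).
#' @param cap Per-group uniform subsample cap (default 36000).
#' @param quota Per-group importance-sample quota (default 454).
#' @param seed RNG seed.
#' @param density_k,density_dim Passed to [importance_sample()].
#' @return Object of class `training_set`: `features` (points x channels),
#'   `provenance` (fly, hour, frame), `quota`, `n_groups`.
#' @export
assemble_training_set <- function(groups, amplitude_threshold = 0.5012,
                                  cap = 36000, quota = 454, seed = 1,
                                  density_k = 20, density_dim = 2) {
  feats <- vector("list", length(groups))
  prov <- vector("list", length(groups))
  with_seed(seed, {
    for (g in seq_along(groups)) {
      gr <- groups[[g]]
      n <- nrow(gr$power)
      valid <- gr$valid %||% rep(TRUE, n)
      edge <- gr$edge %||% rep(FALSE, n)
      amp <- gr$amplitude
      keep <- which(valid & !edge & !is.na(amp) & amp >= amplitude_threshold)
      if (length(keep) == 0L) {
        warning(sprintf("group %d empty after filtering; contributes 0 points", g))
        next
      }
      if (length(keep) > cap) keep <- sort(sample(keep, cap))
      sub <- gr$power[keep, , drop = FALSE]
      sel <- importance_sample(sub, quota, seed = sample.int(1e9, 1),
                               k = density_k, density_dim = density_dim)
      feats[[g]] <- sub[sel, , drop = FALSE]
      frame_ids <- if (!is.null(gr$frames)) gr$frames[keep[sel]] else keep[sel]
      prov[[g]] <- data.frame(fly_id = gr$fly_id %||% as.character(g),
                              hour = gr$hour %||% NA_integer_,
                              frame = frame_ids)
    }
  })
  structure(list(features = do.call(rbind, feats),
                 provenance = do.call(rbind, prov),
                 quota = quota, n_groups = length(groups)),
            class = "training_set")
}

#' Importance-sample points to equalize coverage
#'
#' Estimates the local density of each point from its distance to the k-th
#' nearest neighbor and samples `quota` points without replacement with
#' probability proportional to the inverse density, enriching sparse regions
#' of dynamics space. Density uses a fixed effective dimension
#' (`density_dim`, default 2) so that weights stay numerically stable for
#' high-dimensional spectral features.
#'
#' @param x Feature matrix (points x dims).
#' @param quota Number of points to select; `quota >= nrow(x)` returns all.
#' @param seed RNG seed.
#' @param k Neighbor rank for the density estimate (default 20).
#' @param density_dim Effective dimension of the density model.
#' @return Integer row indices of the selected points.
#' @export
importance_sample <- function(x, quota, seed = 1, k = 20, density_dim = 2) {
  n <- nrow(x)
  if (quota <= 0) return(integer(0))
  if (quota >= n) return(seq_len(n))
  kk <- min(k, n - 1L)
  d_k <- FNN::knn.dist(x, k = kk)[, kk]
  d_k[d_k <= 0 | !is.finite(d_k)] <- min(d_k[d_k > 0 & is.finite(d_k)], 1e-12)
  w <- d_k^density_dim  # 1/density up to a constant
  with_seed(seed, sort(sample.int(n, quota, prob = w)))
}

#' Fit the 2-D behavioral embedding
#'
#' UMAP embedding of the training set with a retained model for
#' out-of-sample transformation of new feature vectors; deterministic for a
#' fixed seed (single-threaded layout optimization).
#'
#' @param train A `training_set` (or bare feature matrix).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed RNG seed.
#' @return Object of class `embedded_map`: `train_coords` (points x 2),
#'   `model` (uwot model for [embed_points()]), `hyperparameters`, `seed`.
#' @export
fit_embedding <- function(train, n_neighbors = 15, min_dist = 0.1, seed = 1) {
  x <- if (inherits(train, "training_set")) train$features else train
  if (is.null(dim(x)) || nrow(x) < 10L) stop("need at least 10 training points")
  if (all(apply(x, 2, function(v) max(v) - min(v)) == 0)) {
    stop("degenerate training set: all feature vectors identical")
  }
  nn <- min(n_neighbors, nrow(x) - 1L)
  model <- with_seed(seed, uwot::umap(x, n_neighbors = nn,
                                      min_dist = min_dist, n_threads = 1,
                                      n_sgd_threads = 0, ret_model = TRUE))
  structure(list(train_coords = model$embedding, model = model,
                 hyperparameters = list(n_neighbors = nn, min_dist = min_dist),
                 seed = seed),
            class = "embedded_map")
}

#' @rdname fit_embedding
#' @param map An `embedded_map`.
#' @param x New feature matrix (same channels as training).
#' @return `embed_points()`: matrix of 2-D coordinates.
#' @export
embed_points <- function(map, x) {
  with_seed(map$seed, uwot::umap_transform(x, map$model, n_threads = 1))
}

# Sliding local mean (boxcar, window `block` cells per axis, renormalized
# at the grid boundary) used by the adaptive threshold.
local_mean_grid <- function(z, block) {
  k <- max(1L, block %/% 2L)
  box1 <- function(m) {
    pad <- matrix(0, k, ncol(m))
    num <- stats::filter(rbind(pad, m, pad), rep(1, 2 * k + 1), sides = 2)
    cnt <- stats::filter(rbind(pad, matrix(1, nrow(m), ncol(m)), pad),
                         rep(1, 2 * k + 1), sides = 2)
    (num / cnt)[(k + 1):(k + nrow(m)), , drop = FALSE]
  }
  t(box1(t(box1(z))))
}

#' Segment the embedding density into behavior regions
#'
#' Kernel density estimate of the training points on a `grid_size`^2 grid
#' over a padded bounding box. Cells of extreme low density -- below the
#' `low_density_quantile` quantile of the density observed at the training
#' points themselves -- are zeroed. A local adaptive threshold (sliding
#' `adaptive_block`-cell mean minus `adaptive_offset` times the peak
#' density) isolates density peaks, whose 4-connected components seed
#' regions 1..K; every remaining above-floor cell then joins its nearest
#' seed, so the regions partition the above-threshold density support
#' (0 = unstereotyped background).
#'
#' @param map An `embedded_map` (or points x 2 matrix).
#' @param grid_size Cells per axis (default 512).
#' @param kde_factor Multiplier on the per-axis Scott bandwidth.
#' @param low_density_quantile Quantile of positive cell densities zeroed
#'   as extreme low density (default 0.05).
#' @param adaptive_block Block size in cells for the local threshold.
#' @param adaptive_offset Offset subtracted from the block mean, as a
#'   fraction of the maximum density (default 0.2).
#' @return Object of class `region_map`: `density`, `labels` (grid
#'   matrices), `extent` (xmin, xmax, ymin, ymax), `kde_bandwidth`,
#'   `behavior_names` (NULL until labeled), `n_regions`.
#' @export
segment_density <- function(map, grid_size = 512, kde_factor = 1,
                            low_density_quantile = 0.05,
                            adaptive_block = 32, adaptive_offset = 0.2) {
  pts <- if (inherits(map, "embedded_map")) map$train_coords else map
  if (is.null(pts) || nrow(pts) == 0L) {
    z <- matrix(0, grid_size, grid_size)
    return(structure(list(density = z, labels = z, extent = c(0, 1, 0, 1),
                          kde_bandwidth = c(NA, NA), behavior_names = NULL,
                          n_regions = 0L), class = "region_map"))
  }
  pad <- 0.05
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  rx <- rx + c(-1, 1) * max(diff(rx), 1e-6) * pad
  ry <- ry + c(-1, 1) * max(diff(ry), 1e-6) * pad
  n <- nrow(pts)
  bw <- c(sd(pts[, 1]), sd(pts[, 2])) * n^(-1 / 6) * kde_factor
  bw[bw <= 0 | !is.finite(bw)] <- 1e-3
  if (any(bw <= 0)) stop("KDE bandwidth must be > 0")
  # MASS::kde2d parameterizes bandwidth as full width = 4 * sd
  kde <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bw,
                     n = grid_size, lims = c(rx, ry))
  z <- kde$z
  z[z < 0] <- 0
  # floor: density below what all but a `low_density_quantile` fraction of
  # the training points themselves sit in counts as background
  ext0 <- c(rx[1], rx[2], ry[1], ry[2])
  pt_cells <- grid_cell_index(pts, ext0, dim(z))
  pt_dens <- z[pt_cells]
  floor_d <- quantile(pt_dens, low_density_quantile)
  z[z < floor_d] <- 0
  bm <- local_mean_grid(z, adaptive_block)
  seeds <- z > 0 & z > bm - adaptive_offset * max(z)
  labels <- connected_components_grid(seeds)
  # extend seed labels over the whole above-floor support (nearest seed)
  support <- which(z > 0 & labels == 0L)
  seed_cells <- which(labels > 0L)
  if (length(support) && length(seed_cells)) {
    g1 <- dim(z)[1]
    to_rc <- function(ix) cbind((ix - 1L) %% g1 + 1L, (ix - 1L) %/% g1 + 1L)
    nn <- FNN::get.knnx(to_rc(seed_cells), to_rc(support), k = 1)
    labels[support] <- labels[seed_cells][nn$nn.index[, 1]]
  }
  structure(list(density = z, labels = labels,
                 extent = c(rx[1], rx[2], ry[1], ry[2]),
                 kde_bandwidth = bw, behavior_names = NULL,
                 n_regions = max(labels)), class = "region_map")
}

# Label 4-connected components of a logical grid, largest region first.
connected_components_grid <- function(keep) {
  g <- dim(keep)
  lab <- matrix(0L, g[1], g[2])
  on <- which(keep)
  if (!length(on)) return(lab)
  id <- match(seq_len(g[1] * g[2]), on)  # cell -> vertex index or NA
  row <- (on - 1L) %% g[1] + 1L
  col <- (on - 1L) %/% g[1] + 1L
  edges <- integer(0)
  right <- on + g[1]
  ok <- col < g[2] & !is.na(id[pmin(right, g[1] * g[2])])
  down <- on + 1L
  ok2 <- row < g[1] & !is.na(id[pmin(down, g[1] * g[2])])
  edges <- c(rbind(id[on[ok]], id[right[ok]]),
             rbind(id[on[ok2]], id[down[ok2]]))
  gr <- igraph::make_graph(edges, n = length(on), directed = FALSE)
  comp <- igraph::components(gr)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- match(comp$membership, ord)
  lab[on] <- relabel
  lab
}

# Linear grid-cell index of 2-D points (NA outside the extent).
grid_cell_index <- function(coords, ext, g) {
  x <- coords[, 1]; y <- coords[, 2]
  ok <- is.finite(x) & is.finite(y) & x >= ext[1] & x <= ext[2] &
    y >= ext[3] & y <= ext[4]
  ix <- pmin(g[1], floor((x - ext[1]) / (ext[2] - ext[1]) * g[1]) + 1L)
  iy <- pmin(g[2], floor((y - ext[3]) / (ext[4] - ext[3]) * g[2]) + 1L)
  out <- rep(NA_integer_, nrow(coords))
  out[ok] <- ix[ok] + (iy[ok] - 1L) * g[1]
  out
}

# Region id of 2-D points (0 = outside extent or background).
region_of_points <- function(regions, coords) {
  cells <- grid_cell_index(coords, regions$extent, dim(regions$labels))
  out <- integer(nrow(coords))
  ok <- !is.na(cells)
  out[ok] <- regions$labels[cells[ok]]
  out
}

#' Name map regions by majority vote against reference labels
#'
#' Production use names regions from manually reviewed exemplar clips; for
#' validation the generator's ground truth stands in: each region is named
#' by the majority reference label of the training points inside it.
#' Regions without any point keep the name `"unstereotyped"`.
#'
#' @param regions A `region_map`.
#' @param coords 2-D coordinates of reference points (e.g. train_coords).
#' @param ref_labels Reference behavior label per point.
#' @return The `region_map` with `behavior_names` set (named character
#'   vector indexed by region id).
#' @export
label_regions <- function(regions, coords, ref_labels) {
  k <- regions$n_regions
  nm <- setNames(rep("unstereotyped", k), seq_len(k))
  rid <- region_of_points(regions, coords)
  for (r in seq_len(k)) {
    inside <- rid == r
    if (any(inside)) {
      tab <- table(ref_labels[inside])
      nm[r] <- names(tab)[which.max(tab)]
    }
  }
  regions$behavior_names <- nm
  regions
}

#' Assign every frame to a behavior
#'
#' Per-frame precedence: an edge flag wins; then frames with invalid
#' features become unstereotyped; then total amplitude below the idle
#' threshold gives idle (sub-threshold frames are never embedded); the rest
#' are embedded out-of-sample and looked up in the region map. Background
#' (region 0) and out-of-extent points are unstereotyped; regions named
#' "idle" (tracking-error clusters) merge into idle.
#'
#' @param power Feature matrix (frames x channels).
#' @param valid Logical per frame (spectral window occupancy).
#' @param edge_flags Logical per frame.
#' @param amplitude Total spectral amplitude per frame (mm^2).
#' @param map An `embedded_map`.
#' @param regions A labeled `region_map`.
#' @param amplitude_threshold Idle cut (mm^2).
#' @param batch_size Frames embedded per batch.
#' @return Character vector of per-frame labels.
#' @export
assign_behaviors <- function(power, valid, edge_flags, amplitude, map,
                             regions, amplitude_threshold = 0.5012,
                             batch_size = 20000) {
  if (is.null(regions$behavior_names)) {
    stop("regions are unlabeled; run label_regions() first (regions 1..",
         regions$n_regions, ")")
  }
  n <- nrow(power)
  out <- rep("unstereotyped", n)
  edge_flags <- edge_flags %||% rep(FALSE, n)
  valid <- valid %||% rep(TRUE, n)
  idle_mask <- !edge_flags & valid & !is.na(amplitude) &
    amplitude < amplitude_threshold
  out[idle_mask] <- "idle"
  out[edge_flags] <- "edge"
  todo <- which(!edge_flags & valid & !idle_mask & !is.na(amplitude))
  for (start in seq(1L, length(todo), by = batch_size)) {
    idx <- todo[start:min(length(todo), start + batch_size - 1L)]
    xy <- embed_points(map, power[idx, , drop = FALSE])
    rid <- region_of_points(regions, xy)
    lab <- rep("unstereotyped", length(idx))
    hit <- rid > 0
    lab[hit] <- unname(regions$behavior_names[rid[hit]])
    out[idx] <- lab
  }
  out
}
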