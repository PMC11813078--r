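# Wall ("edge") detection. Flies walking on the arena wall are seen side-on
# and tracked unreliably; such frames are flagged and excluded from behavior
# mapping. Features per frame: all pairwise distances among the 13
# non-proboscis nodes (78), per-node speeds (13), and per-node distances to
# the arena boundary (13) -- 104 values, all in mm or mm/s, all invariant to
# rotation about the arena center and to a common translation of pose and
# arena.

#' Build edge-detection features
#'
#' @param pose An interpolated [pose_sequence()].
#' @param arena An [arena_geometry()].
#' @return Matrix frames x 104 (`edge_features` class attribute retained as
#'   a plain matrix); rows with any missing non-proboscis node are all-`NA`.
#' @export
build_edge_features <- function(pose, arena) {
  if (arena$radius_px <= 0) stop("arena radius must be > 0")
  nodes <- setdiff(pose$node_names, "proboscis")
  k <- length(nodes)
  n <- n_frames(pose)
  ppm <- pose$px_per_mm
  idx <- match(nodes, pose$node_names)
  x <- pose$coords[, idx, 1, drop = FALSE][, , 1, drop = TRUE]
  y <- pose$coords[, idx, 2, drop = FALSE][, , 1, drop = TRUE]
  if (n == 1L) { x <- matrix(x, 1); y <- matrix(y, 1) }

  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  feat <- matrix(NA_real_, n, np + k + k)
  cn <- character(np + k + k)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    feat[, p] <- sqrt((x[, i] - x[, j])^2 + (y[, i] - y[, j])^2) / ppm
    cn[p] <- paste0("dist_", nodes[i], "_", nodes[j])
  }
  # centered-difference speeds (one-sided at the ends), mm/s
  for (i in seq_len(k)) {
    sp <- rep(NA_real_, n)
    if (n >= 3L) {
      dx <- (x[3:n, i] - x[1:(n - 2), i]) / 2
      dy <- (y[3:n, i] - y[1:(n - 2), i]) / 2
      sp[2:(n - 1)] <- sqrt(dx^2 + dy^2) * pose$fps / ppm
    }
    if (n >= 2L) {
      sp[1] <- sqrt((x[2, i] - x[1, i])^2 + (y[2, i] - y[1, i])^2) * pose$fps / ppm
      sp[n] <- sqrt((x[n, i] - x[n - 1, i])^2 + (y[n, i] - y[n - 1, i])^2) *
        pose$fps / ppm
    } else if (n == 1L) sp[1] <- 0
    feat[, np + i] <- sp
    cn[np + i] <- paste0("speed_", nodes[i])
  }
  for (i in seq_len(k)) {
    r <- sqrt((x[, i] - arena$center_px[1])^2 + (y[, i] - arena$center_px[2])^2)
    feat[, np + k + i] <- pmax(0, arena$radius_px - r) / ppm
    cn[np + k + i] <- paste0("edgedist_", nodes[i])
  }
  colnames(feat) <- cn
  incomplete <- rowSums(pose$missing[, idx, drop = FALSE]) > 0
  feat[incomplete, ] <- NA_real_
  feat
}

# Squared-hinge linear SVM fit by BFGS; returns list(w, b).
fit_linear_svm <- function(x, y, lambda = 1e-3) {
  yy <- ifelse(y, 1, -1)
  d <- ncol(x)
  obj <- function(par) {
    w <- par[1:d]; b <- par[d + 1]
    marg <- 1 - yy * (x %*% w + b)
    mean(pmax(0, marg)^2) + lambda * sum(w^2)
  }
  grad <- function(par) {
    w <- par[1:d]; b <- par[d + 1]
    marg <- as.vector(1 - yy * (x %*% w + b))
    act <- pmax(0, marg)
    gw <- -2 * crossprod(x, act * yy) / nrow(x) + 2 * lambda * w
    gb <- -2 * mean(act * yy)
    c(gw, gb)
  }
  fit <- optim(rep(0, d + 1), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[1:d], b = fit$par[d + 1])
}

#' Train the edge classifier
#'
#' Standardizes features and fits a max-margin linear classifier
#' (squared-hinge SVM) on a stratified 80% of the data; the remaining 20%
#' provides the held-out accuracy.
#'
#' @param features Complete feature matrix (rows with `NA` are dropped).
#' @param labels Logical (or 0/1) per row; `TRUE` = on edge.
#' @param seed RNG seed for the split.
#' @param lambda Ridge penalty on the weights.
#' @return Object of class `edge_model` with elements `w`, `b`, `center`,
#'   `scale`, `heldout_accuracy`, `n_train`, `class_balance`, `seed`.
#' @export
train_edge_classifier <- function(features, labels, seed = 1, lambda = 1e-3) {
  keep <- complete.cases(features)
  x <- features[keep, , drop = FALSE]
  y <- as.logical(labels)[keep]
  if (length(unique(y)) < 2L) stop("both on- and off-edge examples required")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, ctr, scl)
  with_seed(seed, {
    test_idx <- unlist(lapply(c(TRUE, FALSE), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(0.2 * length(idx))))
    }))
    train_idx <- setdiff(seq_along(y), test_idx)
    fit <- fit_linear_svm(xs[train_idx, , drop = FALSE], y[train_idx], lambda)
    pred <- as.vector(xs[test_idx, , drop = FALSE] %*% fit$w + fit$b) > 0
    acc <- mean(pred == y[test_idx])
    structure(list(w = fit$w, b = fit$b, center = ctr, scale = scl,
                   heldout_accuracy = acc, n_train = length(train_idx),
                   class_balance = mean(y), seed = seed),
              class = "edge_model")
  })
}

#' Predict edge frames
#'
#' Frames with incomplete features are conservatively flagged as on-edge
#' (occlusion correlates with wall visits); otherwise the trained classifier
#' decides.
#'
#' @param model An `edge_model`.
#' @param features Feature matrix from [build_edge_features()].
#' @return Logical vector, `TRUE` = on edge.
#' @export
predict_edge <- function(model, features) {
  if (ncol(features) != length(model$w)) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(features), length(model$w)))
  }
  out <- rep(TRUE, nrow(features))
  ok <- complete.cases(features)
  if (any(ok)) {
    xs <- scale(features[ok, , drop = FALSE], model$center, model$scale)
    out[ok] <- as.vector(xs %*% model$w + model$b) > 0
  }
  out
}

#' @export
print.edge_model <- function(x, ...) {
  cat(sprintf(
    "<edge_model> linear SVM on %d features; held-out accuracy %.3f (n_train %d)\n",
    length(x$w), x$heldout_accuracy, x$n_train))
  invisible(x)
}
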