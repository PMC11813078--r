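# Compositional analysis of fly-hour ethograms. Hourly behavior fractions
# live on the 7-part simplex; averages are geometric means, geometry is
# log-ratio (CLR/ILR), and principal components use a Minimum Covariance
# Determinant estimate of the ILR covariance so that outlying fly-hours
# (death, tracking failures) do not dominate.

closure <- function(x) {
  if (is.matrix(x)) x / rowSums(x) else x / sum(x)
}

#' Hourly behavior compositions from an ethogram
#'
#' For each (fly, day, ZT hour): the fraction of frames in each of the seven
#' behaviors, computed over frames not labeled `edge` or `unstereotyped`,
#' closed to sum 1. Hours retaining fewer than `min_frames_frac` of their
#' frames are dropped. Zeros are then replaced multiplicatively: each zero
#' part becomes `delta_j` (half the smallest observed nonzero fraction of
#' that part across the table) and nonzero parts are rescaled.
#'
#' @param etho An [ethogram()].
#' @param lights_on_clock Wall-clock hour of lights-on (ZT 0).
#' @param min_frames_frac Minimum usable-frame fraction per hour.
#' @return Object of class `composition_table`: `parts` (hours x 7, strictly
#'   positive rows summing to 1) and `meta` (`fly_id`, `day_index`,
#'   `zt_hour`, `n_frames_used`).
#' @export
hourly_compositions <- function(etho, lights_on_clock = 8,
                                min_frames_frac = 0.1) {
  alpha <- behavior_alphabet()
  n <- length(etho$labels)
  fph <- etho$frames_per_hour
  hour_index <- floor((seq_len(n) - 1) / fph)
  offset <- etho$t0_clock - lights_on_clock
  hours <- sort(unique(hour_index))
  hfac <- factor(hour_index, levels = hours)
  xtab <- table(hfac, factor(etho$labels, levels = ethogram_alphabet()))
  hour_n <- as.integer(rowSums(xtab))
  counts <- xtab[, alpha, drop = FALSE]
  used <- as.integer(rowSums(counts))
  rows <- list(); meta <- list()
  for (k in seq_along(hours)) {
    h <- hours[k]
    if (used[k] < min_frames_frac * min(fph, hour_n[k])) {
      warning(sprintf("hour %d dropped: only %d usable frames", h, used[k]))
      next
    }
    rows[[length(rows) + 1L]] <- as.numeric(counts[k, ]) / used[k]
    meta[[length(meta) + 1L]] <- data.frame(
      fly_id = etho$fly_id, day_index = floor((offset + h) / 24) + 1,
      zt_hour = (offset + h) %% 24, n_frames_used = used[k])
  }
  parts <- do.call(rbind, rows)
  if (is.null(parts)) {
    parts <- matrix(numeric(0), 0, length(alpha))
  }
  colnames(parts) <- alpha
  composition_table(replace_zeros(parts), do.call(rbind, meta),
                    raw_parts = parts)
}

#' @rdname hourly_compositions
#' @param parts Hours x parts matrix (positive rows summing to 1).
#' @param meta Data frame aligned with `parts`.
#' @param raw_parts Optional pre-zero-replacement fractions (may contain
#'   exact zeros), kept for reporting.
#' @export
composition_table <- function(parts, meta = NULL, raw_parts = NULL) {
  if (nrow(parts) > 0) {
    stopifnot(all(parts > 0), all(abs(rowSums(parts) - 1) < 1e-9))
  }
  if (is.null(meta)) {
    n <- nrow(parts)
    meta <- data.frame(fly_id = rep("fly1", n), day_index = rep(1, n),
                       zt_hour = rep(NA_real_, n),
                       n_frames_used = rep(NA_integer_, n))
  }
  structure(list(parts = parts, meta = meta, raw_parts = raw_parts),
            class = "composition_table")
}

# Multiplicative zero replacement, delta_j = 0.5 * min observed nonzero
# fraction of part j. A part never observed anywhere has no observed
# minimum and falls back to a tenth of the smallest fraction observed for
# any part (fraction-based, so all downstream statistics stay invariant to
# rescaling raw counts). Deltas are rescaled if they would consume half the
# row's mass.
replace_zeros <- function(parts) {
  if (nrow(parts) == 0L) return(parts)
  nz <- parts
  nz[nz == 0] <- NA
  delta <- apply(nz, 2, function(v) {
    if (all(is.na(v))) NA_real_ else 0.5 * min(v, na.rm = TRUE)
  })
  global_min <- min(nz, na.rm = TRUE)  # some part is nonzero in every row
  delta[!is.finite(delta)] <- 0.1 * global_min
  out <- parts
  for (i in seq_len(nrow(parts))) {
    z <- parts[i, ] == 0
    if (any(z)) {
      d <- delta[z]
      if (sum(d) >= 0.5) d <- d * 0.5 / sum(d)
      out[i, z] <- d
      out[i, !z] <- parts[i, !z] * (1 - sum(d))
    }
  }
  out
}

#' Geometric mean composition ("behavior components")
#'
#' Component-wise geometric mean of closed compositions, re-closed to 1 --
#' the compositionally correct average.
#'
#' @param comps A `composition_table` or matrix of rows on the simplex.
#' @return Named numeric composition.
#' @export
geometric_mean_composition <- function(comps) {
  parts <- if (inherits(comps, "composition_table")) comps$parts else comps
  if (is.null(dim(parts))) parts <- matrix(parts, 1,
                                           dimnames = list(NULL, names(parts)))
  stopifnot(nrow(parts) >= 1)
  closure(exp(colMeans(log(parts))))
}

#' Centered log-ratio transform
#'
#' `clr_i = log(x_i) - mean(log x)`; coordinates sum to zero. Accepts a
#' vector or a matrix of row compositions. `clr_inverse()` is the closure of
#' exponentials.
#'
#' @param x Strictly positive composition (vector or rows of a matrix).
#' @return CLR coordinates of the same shape.
#' @export
clr <- function(x) {
  if (any(x <= 0)) stop("clr requires strictly positive parts")
  if (is.matrix(x)) log(x) - rowMeans(log(x)) else log(x) - mean(log(x))
}

#' @rdname clr
#' @export
clr_inverse <- function(x) {
  if (is.matrix(x)) closure(exp(x)) else closure(exp(x))
}

#' Isometric log-ratio basis
#'
#' Default pivot (sequential binary partition) basis: a `(D-1) x D` matrix
#' with orthonormal zero-sum rows. Any rotation `Q %*% B` of the rows is an
#' equally valid basis; downstream results are basis-invariant.
#'
#' @param D Number of parts (default 7).
#' @return Matrix of class `ilr_basis`.
#' @export
ilr_basis <- function(D = 7) {
  B <- matrix(0, D - 1, D)
  for (k in seq_len(D - 1)) {
    B[k, seq_len(k)] <- sqrt(k / (k + 1)) / k
    B[k, k + 1] <- -sqrt(k / (k + 1))
  }
  structure(B, class = c("ilr_basis", "matrix"))
}

#' Isometric log-ratio transform
#'
#' `ilr = B clr(x)` for an orthonormal zero-sum basis `B`; invertible via
#' `ilr_inverse()`.
#'
#' @param x Composition vector or matrix of row compositions.
#' @param basis An [ilr_basis()].
#' @return ILR coordinates (`D-1` per composition).
#' @export
ilr <- function(x, basis = ilr_basis(if (is.matrix(x)) ncol(x) else length(x))) {
  cl <- clr(x)
  if (is.matrix(cl)) cl %*% t(basis) else as.vector(basis %*% cl)
}

#' @rdname ilr
#' @param z ILR coordinates.
#' @export
ilr_inverse <- function(z, basis = ilr_basis(
  if (is.matrix(z)) ncol(z) + 1L else length(z) + 1L)) {
  cl <- if (is.matrix(z)) z %*% basis else as.vector(t(basis) %*% z)
  clr_inverse(cl)
}

#' Robust principal components of behavior compositions
#'
#' PCA of the ILR-transformed fly-hours using a Minimum Covariance
#' Determinant covariance (classical covariance with `robust = FALSE`).
#' Loadings are back-transformed to CLR space, where they are interpretable
#' per behavior and sum to zero. Sign convention: PC1 has a non-negative
#' locomotion loading, PC2 a non-negative total grooming loading, further
#' components have their largest-magnitude loading positive; scores and
#' CLR loadings are therefore invariant to the choice of ILR basis.
#'
#' @param comps A `composition_table` (>= 8 fly-hours).
#' @param basis An [ilr_basis()].
#' @param robust Use the MCD covariance (default TRUE).
#' @param support_fraction MCD support fraction (default 0.75).
#' @param seed Seed for the MCD subsampling.
#' @return Object of class `comp_pca`: `clr_loadings` (parts x components),
#'   `scores`, `variance_explained`, `center_ilr`, `robust`,
#'   `mcd_support_fraction`.
#' @export
robust_composition_pca <- function(comps, basis = ilr_basis(),
                                   robust = TRUE, support_fraction = 0.75,
                                   seed = 1) {
  parts <- if (inherits(comps, "composition_table")) comps$parts else comps
  n <- nrow(parts)
  D <- ncol(parts)
  if (n < D + 1L) stop("need more fly-hours than ILR dimensions (>= 8 for 7 parts)")
  X <- ilr(parts, basis)
  sv <- svd(scale(X, scale = FALSE))$d
  if (any(sv < 1e-10 * max(sv))) {
    stop("rank-deficient compositions; some parts are collinear: ",
         paste(colnames(parts), collapse = ", "))
  }
  if (robust) {
    est <- with_seed(seed, MASS::cov.rob(X, method = "mcd",
                                         quantile.used = floor(support_fraction * n)))
    S <- est$cov; ctr <- est$center
  } else {
    S <- stats::cov(X); ctr <- colMeans(X)
  }
  eg <- eigen(S, symmetric = TRUE)
  V <- eg$vectors
  scores <- sweep(X, 2, ctr) %*% V
  L <- t(basis) %*% V  # clr loadings, parts x components
  rownames(L) <- colnames(parts)
  for (k in seq_len(ncol(L))) {
    flip <- if (k == 1L) L["locomotion", k] < 0
    else if (k == 2L) sum(L[c("fore_groom", "hind_groom", "wing_groom"), k]) < 0
    else L[which.max(abs(L[, k])), k] < 0
    if (isTRUE(flip)) {
      L[, k] <- -L[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(clr_loadings = L, scores = scores,
                 variance_explained = eg$values / sum(eg$values),
                 center_ilr = ctr, robust = robust,
                 mcd_support_fraction = if (robust) support_fraction else NA,
                 seed = seed),
            class = "comp_pca")
}

#' @export
print.comp_pca <- function(x, ...) {
  cat(sprintf("<comp_pca> %s, %d fly-hours; variance explained: %s\n",
              if (x$robust) "MCD-robust" else "classical", nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained[1:2]),
                    collapse = ", ")))
  invisible(x)
}

#' Day/night PC1 contrast per experimental day
#'
#' The absolute difference between the mean night (ZT 12-24) and mean day
#' (ZT 0-12) PC1 projection, computed per fly and day, then averaged across
#' flies with its standard error. A fly-day missing one phase contributes a
#' missing value.
#'
#' @param scores PC1 score per fly-hour.
#' @param zt_hour,day_index,fly_id Aligned metadata vectors.
#' @return Data frame: `day_index`, `mean_diff`, `se`, `n_flies`.
#' @export
day_night_difference <- function(scores, zt_hour, day_index,
                                 fly_id = rep("fly1", length(scores))) {
  df <- data.frame(s = scores, zt = zt_hour, day = day_index, fly = fly_id)
  combos <- unique(df[, c("fly", "day")])
  combos$diff <- mapply(function(f, d) {
    sub <- df[df$fly == f & df$day == d, ]
    day_s <- sub$s[sub$zt < 12]
    night_s <- sub$s[sub$zt >= 12]
    if (!length(day_s) || !length(night_s)) return(NA_real_)
    abs(mean(night_s) - mean(day_s))
  }, combos$fly, combos$day)
  out <- do.call(rbind, lapply(split(combos, combos$day), function(g) {
    v <- g$diff[!is.na(g$diff)]
    data.frame(day_index = g$day[1], mean_diff = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n_flies = length(v))
  }))
  rownames(out) <- NULL
  out[order(out$day_index), ]
}

#' Condense to a three-part composition and ternary coordinates
#'
#' Amalgamation by summation: `groom` = fore + hind + wing grooming,
#' `loco` = locomotion + altered locomotion, `rest` = idle + proboscis.
#'
#' @param x A 7-part composition (vector or matrix rows).
#' @return `condense()`: 3-part composition(s) in order (groom, loco, rest).
#' @export
condense <- function(x) {
  one <- function(v) {
    closure(c(groom = unname(v["fore_groom"] + v["hind_groom"] + v["wing_groom"]),
              loco = unname(v["locomotion"] + v["altered_locomotion"]),
              rest = unname(v["idle"] + v["proboscis"])))
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' @rdname condense
#' @param comp3 3-part composition (a, b, c) in its given order.
#' @return `ternary_coords()`: (x, y) in the unit-edge triangle, vertex a at
#'   the origin.
#' @export
ternary_coords <- function(comp3) {
  one <- function(v) {
    tot <- sum(v)
    c(x = 0.5 * (2 * v[[2]] + v[[3]]) / tot,
      y = sqrt(3) / 2 * v[[3]] / tot)
  }
  if (is.matrix(comp3)) t(apply(comp3, 1, one)) else one(comp3)
}

#' Principal-component direction as a simplex curve
#'
#' Aitchison perturbation of a center composition by `exp(s * loading)` for
#' each scale `s`: the image of the PC axis in the simplex.
#'
#' @param center Positive composition.
#' @param clr_loading Zero-sum CLR loading vector.
#' @param scales Numeric scales.
#' @return Matrix (length(scales) x parts) of compositions.
#' @export
pc_direction_curve <- function(center, clr_loading, scales) {
  stopifnot(all(center > 0), abs(sum(clr_loading)) < 1e-6)
  out <- t(vapply(scales, function(s) closure(center * exp(s * clr_loading)),
                  numeric(length(center))))
  colnames(out) <- names(center)
  out
}

#' Hourly enrichment of a behavior component with bootstrap CI
#'
#' Ratio of the geometric-mean component at one ZT hour (across flies) to a
#' reference component (typically the geometric mean across all hours),
#' with a percentile bootstrap over flies.
#'
#' @param hour_parts Matrix of per-fly compositions at the hour (7- or
#'   3-part).
#' @param reference Reference composition on the same parts.
#' @param part Part name; one of the composition's parts, or one of
#'   "groom", "loco", "rest" to condense a 7-part input first.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return Object of class `enrichment`: `ratio`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_flies`.
#' @export
enrichment_bootstrap <- function(hour_parts, reference, part,
                                 n_boot = 1000, seed = 1) {
  if (n_boot < 100) warning("n_boot < 100: confidence interval is unreliable")
  if (is.null(dim(hour_parts))) hour_parts <- matrix(
    hour_parts, 1, dimnames = list(NULL, names(hour_parts)))
  if (nrow(hour_parts) < 2L) stop("need at least 2 flies at the hour")
  if (part %in% c("groom", "loco", "rest")) {
    if (!part %in% colnames(hour_parts)) hour_parts <- condense(hour_parts)
    if (!part %in% names(reference)) reference <- condense(reference)
  }
  stopifnot(part %in% colnames(hour_parts))
  ratio_of <- function(rows) {
    gm <- geometric_mean_composition(hour_parts[rows, , drop = FALSE])
    unname(gm[part] / reference[[part]])
  }
  n <- nrow(hour_parts)
  ratio <- ratio_of(seq_len(n))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    ratio_of(sample.int(n, n, replace = TRUE))
  }, 0))
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  structure(list(ratio = ratio, ci_low = min(ci[1], ratio),
                 ci_high = max(ci[2], ratio), n_boot = n_boot, n_flies = n),
            class = "enrichment")
}
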