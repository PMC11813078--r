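# Ethogram containers and bout-level operations: run-length bout
# extraction, a two-component geometric mixture for dwell times (short
# tracking-noise bouts vs legitimate behavior bouts), the exclusion
# fractions that motivate a minimum bout duration, and forward-filling of
# sub-minimum bouts.

#' Construct an ethogram
#'
#' @param labels Per-frame labels from [ethogram_alphabet()].
#' @param fps Frame rate (Hz).
#' @param t0_clock Wall-clock hour of frame 0.
#' @param fly_id Identifier.
#' @param frames_per_hour Frames per ZT hour (see [pose_sequence()]).
#' @return Object of class `ethogram`.
#' @export
ethogram <- function(labels, fps = 100, t0_clock = 8, fly_id = "fly1",
                     frames_per_hour = fps * 3600) {
  labels <- as.character(labels)
  check_labels(labels, ethogram_alphabet(), "ethogram label")
  structure(list(labels = labels, fps = fps, t0_clock = t0_clock,
                 fly_id = fly_id, frames_per_hour = frames_per_hour),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<ethogram> %s: %d frames (%.1f s at %g fps)\n",
              x$fly_id, n, n / x$fps, x$fps))
  if (n > 0) print(round(sort(table(x$labels) / n, decreasing = TRUE), 3))
  invisible(x)
}

#' Extract bouts from an ethogram
#'
#' Maximal runs of identical labels, in order, with half-open
#' `[start, end)` frame intervals; concatenating the bouts reproduces the
#' ethogram.
#'
#' @param etho An [ethogram()] (or a bare label vector).
#' @return Data frame with columns `behavior`, `start`, `end`,
#'   `duration_frames`.
#' @export
extract_bouts <- function(etho) {
  labels <- if (inherits(etho, "ethogram")) etho$labels else as.character(etho)
  runs <- rle_runs(labels)
  data.frame(behavior = runs$value, start = runs$start, end = runs$end,
             duration_frames = runs$length, stringsAsFactors = FALSE)
}

# Mixture log-likelihood pieces in log space (support starts at 1 frame).
geom_logpmf <- function(x, p) (x - 1) * log1p(-p) + log(p)

#' Fit a two-component geometric mixture to dwell times
#'
#' EM on the mixture `w Geom(p_short) + (1 - w) Geom(p_long)` (support
#' starting at 1 frame), with seeded random restarts; the best
#' log-likelihood fit is kept and components are ordered so that
#' `p_short >= p_long`. Identical durations trigger a degenerate
#' single-component fallback.
#'
#' @param durations Integer dwell times in frames, all >= 1; at least 10.
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of EM restarts (default 5).
#' @param max_iter,tol EM stopping rule: `|delta loglik| < tol` or
#'   `max_iter` iterations.
#' @return Object of class `dwell_mixture`: `w`, `p_short`, `p_long`,
#'   `loglik`, `n_iter`, `converged`, `degenerate`, and the per-iteration
#'   `loglik_trace` of the winning restart.
#' @export
fit_dwell_mixture <- function(durations, seed = 1, n_restarts = 5,
                              max_iter = 500, tol = 1e-8) {
  x <- as.numeric(durations)
  if (length(x) < 10L) stop("need at least 10 dwell times")
  if (any(x < 1)) stop("dwell times must be >= 1 frame")
  if (length(unique(x)) == 1L) {
    p <- min(1, 1 / mean(x))
    return(structure(list(w = 1, p_short = p, p_long = p,
                          loglik = sum(geom_logpmf(x, p)), n_iter = 0L,
                          converged = TRUE, degenerate = TRUE,
                          loglik_trace = numeric(0)),
                     class = "dwell_mixture"))
  }
  em_once <- function(w, p1, p2) {
    ll_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      l1 <- log(w) + geom_logpmf(x, p1)
      l2 <- log1p(-w) + geom_logpmf(x, p2)
      m <- pmax(l1, l2)
      ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
      trace <- c(trace, ll)
      r <- 1 / (1 + exp(l2 - l1))
      w <- mean(r)
      w <- min(max(w, 1e-10), 1 - 1e-10)
      p1 <- min(1 - 1e-12, sum(r) / sum(r * x))
      p2 <- min(1 - 1e-12, sum(1 - r) / sum((1 - r) * x))
      if (abs(ll - ll_old) < tol) {
        return(list(w = w, p1 = p1, p2 = p2, loglik = ll, n_iter = it,
                    converged = TRUE, trace = trace))
      }
      ll_old <- ll
    }
    list(w = w, p1 = p1, p2 = p2, loglik = ll_old, n_iter = max_iter,
         converged = FALSE, trace = trace)
  }
  best <- NULL
  with_seed(seed, {
    mean_inv <- 1 / mean(x)
    for (r in seq_len(n_restarts)) {
      init_w <- runif(1, 0.3, 0.7)
      init_p1 <- runif(1, min(1, mean_inv * 2), min(1, max(mean_inv * 4, 0.9)))
      init_p2 <- runif(1, mean_inv / 10, mean_inv)
      fit <- em_once(init_w, init_p1, init_p2)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  # order components: short = larger success probability
  if (best$p1 < best$p2) {
    best <- list(w = 1 - best$w, p1 = best$p2, p2 = best$p1,
                 loglik = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, trace = best$trace)
  }
  structure(list(w = best$w, p_short = best$p1, p_long = best$p2,
                 loglik = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, degenerate = FALSE,
                 loglik_trace = best$trace),
            class = "dwell_mixture")
}

#' @export
print.dwell_mixture <- function(x, ...) {
  cat(sprintf(
    "<dwell_mixture> w=%.3f p_short=%.4f p_long=%.5f (mean dwell %.1f frames)%s\n",
    x$w, x$p_short, x$p_long,
    mixture_mean_dwell(x$w, x$p_short, x$p_long),
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fraction of bouts excluded by a minimum-duration threshold
#'
#' For each mixture component, the probability that a bout is shorter than
#' `t` frames: `P(X < t) = 1 - (1 - p)^(t - 1)` (support starting at 1).
#' Used to justify the minimum bout duration: at the default 5-frame
#' threshold the short component loses ~95% of its bouts while the long
#' component keeps ~86% of its.
#'
#' @param fit A `dwell_mixture`.
#' @param t Threshold in frames (>= 1).
#' @return Named numeric: `frac_short_excluded`, `frac_long_excluded`.
#' @export
exclusion_fractions <- function(fit, t) {
  stopifnot(t >= 1)
  c(frac_short_excluded = 1 - (1 - fit$p_short)^(t - 1),
    frac_long_excluded = 1 - (1 - fit$p_long)^(t - 1))
}

#' Enforce a minimum bout duration by forward-filling
#'
#' Scanning forward, every behavior bout shorter than `min_frames` is
#' relabeled to the most recent preceding bout of duration >= `min_frames`;
#' leading short bouts take the first subsequent long bout's label. `edge`
#' and `unstereotyped` bouts are flags reported by upstream classifiers, not
#' behaviors: they are never themselves relabeled (even when short), though
#' they can supply the fill label. Frame count is conserved and adjacent
#' same-label bouts are merged afterwards. On flag-free ethograms the output
#' contains no interior bout shorter than `min_frames`.
#'
#' @param etho An [ethogram()].
#' @param min_frames Minimum bout duration (default 5 frames, ~1/20 s at
#'   100 fps).
#' @return The corrected `ethogram`.
#' @export
enforce_min_bout <- function(etho, min_frames = 5) {
  bouts <- extract_bouts(etho)
  if (nrow(bouts) == 0L) return(etho)
  behaviors <- behavior_alphabet()
  long <- bouts$duration_frames >= min_frames
  if (!any(long)) {
    warning("no bout reaches the minimum duration; ethogram returned unchanged")
    return(etho)
  }
  new_label <- bouts$behavior
  last_long <- NA_character_
  pending <- integer(0)  # leading short bouts awaiting a forward target
  for (i in seq_len(nrow(bouts))) {
    if (long[i]) {
      if (length(pending)) {
        new_label[pending] <- bouts$behavior[i]
        pending <- integer(0)
      }
      last_long <- bouts$behavior[i]
    } else if (bouts$behavior[i] %in% behaviors) {
      if (!is.na(last_long)) new_label[i] <- last_long
      else pending <- c(pending, i)
    }
  }
  labels <- rep(new_label, bouts$duration_frames)
  ethogram(labels, fps = etho$fps, t0_clock = etho$t0_clock,
           fly_id = etho$fly_id, frames_per_hour = etho$frames_per_hour)
}
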