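# Spectral featurization: rolling Lomb-Scargle periodograms of egocentric
# node trajectories. The periodogram is the least-squares sinusoid fit with a
# floating mean, so unevenly observed (gappy) windows are handled without
# interpolation. Power is normalized to A^2/4 for a pure sinusoid of
# amplitude A, making amplitude thresholds interpretable in mm^2.

#' Dyadic frequency grid
#'
#' @param n_freqs Number of frequencies (default 25).
#' @param f_min,f_max Bounds in Hz (defaults 0.5 and 25; keep `f_max` below
#'   the Nyquist frequency).
#' @param fps Frame rate used only to validate the Nyquist bound.
#' @return Object of class `frequency_grid` with strictly increasing
#'   log2-spaced `freqs_hz`.
#' @export
frequency_grid <- function(n_freqs = 25, f_min = 0.5, f_max = 25, fps = 100) {
  stopifnot(n_freqs >= 1, f_min > 0, f_max > f_min)
  if (f_max >= fps / 2) stop("f_max must be below the Nyquist frequency fps/2")
  freqs <- 2^seq(log2(f_min), log2(f_max), length.out = n_freqs)
  structure(list(freqs_hz = freqs, n_freqs = n_freqs,
                 f_min = f_min, f_max = f_max), class = "frequency_grid")
}

#' Lomb-Scargle periodogram of one irregularly sampled signal
#'
#' Least-squares fit of `mu + a cos(2 pi f t) + b sin(2 pi f t)` at each grid
#' frequency; returned power is `(a^2 + b^2) / 4` (units of the signal
#' squared), which equals `A^2/4` for a complete evenly sampled sinusoid of
#' amplitude `A`.
#'
#' @param times Sample times (seconds).
#' @param values Sample values (mm); `NA`s are dropped.
#' @param freqs A [frequency_grid()] or numeric vector of frequencies (Hz).
#' @return Numeric vector of powers per frequency; all-`NA` with attribute
#'   `valid = FALSE` when fewer than 2 distinct samples are available.
#' @export
lomb_scargle <- function(times, values, freqs) {
  if (inherits(freqs, "frequency_grid")) freqs <- freqs$freqs_hz
  keep <- !is.na(values) & !is.na(times)
  t <- times[keep]; y <- values[keep]
  if (length(unique(t)) < 2L) {
    out <- rep(NA_real_, length(freqs))
    attr(out, "valid") <- FALSE
    return(out)
  }
  n <- length(t)
  power <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    cc <- cos(w * t); ss <- sin(w * t)
    M <- rbind(c(n, sum(cc), sum(ss)),
               c(sum(cc), sum(cc * cc), sum(cc * ss)),
               c(sum(ss), sum(cc * ss), sum(ss * ss)))
    rhs <- c(sum(y), sum(y * cc), sum(y * ss))
    beta <- tryCatch(solve(M, rhs), error = function(e) c(0, 0, 0))
    (beta[2]^2 + beta[3]^2) / 4
  }, 0)
  attr(power, "valid") <- TRUE
  power
}

# Rolling-window sums of v over windows [lo_i, hi_i] (1-based, inclusive),
# evaluated at arbitrary index vectors. v may contain NA; treat as 0.
roll_sum <- function(v, lo, hi) {
  v[is.na(v)] <- 0
  cs <- c(0, cumsum(v))
  cs[hi + 1] - cs[lo]
}

#' Rolling Lomb-Scargle spectral features
#'
#' For each frequency `f` the window is `window_periods / f` seconds
#' (minimum 5 frames), centered on the evaluated frame, so low frequencies
#' integrate over proportionally longer envelopes. Each of the 26 channels
#' (x and y of every node except the thorax, which is identically zero in
#' the egocentric frame) is fit independently on its observed samples.
#' Frames whose worst channel-window occupancy falls below `min_occupancy`
#' are marked invalid.
#'
#' @param ego An `egocentric_pose` (coordinates in mm).
#' @param grid A [frequency_grid()].
#' @param window_periods Window length in signal periods (default 5).
#' @param stride Evaluate every `stride`-th frame (default 1).
#' @param min_occupancy Minimum fraction of window samples present.
#' @return Object of class `spectral_features`: `power` (evaluated frames x
#'   channels*freqs, mm^2), `valid`, `eval_frames` (1-based original frame
#'   indices), `channel_index` (node, coord, freq_hz per column), and
#'   recording metadata.
#' @export
rolling_spectral_features <- function(ego, grid = frequency_grid(),
                                      window_periods = 5, stride = 1,
                                      min_occupancy = 0.5) {
  n <- dim(ego$coords)[1]
  fps <- ego$fps
  nodes <- setdiff(ego$node_names, "thorax")
  eval_frames <- seq.int(1L, n, by = stride)
  ne <- length(eval_frames)
  nf <- grid$n_freqs
  ncol_out <- length(nodes) * 2L * nf
  power <- matrix(NA_real_, ne, ncol_out)
  occ_min <- rep(Inf, ne)
  channel_index <- data.frame(
    node = rep(nodes, each = 2L * nf),
    coord = rep(rep(c("x", "y"), each = nf), length(nodes)),
    freq_hz = rep(grid$freqs_hz, length(nodes) * 2L))

  if (n > 0) {
    tsec <- (seq_len(n) - 1) / fps
    for (fi in seq_len(nf)) {
      f <- grid$freqs_hz[fi]
      L <- max(5L, round(window_periods * fps / f))
      lo <- pmax(1L, eval_frames - (L - 1L) %/% 2L)
      hi <- pmin(n, lo + L - 1L)
      lo <- pmax(1L, hi - L + 1L)
      w <- 2 * pi * f
      cc <- cos(w * tsec); ss <- sin(w * tsec)
      ccss <- cc * ss; cc2 <- cc * cc; ss2 <- ss * ss
      for (ni in seq_along(nodes)) {
        j <- match(nodes[ni], ego$node_names)
        m <- as.numeric(!ego$missing[, j])
        # mask-dependent design sums, shared by the node's two coordinates
        Sm <- roll_sum(m, lo, hi)
        Sc <- roll_sum(m * cc, lo, hi)
        Ss <- roll_sum(m * ss, lo, hi)
        Scc <- roll_sum(m * cc2, lo, hi)
        Sss <- roll_sum(m * ss2, lo, hi)
        Scs <- roll_sum(m * ccss, lo, hi)
        det <- Sm * (Scc * Sss - Scs * Scs) - Sc * (Sc * Sss - Scs * Ss) +
          Ss * (Sc * Scs - Scc * Ss)
        bad_det <- !is.finite(det) | abs(det) < 1e-10 * pmax(1, Sm)^3
        occ_min <- pmin(occ_min, Sm / L)
        for (d in 1:2) {
          y <- ego$coords[, j, d]
          y[is.na(y)] <- 0
          ym <- y * m
          Sy <- roll_sum(ym, lo, hi)
          Syc <- roll_sum(ym * cc, lo, hi)
          Sys <- roll_sum(ym * ss, lo, hi)
          # Cramer solve of the 3x3 normal equations [1, cos, sin]
          a <- (Sy * (Scs * Ss - Sc * Sss) + Syc * (Sm * Sss - Ss * Ss) +
                  Sys * (Sc * Ss - Sm * Scs)) / det
          b <- (Sy * (Sc * Scs - Scc * Ss) + Syc * (Ss * Sc - Sm * Scs) +
                  Sys * (Sm * Scc - Sc * Sc)) / det
          p <- (a * a + b * b) / 4
          p[!is.finite(p) | bad_det] <- 0
          col <- (ni - 1L) * 2L * nf + (d - 1L) * nf + fi
          power[, col] <- p
        }
      }
    }
  }
  valid <- occ_min >= min_occupancy
  power[!valid, ] <- NA_real_
  structure(list(power = power, valid = valid, eval_frames = eval_frames,
                 channel_index = channel_index, freqs_hz = grid$freqs_hz,
                 stride = stride, fps = fps,
                 frames_per_hour = ego$frames_per_hour,
                 t0_clock = ego$t0_clock, fly_id = ego$fly_id),
            class = "spectral_features")
}

#' Total spectral amplitude per frame
#'
#' Sum of Lomb-Scargle power across all channels and frequencies; frames
#' below the idle threshold (default 0.5012 mm^2) are treated as motionless
#' downstream.
#'
#' @param features A `spectral_features` object.
#' @return Numeric vector (mm^2) per evaluated frame; `NA` where invalid.
#' @export
total_spectral_amplitude <- function(features) {
  out <- rowSums(features$power)
  out[!features$valid] <- NA_real_
  out
}

#' Default idle amplitude threshold (mm^2)
#' @export
amplitude_threshold_default <- function() 0.5012
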