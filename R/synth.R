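# Synthetic fly generator: diurnally modulated semi-Markov state sequences,
# a rigid-body kinematic renderer for the 14-node skeleton, and a corruption
# stage (dropout, jitter, wall bouts) that returns aligned ground truth.

# Solve for bout-level transition weights c so that the stationary frame
# occupancy of the semi-Markov chain matches the target weights. For the
# embedded chain P(j | i) = c_j / (1 - c_i), j != i, the stationary bout
# distribution is proportional to c_i (1 - c_i), hence frame occupancy is
# proportional to c_i (1 - c_i) * mean_dwell_i. We invert that relation with
# a one-dimensional root find; if the target is infeasible (one state too
# dominant for its dwell time) we fall back to c proportional to w / dwell.
solve_bout_weights <- function(w_occ, mean_dwell) {
  stopifnot(length(w_occ) == length(mean_dwell))
  pos <- w_occ > 0
  c_out <- numeric(length(w_occ))
  if (sum(pos) <= 1L) {
    c_out[pos] <- 1
    return(c_out)
  }
  w <- w_occ[pos] / sum(w_occ[pos])
  md <- mean_dwell[pos]
  lam_max <- min(md / (4 * w))
  csum <- function(lam) sum((1 - sqrt(pmax(0, 1 - 4 * lam * w / md))) / 2)
  if (csum(lam_max) < 1) {
    cc <- w / md
    c_out[pos] <- cc / sum(cc)
    return(c_out)
  }
  lam <- stats::uniroot(function(l) csum(l) - 1, c(1e-12, lam_max),
                        tol = 1e-12)$root
  c_out[pos] <- (1 - sqrt(pmax(0, 1 - 4 * lam * w / md))) / 2
  c_out / sum(c_out)
}

# Per-phase dwell parameter table with the night factor applied.
phase_dwell <- function(schedule, night) {
  d <- schedule$dwell
  if (night && length(schedule$night_dwell_factor)) {
    f <- schedule$night_dwell_factor
    idx <- match(names(f), d$behavior)
    ok <- !is.na(idx)
    d$p_short[idx[ok]] <- pmin(1, d$p_short[idx[ok]] / f[ok])
    d$p_long[idx[ok]] <- pmin(1, d$p_long[idx[ok]] / f[ok])
  }
  d
}

# Phase weights for a given experimental day, with contrast decay applied.
phase_weights <- function(schedule, night, day_index) {
  w <- if (night) schedule$night_state_weights else schedule$day_state_weights
  gam <- schedule$contrast_decay
  if (is.null(gam)) return(w)
  g <- gam[min(day_index, length(gam))]
  mid <- (schedule$day_state_weights[names(w)] +
            schedule$night_state_weights[names(w)]) / 2
  mid + g * (w - mid)
}

draw_dwell <- function(dw_row) {
  if (runif(1) < dw_row$w) rgeom(1, dw_row$p_short) + 1L
  else rgeom(1, dw_row$p_long) + 1L
}

#' Generate a diurnally modulated behavior state sequence
#'
#' Draws a semi-Markov label sequence over the behavior alphabet: bout
#' labels are drawn with Zeitgeber-time-dependent weights (light phase
#' ZT 0-12, dark phase ZT 12-24) and bout lengths from each behavior's
#' two-component geometric dwell mixture. Bout-level transition weights are
#' calibrated so that the long-run fraction of frames per behavior matches
#' the schedule's occupancy weights.
#'
#' @param schedule A [diurnal_schedule()].
#' @param archetypes Named list of archetypes; only names are used here (the
#'   schedule may not reference behaviors without an archetype).
#' @param n_frames Number of frames to generate.
#' @param fps Frame rate (Hz).
#' @param seed RNG seed.
#' @param seconds_per_hour Recorded seconds per ZT hour (3600 = real time).
#' @return Character vector of per-frame labels with attribute `bouts`, a
#'   data frame of the drawn bouts (`state`, `start`, `end` half-open,
#'   `duration` as drawn before any final truncation).
#' @export
generate_state_sequence <- function(schedule, archetypes, n_frames, fps = 100,
                                    seed = 1, seconds_per_hour = 3600) {
  states_avail <- names(archetypes)
  check_labels(names(schedule$day_state_weights), states_avail)
  check_labels(names(schedule$night_state_weights), states_avail)
  n_frames <- as.integer(n_frames)
  if (n_frames <= 0L) {
    out <- character(0)
    attr(out, "bouts") <- data.frame(state = character(0), start = integer(0),
                                     end = integer(0), duration = integer(0))
    return(out)
  }
  fph <- fps * seconds_per_hour
  alpha <- names(schedule$day_state_weights)
  dwell_day <- phase_dwell(schedule, night = FALSE)
  dwell_night <- phase_dwell(schedule, night = TRUE)

  with_seed(seed, {
    # cache per (day, phase): occupancy weights and bout transition weights
    cache <- new.env(parent = emptyenv())
    phase_par <- function(frame) {
      zt <- (frame / fph) %% 24
      day_idx <- floor(frame / (24 * fph)) + 1
      night <- zt >= 12
      key <- paste0(day_idx, if (night) "N" else "D")
      if (is.null(cache[[key]])) {
        w <- phase_weights(schedule, night, day_idx)
        dw <- if (night) dwell_night else dwell_day
        md <- mixture_mean_dwell(dw$w, dw$p_short, dw$p_long)
        names(md) <- dw$behavior
        cache[[key]] <- list(w = w, cvec = solve_bout_weights(w, md[alpha]),
                             dwell = dw, night = night)
      }
      cache[[key]]
    }

    labels <- character(n_frames)
    cap <- 256L
    bouts_state <- character(cap)
    bouts_start <- integer(cap)
    bouts_dur <- integer(cap)
    nb <- 0L
    pos <- 0L
    cur <- NA_character_
    while (pos < n_frames) {
      par <- phase_par(pos)
      if (is.na(cur)) {
        prob <- par$w
      } else if (length(alpha) > 1L) {
        prob <- par$cvec
        names(prob) <- alpha
        prob[cur] <- 0
      } else {
        prob <- setNames(1, alpha)
      }
      if (sum(prob) <= 0) prob <- par$w  # degenerate fallback
      cur <- sample(alpha, 1L, prob = prob)
      dur <- draw_dwell(par$dwell[par$dwell$behavior == cur, ])
      take <- min(dur, n_frames - pos)
      labels[(pos + 1L):(pos + take)] <- cur
      nb <- nb + 1L
      if (nb > cap) {  # grow by doubling
        cap <- cap * 2L
        length(bouts_state) <- cap
        length(bouts_start) <- cap
        length(bouts_dur) <- cap
      }
      bouts_state[nb] <- cur
      bouts_start[nb] <- pos
      bouts_dur[nb] <- as.integer(dur)
      pos <- pos + take
    }
    keep <- seq_len(nb)
    attr(labels, "bouts") <- data.frame(
      state = bouts_state[keep], start = bouts_start[keep],
      end = pmin(bouts_start[keep] + bouts_dur[keep], n_frames),
      duration = bouts_dur[keep])
    labels
  })
}

#' Render a pose sequence from a state sequence
#'
#' Kinematic renderer: a rigid body template is carried along a smooth
#' heading random walk confined to the arena disc (translation speed set by
#' the active archetype, optionally reduced at night), and the archetype's
#' oscillating nodes are displaced sinusoidally in the body frame. The
#' proboscis is rendered 0.5 mm anterior of the head when visible and marked
#' missing otherwise (a retracted proboscis is not trackable).
#'
#' @param states Per-frame labels (from [generate_state_sequence()]).
#' @param archetypes Named list of [behavior_archetype()]s covering every
#'   label that occurs.
#' @param config A [synth_config()].
#' @param seed RNG seed.
#' @param night_speed_factor Speed multiplier applied during ZT 12-24.
#' @param fly_id Identifier for the output.
#' @param t0_clock Wall-clock hour of frame 0.
#' @return A noise-free [pose_sequence()] with attribute `states`.
#' @export
render_pose <- function(states, archetypes, config, seed = 1,
                        night_speed_factor = 1, fly_id = "fly1",
                        t0_clock = 8) {
  n <- length(states)
  nodes <- skeleton_nodes()
  missing_states <- setdiff(unique(states), names(archetypes))
  if (length(missing_states)) {
    stop("no archetype for state(s): ", paste(missing_states, collapse = ", "))
  }
  tmpl <- body_template()
  fps <- config$fps
  dt <- 1 / fps
  fph <- fps * config$seconds_per_hour
  arena_r_mm <- config$arena_diameter_mm / 2
  r_conf <- arena_r_mm - 4  # keep the 3.5 mm body half-span off the wall

  coords <- array(NA_real_, c(max(n, 0L), 14L, 2L))
  missing <- matrix(FALSE, max(n, 0L), 14L)
  if (n == 0L) {
    return(pose_sequence(coords[0, , , drop = FALSE], missing[0, , drop = FALSE],
                         fps = fps, px_per_mm = config$px_per_mm,
                         t0_clock = t0_clock, fly_id = fly_id,
                         frames_per_hour = fph))
  }

  with_seed(seed, {
    arch_idx <- match(states, names(archetypes))
    speed <- vapply(archetypes, function(a) a$translation_speed_mm_s, 0)[arch_idx]
    night <- ((seq_len(n) - 1) / fph) %% 24 >= 12
    speed <- speed * ifelse(night, night_speed_factor, 1)
    p_vis <- vapply(archetypes, function(a) a$proboscis_visible, 0)[arch_idx]

    # trajectory: sequential heading walk with reflection off the wall
    dh <- rnorm(n, 0, config$heading_sd * sqrt(dt)) * (speed > 0)
    h <- numeric(n)
    px <- numeric(n)
    py <- numeric(n)
    h0 <- runif(1, 0, 2 * pi)
    r0 <- sqrt(runif(1)) * r_conf * 0.8
    a0 <- runif(1, 0, 2 * pi)
    x <- r0 * cos(a0)
    y <- r0 * sin(a0)
    hh <- h0
    step <- speed * dt
    for (i in seq_len(n)) {
      hh <- hh + dh[i]
      nx <- x + step[i] * cos(hh)
      ny <- y + step[i] * sin(hh)
      if (nx * nx + ny * ny > r_conf * r_conf) {
        hh <- atan2(-y, -x) + rnorm(1, 0, 0.3)
        nx <- x + step[i] * cos(hh)
        ny <- y + step[i] * sin(hh)
      }
      x <- nx; y <- ny
      h[i] <- hh; px[i] <- x; py[i] <- y
    }

    # body-frame oscillation offsets (x: sin, y: half-amplitude quadrature)
    tsec <- (seq_len(n) - 1) * dt
    phases <- setNames(runif(14, 0, 2 * pi), nodes)
    offx <- matrix(0, n, 14, dimnames = list(NULL, nodes))
    offy <- matrix(0, n, 14, dimnames = list(NULL, nodes))
    for (aname in unique(states)) {
      a <- archetypes[[aname]]
      if (nrow(a$oscillations) == 0) next
      sel <- states == aname
      for (k in seq_len(nrow(a$oscillations))) {
        nd <- a$oscillations$node[k]
        f <- a$oscillations$freq_hz[k]
        amp <- a$oscillations$amplitude_mm[k]
        ph <- phases[nd]
        offx[sel, nd] <- offx[sel, nd] + amp * sin(2 * pi * f * tsec[sel] + ph)
        offy[sel, nd] <- offy[sel, nd] + 0.5 * amp * cos(2 * pi * f * tsec[sel] + ph)
      }
    }

    ch <- cos(h); sh <- sin(h)
    for (j in seq_along(nodes)) {
      lx <- tmpl[j, 1] + offx[, j]
      ly <- tmpl[j, 2] + offy[, j]
      coords[, j, 1] <- (px + ch * lx - sh * ly) * config$px_per_mm
      coords[, j, 2] <- (py + sh * lx + ch * ly) * config$px_per_mm
    }

    vis <- runif(n) < p_vis
    pr <- match("proboscis", nodes)
    missing[!vis, pr] <- TRUE
    coords[!vis, pr, ] <- NA_real_
  })

  pose <- pose_sequence(coords, missing, fps = fps,
                        px_per_mm = config$px_per_mm, t0_clock = t0_clock,
                        fly_id = fly_id, frames_per_hour = fph)
  attr(pose, "states") <- states
  pose
}

#' Corrupt a rendered pose and return aligned ground truth
#'
#' Applies, in order: wall ("edge") bouts that drag the body to the arena
#' boundary and occlude the six tarsi; per-node per-frame dropout; Gaussian
#' tracking jitter on observed coordinates.
#'
#' @param pose A rendered [pose_sequence()] carrying a `states` attribute.
#' @param config A [synth_config()].
#' @param seed RNG seed.
#' @return List with elements `pose` (corrupted sequence) and `truth`
#'   (`ground_truth`: `true_ethogram`, `true_edge_mask`, `true_missing_mask`).
#' @export
corrupt <- function(pose, config, seed = 1) {
  n <- n_frames(pose)
  coords <- pose$coords
  missing <- pose$missing
  nodes <- pose$node_names
  legs <- c("forelegL", "forelegR", "midlegL", "midlegR",
            "hindlegL", "hindlegR")
  edge_mask <- logical(n)

  with_seed(seed, {
    if (n > 0 && config$edge_bout_rate > 0) {
      starts <- which(runif(n) < config$edge_bout_rate / config$fps)
      mean_frames <- max(1, config$edge_bout_duration_s * config$fps)
      for (s in starts) {
        dur <- rgeom(1, 1 / mean_frames) + 1L
        edge_mask[s:min(n, s + dur - 1L)] <- TRUE
      }
      if (any(edge_mask)) {
        runs <- true_runs(edge_mask)
        wall_r <- 0.96 * config$arena_diameter_mm / 2 * config$px_per_mm
        th <- match("thorax", nodes)
        for (k in seq_len(nrow(runs))) {
          idx <- (runs$start[k] + 1L):runs$end[k]
          ang <- atan2(coords[idx[1], th, 2], coords[idx[1], th, 1])
          if (!is.finite(ang)) ang <- runif(1, 0, 2 * pi)
          dx <- wall_r * cos(ang) - coords[idx, th, 1]
          dy <- wall_r * sin(ang) - coords[idx, th, 2]
          coords[idx, , 1] <- coords[idx, , 1] + dx
          coords[idx, , 2] <- coords[idx, , 2] + dy
          missing[idx, match(legs, nodes)] <- TRUE
        }
      }
    }
    if (config$missing_rate > 0 && n > 0) {
      drop <- matrix(runif(n * 14) < config$missing_rate, n, 14)
      missing <- missing | drop
    }
    coords[, , 1][missing] <- NA_real_
    coords[, , 2][missing] <- NA_real_
    if (config$noise_sd_mm > 0 && n > 0) {
      sdpx <- config$noise_sd_mm * config$px_per_mm
      obs <- !missing
      nobs <- sum(obs)
      coords[, , 1][obs] <- coords[, , 1][obs] + rnorm(nobs, 0, sdpx)
      coords[, , 2][obs] <- coords[, , 2][obs] + rnorm(nobs, 0, sdpx)
    }
  })

  out <- pose_sequence(coords, missing, node_names = nodes, fps = pose$fps,
                       px_per_mm = pose$px_per_mm, t0_clock = pose$t0_clock,
                       fly_id = pose$fly_id,
                       frames_per_hour = pose$frames_per_hour)
  truth <- structure(list(true_ethogram = attr(pose, "states"),
                          true_edge_mask = edge_mask,
                          true_missing_mask = missing),
                     class = "ground_truth")
  list(pose = out, truth = truth)
}

#' Simulate one fly or a cohort
#'
#' Convenience wrappers chaining [generate_state_sequence()],
#' [render_pose()] and [corrupt()]. Each fly gets an independent seed
#' derived from the config seed.
#'
#' @param config A [synth_config()].
#' @param schedule A [diurnal_schedule()].
#' @param archetypes Named archetype list.
#' @param fly_index Fly number within the cohort (seeds the fly's streams).
#' @return `simulate_fly()`: list `pose`, `truth`. `simulate_cohort()`: list
#'   of such lists, one per fly.
#' @export
simulate_fly <- function(config, schedule = diurnal_schedule(),
                         archetypes = default_archetypes(), fly_index = 1) {
  nfr <- round(config$n_hours * config$seconds_per_hour * config$fps)
  base <- (config$seed * 1000L + fly_index * 10L) %% .Machine$integer.max
  states <- generate_state_sequence(schedule, archetypes, nfr, config$fps,
                                    seed = base + 1L,
                                    seconds_per_hour = config$seconds_per_hour)
  pose <- render_pose(states, archetypes, config, seed = base + 2L,
                      night_speed_factor = schedule$night_speed_factor,
                      fly_id = sprintf("fly%02d", fly_index),
                      t0_clock = schedule$lights_on_hour)
  res <- corrupt(pose, config, seed = base + 3L)
  res$states_bouts <- attr(states, "bouts")
  res
}

#' @rdname simulate_fly
#' @export
simulate_cohort <- function(config, schedule = diurnal_schedule(),
                            archetypes = default_archetypes()) {
  lapply(seq_len(config$n_flies), function(i) {
    simulate_fly(config, schedule, archetypes, fly_index = i)
  })
}
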