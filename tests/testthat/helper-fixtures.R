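# Shared fixtures, built in code and memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small simulated fly: 2 ZT hours, 30 s recorded per hour.
small_fly <- function() {
  memo("small_fly", {
    cfg <- synth_config(n_flies = 1, n_hours = 2, seconds_per_hour = 30,
                        seed = 5)
    c(simulate_fly(cfg, fly_index = 1), list(config = cfg))
  })
}

# Rendered single-behavior pose, no corruption.
render_single <- function(behavior, n = 1000, seed = 11, noise = FALSE,
                          seconds_per_hour = 3600) {
  cfg <- synth_config(seed = seed, seconds_per_hour = seconds_per_hour,
                      noise_sd_mm = if (noise) 0.02 else 0)
  render_pose(rep(behavior, n), default_archetypes(), cfg, seed = seed)
}

# Hourly composition cohort computed from ground-truth state sequences
# (no rendering), at a chosen seconds-per-hour scale.
truth_composition_cohort <- function(n_flies = 2, n_hours = 48,
                                     seconds_per_hour = 3600, seed = 1,
                                     schedule = diurnal_schedule()) {
  parts <- NULL; meta <- NULL
  for (fly in seq_len(n_flies)) {
    n <- n_hours * seconds_per_hour * 100
    s <- generate_state_sequence(schedule, default_archetypes(), n,
                                 fps = 100, seed = seed * 100 + fly,
                                 seconds_per_hour = seconds_per_hour)
    e <- ethogram(s, fps = 100, t0_clock = 8,
                  fly_id = sprintf("fly%02d", fly),
                  frames_per_hour = 100 * seconds_per_hour)
    ct <- hourly_compositions(e)
    parts <- rbind(parts, ct$parts)
    meta <- rbind(meta, ct$meta)
    rm(s, e)
  }
  composition_table(parts, meta)
}

# Random strictly positive composition rows.
random_compositions <- function(n, D = 7, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * D, 0.05, 1), n, D)
    m <- m / rowSums(m)
    colnames(m) <- if (D == 7) behavior_alphabet() else paste0("p", seq_len(D))
    m
  })
}

# Random orthogonal rotation of an ilr basis (another valid basis).
rotated_basis <- function(basis, seed = 1) {
  d <- nrow(basis)
  Q <- withr::with_seed(seed, qr.Q(qr(matrix(rnorm(d * d), d, d))))
  structure(Q %*% basis, class = class(basis))
}
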