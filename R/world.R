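# Definitions of the synthetic world: behavior archetypes, the diurnal
# schedule, and the simulation configuration. These are the stated conditions
# under which all validation fixtures are generated; they are chosen once to
# be realistic for a walking fly viewed at 100 Hz and are not tuned.

#' Construct a behavior archetype
#'
#' An archetype describes the kinematic signature of one stereotyped
#' behavior: which nodes oscillate (frequency and amplitude per node), how
#' fast the body translates, and how often the proboscis is visible.
#'
#' @param name Behavior label, one of [behavior_alphabet()].
#' @param oscillations Data frame with columns `node`, `freq_hz`,
#'   `amplitude_mm` (may have zero rows for non-oscillatory behaviors).
#' @param translation_speed_mm_s Mean body translation speed (mm/s); 0 for
#'   behaviors performed in place.
#' @param proboscis_visible Per-frame probability that the proboscis keypoint
#'   is extended (and hence trackable).
#' @return An object of class `behavior_archetype`.
#' @export
behavior_archetype <- function(name, oscillations = NULL,
                               translation_speed_mm_s = 0,
                               proboscis_visible = 0) {
  check_labels(name, behavior_alphabet())
  if (is.null(oscillations)) {
    oscillations <- data.frame(node = character(0), freq_hz = numeric(0),
                               amplitude_mm = numeric(0))
  }
  stopifnot(all(c("node", "freq_hz", "amplitude_mm") %in% names(oscillations)))
  check_labels(oscillations$node, skeleton_nodes(), "node")
  if (any(oscillations$freq_hz <= 0 | oscillations$freq_hz >= 50)) {
    stop("oscillation frequencies must lie in (0, 50) Hz (Nyquist at 100 fps)")
  }
  if (any(oscillations$amplitude_mm < 0)) stop("amplitudes must be >= 0")
  if (translation_speed_mm_s < 0) stop("translation speed must be >= 0")
  if (name == "idle" && (nrow(oscillations) > 0 || translation_speed_mm_s > 0)) {
    stop("the idle archetype has zero amplitude and zero speed by definition")
  }
  structure(list(name = name, oscillations = oscillations,
                 translation_speed_mm_s = translation_speed_mm_s,
                 proboscis_visible = proboscis_visible),
            class = "behavior_archetype")
}

#' Default behavior archetypes
#'
#' One archetype per label of the seven-behavior alphabet. Oscillation
#' frequencies are placed in the walking/grooming band (2-12 Hz) with
#' distinct node sets per behavior so that behaviors are spectrally
#' discriminable; amplitudes are of order 1 mm (leg-sweep scale for a ~3 mm
#' body).
#'
#' @return Named list of `behavior_archetype` objects.
#' @export
default_archetypes <- function() {
  legs <- c("forelegL", "forelegR", "midlegL", "midlegR",
            "hindlegL", "hindlegR")
  osc <- function(nodes, f, a) {
    data.frame(node = nodes, freq_hz = f, amplitude_mm = a)
  }
  list(
    idle = behavior_archetype("idle"),
    proboscis = behavior_archetype(
      "proboscis", osc("proboscis", 2, 1.5),
      proboscis_visible = 0.95),
    fore_groom = behavior_archetype(
      "fore_groom", osc(c("forelegL", "forelegR"), 8, 1.2)),
    hind_groom = behavior_archetype(
      "hind_groom", osc(c("hindlegL", "hindlegR"), 10, 1.2)),
    wing_groom = behavior_archetype(
      "wing_groom", rbind(osc(c("wingL", "wingR"), 5, 1.0),
                          osc(c("hindlegL", "hindlegR"), 5, 0.8))),
    locomotion = behavior_archetype(
      "locomotion", osc(legs, 12, 1.0), translation_speed_mm_s = 3),
    altered_locomotion = behavior_archetype(
      "altered_locomotion", rbind(osc(legs, 4, 1.2), osc("abdomen", 4, 0.6)),
      translation_speed_mm_s = 1)
  )
}

#' Construct a diurnal schedule
#'
#' The schedule carries everything that modulates behavior with Zeitgeber
#' time (ZT): relative state-occupancy weights for the light phase
#' (ZT 0-12) and dark phase (ZT 12-24), per-behavior two-geometric dwell
#' mixtures, and optional night-time modifiers.
#'
#' @param lights_on_hour Wall-clock hour mapped to ZT 0 (default 8).
#' @param day_state_weights,night_state_weights Named non-negative weights
#'   over [behavior_alphabet()]; target fractions of frames per phase.
#' @param dwell Data frame with columns `behavior`, `w`, `p_short`, `p_long`:
#'   mixture weight of the short component and geometric success
#'   probabilities (dwell support starts at 1 frame).
#' @param night_dwell_factor Named numeric: multiplies the mean dwell of the
#'   listed behaviors during the dark phase (default: proboscis bouts 1.5x
#'   longer at night).
#' @param night_speed_factor Multiplies translation speeds during the dark
#'   phase (default 2/3: 3 mm/s day, 2 mm/s night locomotion).
#' @param contrast_decay Optional numeric vector of per-day multipliers in
#'   [0, 1] applied to the day-night weight contrast (1 = full contrast);
#'   day d beyond the vector reuses its last element.
#' @return An object of class `diurnal_schedule`.
#' @export
diurnal_schedule <- function(lights_on_hour = 8,
                             day_state_weights = NULL,
                             night_state_weights = NULL,
                             dwell = NULL,
                             night_dwell_factor = c(proboscis = 1.5),
                             night_speed_factor = 2 / 3,
                             contrast_decay = NULL) {
  alpha <- behavior_alphabet()
  if (is.null(day_state_weights)) {
    day_state_weights <- c(idle = 0.35, proboscis = 0.07, fore_groom = 0.12,
                           hind_groom = 0.08, wing_groom = 0.08,
                           locomotion = 0.22, altered_locomotion = 0.08)
  }
  if (is.null(night_state_weights)) {
    night_state_weights <- c(idle = 0.70, proboscis = 0.08, fore_groom = 0.05,
                             hind_groom = 0.03, wing_groom = 0.03,
                             locomotion = 0.08, altered_locomotion = 0.03)
  }
  if (is.null(dwell)) {
    dwell <- data.frame(
      behavior = alpha,
      w       = c(0.40, 0.30, 0.30, 0.30, 0.30, 0.25, 0.30),
      p_short = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.04, 0.05),
      p_long  = c(0.00125, 0.004, 1 / 300, 1 / 300, 1 / 300, 0.0025, 1 / 300))
  }
  check_labels(names(day_state_weights), alpha)
  check_labels(names(night_state_weights), alpha)
  check_labels(dwell$behavior, alpha)
  for (wts in list(day_state_weights, night_state_weights)) {
    if (any(wts < 0) || sum(wts) <= 0) {
      stop("state weights must be >= 0 and not all zero")
    }
  }
  stopifnot(all(dwell$p_short > 0), all(dwell$p_short <= 1),
            all(dwell$p_long > 0), all(dwell$p_long <= 1),
            all(dwell$w >= 0), all(dwell$w <= 1))
  structure(list(lights_on_hour = lights_on_hour,
                 day_state_weights = day_state_weights,
                 night_state_weights = night_state_weights,
                 dwell = dwell,
                 night_dwell_factor = night_dwell_factor,
                 night_speed_factor = night_speed_factor,
                 contrast_decay = contrast_decay),
            class = "diurnal_schedule")
}

#' Simulation configuration
#'
#' Recording-geometry defaults follow the experimental setup the pipeline is
#' designed for: 100 Hz video at 28.25 px/mm in a 25 mm circular arena.
#' `seconds_per_hour` compresses each ZT hour to a shorter recorded segment
#' so that multi-day fixtures stay desk-sized; 3600 gives real time.
#'
#' @param fps Frames per second (default 100).
#' @param px_per_mm Spatial calibration (default 28.25).
#' @param arena_diameter_mm Arena diameter (default 25).
#' @param n_flies,n_hours Cohort size and recording length in ZT hours.
#' @param seconds_per_hour Recorded seconds representing one ZT hour.
#' @param seed Base RNG seed for the cohort.
#' @param missing_rate Per-node per-frame dropout probability.
#' @param edge_bout_rate Wall-visit starts per second.
#' @param edge_bout_duration_s Mean wall-visit duration (s).
#' @param noise_sd_mm Gaussian tracking jitter (mm).
#' @param heading_sd Heading random-walk increment SD (rad per sqrt s).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fps = 100, px_per_mm = 28.25, arena_diameter_mm = 25,
                         n_flies = 2, n_hours = 48, seconds_per_hour = 3600,
                         seed = 1, missing_rate = 0.05,
                         edge_bout_rate = 0.025, edge_bout_duration_s = 2,
                         noise_sd_mm = 0.02, heading_sd = 1.2) {
  stopifnot(fps > 0, px_per_mm > 0, arena_diameter_mm > 0,
            seconds_per_hour > 0,
            missing_rate >= 0, missing_rate <= 1,
            edge_bout_rate >= 0, noise_sd_mm >= 0)
  structure(list(fps = fps, px_per_mm = px_per_mm,
                 arena_diameter_mm = arena_diameter_mm,
                 n_flies = n_flies, n_hours = n_hours,
                 seconds_per_hour = seconds_per_hour, seed = seed,
                 missing_rate = missing_rate,
                 edge_bout_rate = edge_bout_rate,
                 edge_bout_duration_s = edge_bout_duration_s,
                 noise_sd_mm = noise_sd_mm, heading_sd = heading_sd),
            class = "synth_config")
}

# Rigid body template (mm, body frame: +x anterior). Head 2.5 mm anterior of
# the thorax, legs on a ~1.5 mm lateral arc. Geometry is a scaffold choice.
body_template <- function() {
  m <- rbind(
    head      = c( 2.5,  0.0),
    eyeL      = c( 2.3,  0.5),
    eyeR      = c( 2.3, -0.5),
    proboscis = c( 3.0,  0.0),  # 0.5 mm anterior of the head when visible
    thorax    = c( 0.0,  0.0),
    abdomen   = c(-2.5,  0.0),
    wingL     = c(-3.5,  0.9),
    wingR     = c(-3.5, -0.9),
    forelegL  = c( 1.5,  1.2),
    forelegR  = c( 1.5, -1.2),
    midlegL   = c( 0.0,  1.5),
    midlegR   = c( 0.0, -1.5),
    hindlegL  = c(-1.5,  1.4),
    hindlegR  = c(-1.5, -1.4))
  m[skeleton_nodes(), , drop = FALSE]
}

# Mean dwell (frames) of a two-geometric mixture with support starting at 1.
mixture_mean_dwell <- function(w, p_short, p_long) {
  w / p_short + (1 - w) / p_long
}
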