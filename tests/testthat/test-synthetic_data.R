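# Generator: semi-Markov state sequences, kinematic rendering, corruption.

one_behavior_schedule <- function(w = 0.7, p_short = 0.5, p_long = 0.02) {
  diurnal_schedule(
    day_state_weights = c(idle = 1), night_state_weights = c(idle = 1),
    dwell = data.frame(behavior = "idle", w = w, p_short = p_short,
                       p_long = p_long))
}

test_that("state sequences honor the dwell mixture and the empty case", {
  s0 <- generate_state_sequence(diurnal_schedule(), default_archetypes(), 0)
  expect_length(s0, 0)
  expect_equal(nrow(attr(s0, "bouts")), 0)

  s <- generate_state_sequence(one_behavior_schedule(),
                               default_archetypes()["idle"], 1e6, seed = 3)
  d <- attr(s, "bouts")$duration
  analytic <- 0.7 / 0.5 + 0.3 / 0.02  # 16.4 frames
  expect_lt(abs(mean(d) - analytic) / analytic, 0.02)
  b <- attr(s, "bouts")
  expect_equal(sum(b$end - b$start), length(s))  # bouts tile the sequence

  expect_error(
    generate_state_sequence(
      diurnal_schedule(day_state_weights = c(bogus = 1)),
      default_archetypes(), 10),
    "unknown behavior")
})

test_that("diurnal weights produce more day locomotion than night", {
  # frames within a bout are perfectly correlated, so the effective sample
  # size is the bout count; 1e6 frames give a decisive frame-level test
  s <- generate_state_sequence(diurnal_schedule(), default_archetypes(),
                               1e6, fps = 100, seed = 2,
                               seconds_per_hour = 40)
  zt <- ((seq_along(s) - 1) / (100 * 40)) %% 24
  day_loco <- sum(s[zt < 12] == "locomotion")
  night_loco <- sum(s[zt >= 12] == "locomotion")
  n_day <- sum(zt < 12); n_night <- sum(zt >= 12)
  tst <- prop.test(c(day_loco, night_loco), c(n_day, n_night),
                   alternative = "greater")
  expect_lt(tst$p.value, 0.01)
})

test_that("occupancy converges to the schedule weights", {
  w <- c(idle = 0.4, proboscis = 0.1, fore_groom = 0.1, hind_groom = 0.1,
         wing_groom = 0.1, locomotion = 0.15, altered_locomotion = 0.05)
  sch <- diurnal_schedule(day_state_weights = w, night_state_weights = w)
  s <- generate_state_sequence(sch, default_archetypes(), 2e6, seed = 9)
  frac <- table(factor(s, levels = names(w))) / length(s)
  tv <- sum(abs(as.numeric(frac) - w)) / 2
  expect_lt(tv, 0.02)
})

test_that("generator output is reproducible for a fixed seed", {
  a <- generate_state_sequence(diurnal_schedule(), default_archetypes(),
                               5000, seed = 42)
  b <- generate_state_sequence(diurnal_schedule(), default_archetypes(),
                               5000, seed = 42)
  expect_identical(a, b)
  cfg <- synth_config(n_flies = 1, n_hours = 1, seconds_per_hour = 10,
                      seed = 13)
  expect_identical(simulate_fly(cfg), simulate_fly(cfg))
})

test_that("rendering: idle is stationary, locomotion steps match speed", {
  cfg0 <- synth_config(noise_sd_mm = 0, seed = 4)
  idle <- render_pose(rep("idle", 400), default_archetypes(), cfg0, seed = 4)
  present <- setdiff(skeleton_nodes(), "proboscis")  # retracted when idle
  disp <- apply(idle$coords[, present, , drop = FALSE], 2:3,
                function(v) max(abs(diff(v))))
  expect_lt(max(disp), 1e-9)

  loco <- render_pose(rep("locomotion", 5000), default_archetypes(), cfg0,
                      seed = 4)
  th <- loco$coords[, "thorax", ]
  step <- sqrt(diff(th[, 1])^2 + diff(th[, 2])^2)
  expect_lt(abs(mean(step) - 3 * 28.25 / 100) / (3 * 28.25 / 100), 0.05)
})

test_that("rendered grooming oscillation recovers its frequency", {
  pose <- render_single("fore_groom", n = 1000, seed = 8)
  ego <- egocentrize(pose)
  grid <- frequency_grid()
  p <- lomb_scargle((0:499) / 100, ego$coords[1:500, "forelegL", 1], grid)
  peak <- grid$freqs_hz[which.max(p)]
  i8 <- which.min(abs(grid$freqs_hz - 8))
  expect_lte(abs(which.max(p) - i8), 1)
  expect_gt(peak, 6.5); expect_lt(peak, 10)
})

test_that("corrupt is a no-op when all rates are zero", {
  pose <- render_single("locomotion", n = 300, seed = 2)
  cfg <- synth_config(missing_rate = 0, edge_bout_rate = 0, noise_sd_mm = 0)
  out <- corrupt(pose, cfg, seed = 1)
  expect_identical(out$pose$coords, pose$coords)
  expect_identical(out$pose$missing, pose$missing)
  expect_false(any(out$truth$true_edge_mask))
})

test_that("corrupt drops nodes at the configured rate", {
  pose <- render_single("idle", n = 8000, seed = 3)
  cfg <- synth_config(missing_rate = 0.1, edge_bout_rate = 0, noise_sd_mm = 0)
  out <- corrupt(pose, cfg, seed = 6)
  # exclude the proboscis column: the renderer already masked it
  m <- out$pose$missing[, setdiff(colnames(out$pose$missing), "proboscis")]
  expect_lt(abs(mean(m) - 0.1), 0.01)
})

test_that("edge bouts pin the thorax to the wall and occlude legs", {
  pose <- render_single("locomotion", n = 6000, seed = 10)
  cfg <- synth_config(missing_rate = 0, edge_bout_rate = 0.2,
                      edge_bout_duration_s = 1, noise_sd_mm = 0)
  out <- corrupt(pose, cfg, seed = 21)
  em <- out$truth$true_edge_mask
  expect_gt(sum(em), 0)
  arena <- arena_from_config(cfg)
  r <- ethospan:::node_radius_px(out$pose, arena, "thorax")
  expect_true(all(r[em] > 0.9 * arena$radius_px))
  expect_true(all(out$pose$missing[em, "forelegL"]))
})
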