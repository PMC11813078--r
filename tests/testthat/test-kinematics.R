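# Zeitgeber time, locomotion speed, bout durations, radial occupancy.

test_that("zeitgeber time wraps and counts days", {
  expect_equal(zeitgeber_time(8, 8)$zt_hours, 0)
  z <- zeitgeber_time(20, 8)       # lights-off same day
  expect_equal(z$zt_hours, 12); expect_equal(z$day_index, 1)
  z2 <- zeitgeber_time(24 + 7, 8)  # 07:00 next day
  expect_equal(z2$zt_hours, 23); expect_equal(z2$day_index, 1)
  z3 <- zeitgeber_time(24 + 9, 8)
  expect_equal(z3$zt_hours, 1); expect_equal(z3$day_index, 2)
  expect_error(zeitgeber_time(5, 8), "precedes")
})

straight_pose <- function(n, step_px, fps = 100, px_per_mm = 28.25) {
  coords <- array(0, c(n, 14, 2))
  tmpl <- ethospan:::body_template() * px_per_mm
  for (i in seq_len(n)) {
    coords[i, , 1] <- tmpl[, 1] + (i - 1) * step_px
    coords[i, , 2] <- tmpl[, 2]
  }
  pose_sequence(coords, matrix(FALSE, n, 14), fps = fps,
                px_per_mm = px_per_mm, frames_per_hour = fps * 3600)
}

test_that("locomotion speed converts px/frame to mm/s", {
  n <- 200
  pose0 <- straight_pose(n, 0)
  e <- ethogram(rep("locomotion", n), fps = 100, frames_per_hour = 360000)
  s0 <- locomotion_speed(pose0, e)
  expect_equal(max(abs(s0$speed_mm_s)), 0)

  pose1 <- straight_pose(n, 1)
  s1 <- locomotion_speed(pose1, e)
  expect_equal(unique(round(s1$speed_mm_s, 4)), 3.5398)
  expect_equal(nrow(s1), n)  # only locomotion frames, here all of them
})

test_that("speed windows never cross bout boundaries", {
  n <- 30
  pose <- straight_pose(n, 1, fps = 1, px_per_mm = 1)
  # large jump between bout 1 (frames 1-10) and bout 2 (frames 21-30)
  pose$coords[11:20, , 1] <- pose$coords[11:20, , 1] + 500
  labels <- c(rep("locomotion", 10), rep("idle", 10), rep("locomotion", 10))
  e <- ethogram(labels, fps = 1, frames_per_hour = 3600)
  s <- locomotion_speed(pose, e, window = 5)
  # interior of each locomotion bout moves at 1 px/frame = 1 mm/s; the jump
  # at the idle boundary must not leak into the locomotion windows
  expect_equal(unname(s$speed_mm_s[s$frame %in% 3:8]), rep(1, 6))
  expect_equal(unname(s$speed_mm_s[s$frame %in% 24:29]), rep(1, 6))
  expect_true(all(s$speed_mm_s < 100))

  # a bout shorter than the window gets its plain mean
  e2 <- ethogram(c(rep("idle", 13), rep("locomotion", 3), rep("idle", 14)),
                 fps = 1, frames_per_hour = 3600)
  s2 <- locomotion_speed(straight_pose(n, 2, fps = 1, px_per_mm = 1), e2,
                         window = 5)
  expect_equal(nrow(s2), 3L)
  expect_equal(unname(s2$speed_mm_s), rep(2, 3))
})

test_that("speeds are invariant to global rotation and translation", {
  fly <- small_fly()
  pose <- interpolate_pose(fly$pose)
  e <- ethogram(fly$truth$true_ethogram, fps = 100,
                frames_per_hour = pose$frames_per_hour)
  s1 <- locomotion_speed(pose, e)
  rot <- pose
  th <- 0.6
  x <- pose$coords[, , 1]; y <- pose$coords[, , 2]
  rot$coords[, , 1] <- cos(th) * x - sin(th) * y + 11
  rot$coords[, , 2] <- sin(th) * x + cos(th) * y - 4
  s2 <- locomotion_speed(rot, e)
  expect_equal(s1$speed_mm_s, s2$speed_mm_s, tolerance = 1e-9)
})

test_that("generator round-trip recovers the day/night speed contrast", {
  cfg <- synth_config(n_flies = 1, n_hours = 24, seconds_per_hour = 20,
                      seed = 31, missing_rate = 0, edge_bout_rate = 0,
                      noise_sd_mm = 0)
  fly <- simulate_fly(cfg)
  e <- ethogram(fly$truth$true_ethogram, fps = 100,
                frames_per_hour = 100 * 20)
  s <- locomotion_speed(fly$pose, e)
  by_hour <- speed_by_group(s, "zt_hour")
  day_mean <- mean(by_hour$mean_mm_s[by_hour$zt_hour < 12])
  night_mean <- mean(by_hour$mean_mm_s[by_hour$zt_hour >= 12])
  expect_lt(abs(day_mean - 3) / 3, 0.05)
  expect_lt(abs(night_mean - 2) / 2, 0.05)
})

test_that("bout durations group by start hour and recover contrasts", {
  lab <- c(rep("proboscis", 300), rep("idle", 100))
  e <- ethogram(lab, fps = 100, frames_per_hour = 360000)
  st <- bout_duration_stats(e, "proboscis")
  expect_equal(st$mean_s, 3.0)
  expect_equal(st$n_bouts, 1L)

  # a bout straddling the ZT 12 boundary counts in hour 11
  fph <- 100
  lab2 <- c(rep("idle", 12 * fph - 2), rep("proboscis", 4), rep("idle", 96))
  e2 <- ethogram(lab2, fps = 100, frames_per_hour = fph)
  st2 <- bout_duration_stats(e2, "proboscis")
  expect_equal(st2$group, 11)

  # day bouts mean 2 s, night bouts drawn 1.5x longer (3 s)
  fph3 <- 60000  # 10 recorded minutes per ZT hour
  lab3 <- withr::with_seed(40, unlist(lapply(0:23, function(h) {
    p <- if (h < 12) 1 / 200 else 1 / 300
    out <- character(0)
    while (length(out) < fph3) {
      out <- c(out, rep(c("proboscis", "idle"), c(rgeom(1, p) + 1, 5)))
    }
    out[seq_len(fph3)]
  })))
  e3 <- ethogram(lab3, fps = 100, frames_per_hour = fph3)
  st3 <- bout_duration_stats(e3, "proboscis")
  pooled <- function(rows) {
    sum(st3$mean_s[rows] * st3$n_bouts[rows]) / sum(st3$n_bouts[rows])
  }
  ratio <- pooled(st3$group >= 12) / pooled(st3$group < 12)
  expect_lt(abs(ratio - 1.5), 0.1)
})

test_that("radial occupancy uses equal-area bins", {
  arena <- arena_geometry(c(0, 0), radius_px = 100, px_per_mm = 8)
  n <- 1e5
  coords <- array(0, c(n, 14, 2))
  r <- withr::with_seed(3, sqrt(runif(n)) * 100)
  a <- withr::with_seed(4, runif(n, 0, 2 * pi))
  tj <- match("thorax", skeleton_nodes())
  coords[, tj, 1] <- r * cos(a); coords[, tj, 2] <- r * sin(a)
  pose <- pose_sequence(coords, matrix(FALSE, n, 14), px_per_mm = 8)
  occ <- radial_occupancy(pose, arena, n_bins = 10)
  expect_gt(chisq.test(occ$counts)$p.value, 0.01)

  coords0 <- coords; coords0[, tj, ] <- 0
  pose0 <- pose_sequence(coords0[1:100, , , drop = FALSE],
                         matrix(FALSE, 100, 14), px_per_mm = 8)
  occ0 <- radial_occupancy(pose0, arena, n_bins = 10)
  expect_equal(occ0$counts[1], 100L)
  expect_true(all(occ0$counts[-1] == 0))
})

test_that("wall-visiting cohorts pile up in the outer annulus", {
  fly <- small_fly()
  arena <- arena_from_config(fly$config)
  e <- ethogram(ifelse(fly$truth$true_edge_mask, "edge",
                       fly$truth$true_ethogram),
                fps = 100, frames_per_hour = fly$pose$frames_per_hour)
  occ <- radial_occupancy(fly$pose, arena, e, n_bins = 10)
  edge_col <- occ$behavior_fractions[, "edge"]
  expect_gt(edge_col[10], max(edge_col[1:8]))
})
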