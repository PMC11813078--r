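# Compositional geometry, robust PCA, diurnal metrics, enrichment.

test_that("hourly compositions count frames correctly and exclude flags", {
  labels <- c(rep("idle", 1800), rep("locomotion", 1200),
              rep("fore_groom", 600))
  e <- ethogram(labels, fps = 1, frames_per_hour = 3600)
  ct <- hourly_compositions(e)
  expect_equal(nrow(ct$parts), 1L)
  raw <- c(idle = 0.5, locomotion = 1200 / 3600, fore_groom = 600 / 3600)
  expect_equal(ct$raw_parts[1, names(raw)], raw, tolerance = 1e-12)
  expect_equal(sum(ct$parts[1, ]), 1, tolerance = 1e-12)
  expect_true(all(ct$parts > 0))
  # replaced values deviate from raw only by the replacement mass
  expect_lt(max(abs(ct$parts[1, names(raw)] - raw)), 0.05)

  # edge frames drop out of the denominator
  labels2 <- c(rep("edge", 1800), rep("idle", 900), rep("locomotion", 900))
  e2 <- ethogram(labels2, fps = 1, frames_per_hour = 3600)
  ct2 <- hourly_compositions(e2)
  expect_equal(ct2$meta$n_frames_used, 1800L)
  expect_equal(unname(ct2$raw_parts[1, "idle"]), 0.5, tolerance = 1e-12)

  # an hour that is almost entirely flagged gets dropped
  labels3 <- c(rep("unstereotyped", 3500), rep("idle", 100))
  e3 <- ethogram(labels3, fps = 1, frames_per_hour = 3600)
  expect_warning(ct3 <- hourly_compositions(e3), "dropped")
  expect_equal(nrow(ct3$parts), 0L)
})

test_that("geometric mean composition matches the closed form", {
  x <- matrix(c(0.5, 0.3, 0.2, 0.2, 0.3, 0.5), 2, 3, byrow = TRUE)
  gm <- geometric_mean_composition(x)
  manual <- c(sqrt(0.1), 0.3, sqrt(0.1))  # element-wise geometric means
  expect_equal(unname(gm), manual / sum(manual), tolerance = 1e-12)
  expect_equal(round(unname(gm), 4), c(0.3391, 0.3217, 0.3391), tolerance = 1e-4)

  one <- random_compositions(1, seed = 2)
  expect_equal(geometric_mean_composition(one), one[1, ], tolerance = 1e-12)

  # permutation- and perturbation-equivariance (Aitchison)
  comps <- random_compositions(6, seed = 3)
  perm <- sample(7)
  expect_equal(unname(geometric_mean_composition(comps[, perm])),
               unname(geometric_mean_composition(comps)[perm]),
               tolerance = 1e-12)
  p <- random_compositions(1, seed = 4)[1, ]
  pert <- t(apply(comps, 1, function(r) r * p / sum(r * p)))
  expect_equal(unname(geometric_mean_composition(pert)),
               unname(ethospan:::closure(geometric_mean_composition(comps) * p)),
               tolerance = 1e-10)
})

test_that("clr and ilr are exact inverse pairs on a valid basis", {
  u <- rep(1 / 7, 7)
  expect_equal(clr(u), rep(0, 7), tolerance = 1e-12)
  B <- ilr_basis(7)
  expect_equal(B %*% t(B), diag(6), tolerance = 1e-10)
  expect_equal(as.numeric(B %*% rep(1, 7)), rep(0, 6), tolerance = 1e-10)

  comps <- random_compositions(20, seed = 5)
  expect_lt(max(abs(rowSums(clr(comps)))), 1e-10)
  expect_lt(max(abs(ilr_inverse(ilr(comps, B), B) - comps)), 1e-10)
  v <- comps[1, ]
  expect_lt(max(abs(ilr_inverse(ilr(v, B), B) - v)), 1e-10)
  expect_error(clr(c(0.5, 0, 0.5)), "positive")
})

test_that("composition PCA is basis-invariant with zero-sum clr loadings", {
  comps <- truth_composition_cohort(n_flies = 1, n_hours = 24,
                                    seconds_per_hour = 120, seed = 6)
  B1 <- ilr_basis(7)
  B2 <- rotated_basis(B1, seed = 8)
  p1 <- robust_composition_pca(comps, B1, seed = 4)
  p2 <- robust_composition_pca(comps, B2, seed = 4)
  expect_lt(max(abs(colSums(p1$clr_loadings))), 1e-9)
  expect_lt(max(abs(p1$clr_loadings - p2$clr_loadings)), 1e-8)
  expect_lt(max(abs(p1$scores - p2$scores)), 1e-8)
  expect_true(all(diff(p1$variance_explained) < 1e-12))
  expect_lte(sum(p1$variance_explained), 1 + 1e-9)
  expect_gte(p1$clr_loadings["locomotion", 1], 0)
})

test_that("MCD PCA resists gross outliers on a diurnal contrast axis", {
  set.seed(10)
  n <- 80
  day <- rep(c(TRUE, FALSE), each = n / 2)
  base <- log(c(idle = 0.3, proboscis = 0.05, fore_groom = 0.1,
                hind_groom = 0.08, wing_groom = 0.07, locomotion = 0.3,
                altered_locomotion = 0.1))
  axis <- c(idle = -1, proboscis = 0, fore_groom = 0.2, hind_groom = 0.1,
            wing_groom = 0.1, locomotion = 0.8, altered_locomotion = -0.2)
  logx <- t(vapply(seq_len(n), function(i) {
    base + (if (day[i]) 0.8 else -0.8) * axis + rnorm(7, 0, 0.1)
  }, numeric(7)))
  parts <- exp(logx) / rowSums(exp(logx))
  out_idx <- 1:4  # 5% gross outliers: proboscis-dominated hours
  parts[out_idx, ] <- rep(c(0.02, 0.88, 0.02, 0.02, 0.02, 0.02, 0.02),
                          each = length(out_idx))
  colnames(parts) <- behavior_alphabet()
  tab <- composition_table(ethospan:::replace_zeros(parts))
  rob <- robust_composition_pca(tab, robust = TRUE, seed = 2)
  expect_gt(rob$clr_loadings["locomotion", 1], 0)
  expect_lt(rob$clr_loadings["idle", 1], 0)
  expect_gt(cor(rob$scores[, 1], as.numeric(day)), 0.9)
})

test_that("day/night difference computes per-day contrasts", {
  zt <- rep(c(3, 9, 15, 21), 2)
  day_idx <- rep(1:2, each = 4)
  s0 <- rep(1, 8)
  d0 <- day_night_difference(s0, zt, day_idx)
  expect_equal(d0$mean_diff, c(0, 0))

  s <- ifelse(zt >= 12, -1, 1)  # night = day - 2
  d <- day_night_difference(s, zt, day_idx)
  expect_equal(d$mean_diff, c(2, 2))

  # a day with only day-hours contributes a missing value
  d2 <- day_night_difference(c(1, 1, 0, 5), c(3, 15, 9, 10), c(1, 1, 2, 2))
  expect_equal(d2$n_flies, c(1L, 0L))
})

test_that("condensation and ternary coordinates match the formulas", {
  v <- c(idle = 0.4, proboscis = 0.05, fore_groom = 0.1, hind_groom = 0.1,
         wing_groom = 0.1, locomotion = 0.2, altered_locomotion = 0.05)
  c3 <- condense(v)
  expect_equal(unname(c3), c(0.30, 0.25, 0.45), tolerance = 1e-12)
  expect_equal(names(c3), c("groom", "loco", "rest"))

  expect_equal(unname(ternary_coords(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(ternary_coords(c(1, 1, 1) / 3)),
               c(0.5, sqrt(3) / 6), tolerance = 1e-12)
})

test_that("PC direction curves are Aitchison group orbits", {
  center <- random_compositions(1, seed = 9)[1, ]
  load <- clr(random_compositions(1, seed = 10)[1, ])
  expect_equal(pc_direction_curve(center, load, 0)[1, ], center,
               tolerance = 1e-12)
  c1 <- pc_direction_curve(center, load, 0.4)[1, ]
  c2 <- pc_direction_curve(c1, load, 0.7)[1, ]
  c12 <- pc_direction_curve(center, load, 1.1)[1, ]
  expect_lt(max(abs(c2 - c12)), 1e-10)

  # groom-aligned loading moves the condensed groom coordinate monotonically
  gl <- clr(c(idle = 0.1, proboscis = 0.1, fore_groom = 0.25,
              hind_groom = 0.25, wing_groom = 0.25, locomotion = 0.1,
              altered_locomotion = 0.1))
  curve <- pc_direction_curve(center, gl, seq(-2, 2, by = 0.5))
  groom <- condense(curve)[, "groom"]
  expect_true(all(diff(groom) > 0))
})

test_that("enrichment bootstrap brackets the ratio", {
  ref <- random_compositions(1, seed = 11)[1, ]
  hours <- do.call(rbind, replicate(5, ref, simplify = FALSE))
  e1 <- enrichment_bootstrap(hours, ref, "fore_groom", n_boot = 200, seed = 1)
  expect_equal(e1$ratio, 1, tolerance = 1e-10)
  expect_lte(e1$ci_low, 1 + 1e-10); expect_gte(e1$ci_high, 1 - 1e-10)

  # every fly identical with the part exactly 2x the reference (re-closed on
  # the other parts so rows still sum to 1)
  fg <- ref[["fore_groom"]]
  row2 <- ref
  row2["fore_groom"] <- 2 * fg
  row2[names(row2) != "fore_groom"] <-
    ref[names(ref) != "fore_groom"] * (1 - 2 * fg) / (1 - fg)
  exact <- do.call(rbind, replicate(5, row2, simplify = FALSE))
  e2 <- enrichment_bootstrap(exact, ref, "fore_groom", n_boot = 200, seed = 2)
  expect_equal(e2$ratio, 2, tolerance = 1e-10)
  expect_lt(e2$ci_high - e2$ci_low, 1e-10)  # degenerate bootstrap
  expect_warning(enrichment_bootstrap(exact, ref, "fore_groom", n_boot = 50),
                 "n_boot")
})

test_that("a morning grooming boost is detected with CI excluding 1", {
  hits <- 0L
  for (seed in 1:20) {
    flies <- withr::with_seed(seed, {
      base <- random_compositions(6, seed = seed + 100)
      t(apply(base, 1, function(r) {
        r[c("fore_groom", "hind_groom", "wing_groom")] <-
          r[c("fore_groom", "hind_groom", "wing_groom")] * 2.5
        r / sum(r)
      }))
    })
    ref <- condense(geometric_mean_composition(
      random_compositions(6, seed = seed + 100)))
    e <- enrichment_bootstrap(flies, ref, "groom", n_boot = 300, seed = seed)
    if (e$ratio > 1 && e$ci_low > 1) hits <- hits + 1L
  }
  expect_gte(hits, 11L)  # 20-seed majority
})

test_that("compositions are invariant to count rescaling", {
  labels <- rep(c("idle", "locomotion", "fore_groom"), times = c(60, 30, 10))
  e1 <- ethogram(labels, fps = 1, frames_per_hour = 100)
  e3 <- ethogram(rep(labels, each = 3), fps = 3, frames_per_hour = 300)
  expect_equal(hourly_compositions(e1)$parts, hourly_compositions(e3)$parts,
               tolerance = 1e-12)
})
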