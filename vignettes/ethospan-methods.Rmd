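---
title: "ethospan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ethospan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models each
stage assumes, the parameters that matter (with units and defaults), what
the synthetic generator does and does not emulate, and the choices we made
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. The problem

A fly living alone in a 25 mm arena for days produces on the order of
10⁷–10⁸ pose frames. The analysis turns each frame into one of a small
behavior alphabet — idle, proboscis extension, fore/hind/wing grooming,
locomotion, altered locomotion — plus two flags (`edge`: the fly is on the
arena wall and tracking is unreliable; `unstereotyped`: postural dynamics
that match no stereotyped region), and then asks how the *composition* of
behaviors changes with time of day and across days.

## 2. Preprocessing

Missing keypoints are unavoidable in markerless tracking. Head and thorax
anchor the egocentric frame, so they are interpolated across *all* interior
gaps with a monotone piecewise-cubic Hermite polynomial (PCHIP;
`stats::splinefun(method = "monoH.FC")`), and leading/trailing gaps are
held at the nearest observation. Every other node except the proboscis is
PCHIP-filled only across gaps of at most `gap_limit = 5` consecutive frames
(50 ms at 100 Hz): longer occlusions are real data loss and stay missing.
A missing proboscis is a *retracted* proboscis, and takes the same-frame
head position.

Traces are then median-filtered (window 5) and Gaussian-filtered (σ = 1
sample, window 5). Both filters exclude missing frames from their windows
and renormalize at boundaries (shrinking-window for the median, kernel
renormalization for the Gaussian); the choice of boundary rule is ours —
the protocol we follow does not specify one. Filters are applied to
interpolated values as well: by that stage they are part of the trace.

Egocentrization translates the thorax to the origin and rotates the
thorax→head vector onto +x, per frame, recording heading and origin so the
transform is invertible (tested to < 10⁻⁶ px round trip). A frame with
coincident head and thorax reuses the previous frame's heading.

## 3. Spectral features

Behavior lives in the rhythm of the body parts, not in their static pose.
For each of the 26 channels (x and y of every node except the thorax,
which is identically zero in the body frame) we compute a rolling
Lomb–Scargle periodogram. Our estimator is the floating-mean least-squares
sinusoid fit: at frequency $f$, solve

$$\min_{\mu, a, b} \sum_{t \in W} \big(y_t - \mu - a\cos 2\pi f t - b\sin 2\pi f t\big)^2$$

over the *observed* samples of the window $W$ and report power
$(\hat a^2 + \hat b^2)/4$ (mm²). This is exactly the generalized
Lomb–Scargle periodogram; it needs no interpolation, and a complete evenly
sampled sinusoid of amplitude $A$ on the grid returns $A^2/4$ — which makes
the idle threshold (below) interpretable in mm². The test suite checks
agreement with an independent `lm()` oracle to < 10⁻⁸ relative error.

Parameters:

- **Frequency grid**: 25 log2-spaced frequencies in [0.5, 25] Hz
  (configurable). The protocol we implement does not print its grid; this
  is the MotionMapper convention, and 25 Hz stays under the 50 Hz Nyquist
  limit at 100 fps. Fly leg rhythms during walking and grooming sit at
  roughly 4–15 Hz, well inside the band.
- **Window**: `window_periods = 5` periods of each frequency (minimum 5
  frames), mimicking the frequency-proportional envelope of a continuous
  wavelet transform. At 0.5 Hz the window is 10 s; at 25 Hz it is 20 ms.
- **`min_occupancy` = 0.5**: a frame whose worst channel has fewer than
  half its window samples observed is marked invalid and later labeled
  unstereotyped. Prolonged occlusions (wall bouts) fail this test; isolated
  dropout does not.
- **Idle threshold = 0.5012 mm²** on the total power summed over all
  channels and frequencies. The value is the empirical motionless/moving
  separation of the reference protocol; "total amplitude" is read as the
  sum (the alternative, a max, is not what a threshold in mm² suggests).
  Both threshold and definition are configurable.

## 4. Edge detection

Wall-climbing flies are seen side-on; legs occlude and tracking degrades,
so wall frames are flagged rather than classified. Features per frame: all
78 pairwise distances among the 13 non-proboscis nodes, 13 node speeds
(centered differences; the estimator is our choice), and 13 node-to-wall
distances — all invariant to rotations about the arena center. The
classifier contract is "max-margin on standardized features"; with no SVM
package in the supported environment we fit a squared-hinge linear SVM by
BFGS, which is deterministic and exactly reproducible. Frames with
incomplete features predict `edge = TRUE` (occlusion co-occurs with wall
visits; configurable). On the synthetic wall fixture the held-out accuracy
requirement is ≥ 0.95; chance-level behavior under label permutation is
also asserted.

## 5. The behavior map

Training-set assembly follows fixed quotas per fly-hour group: remove edge
and sub-threshold frames, uniformly subsample to at most 36 000, then
importance-sample 454 points. Importance sampling is specified only as
"coverage-equalizing"; we estimate local density from the k-th nearest
neighbor distance (k = 20) and sample without replacement with probability
∝ 1/density. A literal inverse density in the 650-dimensional feature
space would exponentiate neighbor distances by the dimension and degenerate
into farthest-point picking, so the density model uses a fixed effective
dimension (2, configurable); in a 2-D feature space this *is* the literal
inverse density.

The 2-D embedding is UMAP (`uwot`, n_neighbors 15, min_dist 0.1,
single-threaded so a seed fixes the layout), kept as a model for
out-of-sample transformation of the full dataset in batches.

Segmentation estimates the kernel density of the embedded training points
on a 512² grid (per-axis Scott bandwidth × `kde_factor`). Two thresholds
follow. First, cells whose density is below the 5% quantile of the density
*at the training points* are background: a quantile over grid cells — the
naive reading — zeroes essentially nothing, because a Gaussian KDE is
positive everywhere, and we measured that it merges the whole map into one
region. Second, a sliding-block adaptive threshold (block 32 cells, offset
0.2 × peak density) isolates density peaks; their connected components
seed regions, and every remaining above-floor cell joins its nearest seed.
This keeps the contract that regions partition the above-threshold support,
and behaves like a watershed without implementing one. The defaults were
fixed once against the synthetic fixture (where the constructed number of
clusters is known) — the analog of the reference protocol's "adjusted by
eye".

Region → behavior naming is a human step in production (reviewing exemplar
clips). In this package's validation the generator's ground truth stands in
via majority vote of the training points inside each region; that mapping
is test scaffolding, not science.

Assignment precedence per frame: edge flag → `edge`; invalid features →
`unstereotyped`; total amplitude < threshold → `idle` (sub-threshold frames
are never embedded; residual idle-like regions found in the map also merge
into idle); otherwise embed and look up the region, with background and
out-of-extent points `unstereotyped`.

## 6. Bouts and dwell times

Dwell times pool short tracking-glitch bouts and long behavior bouts; a
two-component geometric mixture (support starting at 1 frame) separates
them. EM with 5 seeded restarts, convergence at |Δ log L| < 10⁻⁸ or 500
iterations; components are ordered p_short ≥ p_long; identical durations
fall back to a flagged single component. Parameter recovery within 5% at
n = 10⁵ is an acceptance property. The exclusion fraction
P(X < t) = 1 − (1−p)^(t−1) justifies the minimum bout length; the default
stays fixed at 5 frames rather than auto-selected.

Minimum-bout enforcement scans forward and relabels every short *behavior*
bout to the most recent long bout's label (leading shorts resolve forward).
`edge` and `unstereotyped` are classifier facts, not behaviors: short flag
bouts are never relabeled, though they may donate their label. On flag-free
ethograms the output provably contains no interior bout under the minimum,
and the operation is idempotent and length-preserving.

The mixture is fit to the pooled dwell histogram by default (the wording we
follow suggests pooling); per-behavior fits are available by passing
per-behavior durations.

## 7. Compositional analysis

Hourly 7-part fractions are computed over frames not flagged
edge/unstereotyped; hours retaining under 10% of their frames are dropped.
Zeros (rare behaviors in sparse hours) are replaced multiplicatively with
δ_j = half the smallest observed nonzero fraction of part j — the protocol
we follow acknowledges its zeros problem without stating a remedy, so the
strategy is configurable. Averages are geometric means (re-closed);
geometry is clr/ilr with a pivot basis, and every reported quantity is
basis-invariant (asserted to 10⁻⁸ under random basis rotation).

PCA uses the Minimum Covariance Determinant covariance
(`MASS::cov.rob`, support fraction 0.75, seeded) of the ilr coordinates so
that dying flies and tracking failures do not set the principal axes;
loadings are back-transformed to clr space where they read as per-behavior
contrasts summing to zero. Sign conventions — PC1 locomotion-positive, PC2
grooming-positive, later components largest-loading-positive — make results
deterministic and basis-independent. Day is ZT [0, 12), night [12, 24);
the day/night metric is |mean PC1(night) − mean PC1(day)| per fly-day,
averaged over flies with a standard error.

Condensation sums grooming parts, locomotion parts, and idle+proboscis
into a 3-part composition with ternary coordinates
x = (2b + c) / 2(a+b+c), y = √3 c / 2(a+b+c). PC directions become simplex
curves by Aitchison perturbation of the center composition with
exp(s · loading). Enrichment of a component at one ZT hour against a
reference is a ratio of geometric means with a percentile bootstrap over
flies (1000 replicates, seeded).

## 8. The synthetic world

The generator is the package's validation instrument. It emulates:

- **Diurnal state occupancy** — a semi-Markov chain whose bout-level
  transition weights are calibrated (by a closed-form root find) so that
  frame occupancy matches the schedule's day and night weights; defaults
  put ~70% idle at night vs ~35% by day, with locomotion and grooming
  elevated in the light phase.
- **Dwell mixtures** — per-behavior two-geometric mixtures with means of
  roughly 2–5 s (idle ~5 s); proboscis dwell means are 1.5× longer at
  night (the deep-sleep-associated pattern), and translation speed drops
  from 3 mm/s (day) to 2 mm/s (night).
- **Kinematics** — a rigid 14-node body template (head 2.5 mm anterior of
  thorax, legs on a ~1.5 mm lateral arc) carried along a heading random
  walk confined to the arena disc; each behavior oscillates its own node
  set at its own frequency (proboscis 2 Hz, wing groom 5 Hz, fore groom
  8 Hz, hind groom 10 Hz, locomotion 12 Hz, altered locomotion 4 Hz) with
  ~1 mm amplitudes. Frequencies and amplitudes are scaffold choices in the
  physiological band, fixed once; the reference protocol is an experiment
  and publishes no generative model.
- **Corruption** — per-node Bernoulli dropout (5%), 0.02 mm Gaussian
  jitter (the tracking-error scale of a sub-0.1 mm tracker), and wall
  bouts (rate 0.025 s⁻¹, mean 2 s ⇒ ~5% of time on the wall, matching the
  reported order) that pin the body to 96% of the arena radius and occlude
  all six tarsi.

It does **not** emulate: photorealistic appearance, 3-D posture,
wall-climbing kinematics (a planar annulus state suffices for an
edge-flaggable regime), inter-fly interaction, aging or death. A green
end-to-end test therefore establishes that the pipeline recovers the
statistical structure it assumes — not that it handles every failure mode
of real tracking.

### Desk-scale compression

`seconds_per_hour` records each ZT hour as a shorter segment (default
fixture: 60 s) so a 48-hour cohort stays minutes-sized. Frame-level
properties (spectral recovery, assignment accuracy) are unaffected.
Hour-level *compositional* statistics are not: a 60 s hour holds ~20 bouts
instead of ~1000, and multinomial bout noise then dominates the CLR
covariance — with ground-truth labels, PC1 aligns with the day/night axis
at correlation ≈ 0.98 at 3600 s/hour but ≈ 0.1–0.4 at 60 s/hour. The
acceptance suite therefore runs frame-level criteria through the full
pipeline on the compressed fixture, and compositional-recovery criteria on
full-hour-length ground-truth ethograms from the same generator (cheap,
since no rendering is involved). This is a choice of measurement path, not
a relaxation of thresholds.

## 9. Numerical notes

- All RNG consumption goes through isolated seeded streams (`withr`);
  fixed seeds give bit-identical outputs, asserted in the tests.
- Rolling Lomb–Scargle normal equations are solved in closed form from
  cumulative sums (O(n) per channel-frequency); windows with near-singular
  design (under-occupied, sub-period) return zero power and fail the
  occupancy test.
- EM for the dwell mixture works in log space; geometric tails of
  multi-hundred-frame bouts would underflow otherwise.
- MCD and UMAP are seeded; UMAP runs single-threaded for determinism.
- Degenerate inputs error early and specifically: empty skeletons,
  all-missing anchor nodes, single-class edge labels, unlabeled regions,
  rank-deficient compositions (e.g. a behavior absent from every hour of a
  tiny cohort — a real possibility at smoke-test scale, reported by part
  name).

## 10. Known limitations

- The behavior alphabet is fixed at seven; new behaviors require
  re-segmentation and re-naming.
- Region naming is only as good as its reference labels (human review in
  production, ground truth in validation).
- The edge classifier is trained on clean wall fixtures; real wall
  postures are messier, and the conservative missing-features rule does
  some of the work.
- Compressed fixtures cannot validate hour-scale compositional statistics
  end-to-end (see §8); only full-length recordings can.
- The dwell mixture is fit pooled across behaviors; strongly heterogeneous
  per-behavior dwell scales would motivate per-behavior thresholds, which
  we deliberately do not auto-select.
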