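---
title: "Quantifying copper-barrier sensory-integration assays from worm tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying copper-barrier sensory-integration assays from worm tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coppertracks)
```

## The measurement problem

In the sensory-integration assay, a population of *C. elegans* is placed on
one side of a stripe of copper sulfate — a contact repellent — with a
volatile attractant (diacetyl) on the far side. Hungrier animals accept
more risk and cross the barrier sooner. Plates are filmed at 3 frames/s
over a ~47 mm field of view and tracking software exports per-frame animal
midpoints. Three practical constraints shape every downstream statistic:

1. the field of view does not cover the whole plate, so tracks appear and
   disappear and the number of animals must be *estimated*;
2. the ink marker that demarcates the copper stripe defeats the tracker,
   so an animal that crosses is lost — a crossing is observed as a *track
   terminating at the barrier*, and animals cannot be re-identified
   afterwards (hence no per-animal crossing rate, only population counts);
3. the videos lack the resolution for path-length (body-bend) estimates,
   so velocity is defined as a Euclidean chord over a 2-s window.

`coppertracks` implements the resulting quantification pipeline —
exclusion filters, barrier-crossing scores, residence and velocity
profiles, and per-bin group statistics — together with a simulator that
generates track sets with exact ground truth so that every stage can be
validated.

## The pipeline and its parameters

**Units and axes.** Trackers export pixels; filtering happens in pixel
units (its thresholds are printed in pixels), then `calibrate()` converts
to mm with `pixel_scale` (default 47/1024 mm/px, user-settable because the
field of view is only approximately 47 mm). All spatial metrics work on the
*signed distance from the barrier* along the odor axis: negative on the
starting side, positive on the odor side. Arenas with the odor to the left
declare `odor_direction = "decreasing_x"` and are reflected internally, so
a single code path serves both orientations. Frame indices are
authoritative; time is derived as `frame / frame_rate` when absent.

**Exclusion filters** (`filter_tracks()`). A track is excluded if it (1)
overlaps a user-declared exclusion region (shadows and markings need scene
knowledge, so they are supplied as rectangles rather than detected), (2)
lasts less than 10 s by timestamps (not point counts, so dropped frames do
not shorten a track), (3) has bounding-box area under 30 px², or (4) spans
fewer than 10 px in both axis directions. The printed form of criterion 3
("30 pixels²") is ambiguous between an area and a mistyped path length;
the package defaults to the area reading — criterion 4 already handles
linear displacement — and offers `criterion3 = "path_length"` for the
other. Thresholds are strict `<`, the audit label is the first criterion
that fires, and filtering is idempotent.

**Barrier terminations** (`classify_terminations()`). A track terminates
at the barrier when its last point lies within `dead_zone_halfwidth +
termination_margin` of the barrier midline (defaults 1.5 mm + 1 mm; the
margin is a package choice — the tracker loses animals at an inked stripe
of only approximately known width). Tracks that both start and end in that
band are *reversals* and are discounted. Direction is decided by the side
of the barrier where the track ends (`direction = "side"`): a track ending
on the origin side was entering the marker zone toward the odor (forward),
one ending on the odor side was heading back (reverse). An alternative
rule (`direction = "trailing"`) uses the sign of the net odor-axis
displacement over the trailing 2-s window, with ties labelled reversal;
the side rule is the default because it is parameter-free, matches how
forward and reverse tracks are described for this assay, and agrees
exactly with simulator ground truth, whereas a displacement sign can be
flipped by step noise on rare approaches. A recording-end subtlety the
assay description leaves open: a track whose animal happens to sit near
the barrier when the video ends also "terminates" there. `censor_at`
(optional) labels tracks that end with the recording as `none`; the
default leaves censoring off.

**Crossing score** (`cumulative_crossings()`). At each checkpoint (15, 30,
45 min), score = (forward − reverse terminations so far) / estimated
animal count, the count being the maximum number of simultaneous tracks in
one frame. The chemotactic index for endpoint assays is
`chemotactic_index(n_odor, n_origin)`.

**Residence probability** (`residence_probability()`). Every midpoint of
every kept track at every frame contributes once; per-bin probability is
midpoints-in-bin over total midpoints, normalized *per plate* (the
replicate unit for statistics is the plate, matching how the profiles are
averaged with SEM across plates). Bins are half-open `[left, right)` on
integer-mm edges — edge ownership is a package convention, stated because
no standard exists for it. The default grid spans the field of view on
both sides of the barrier; with a 47-mm field this yields ~45–47 bins
depending on where the barrier sits.

**Velocity** (`instantaneous_velocity()`, `velocity_profile()`).
v(t) = ‖x(t+1 s) − x(t−1 s)‖ / 2 s in μm/s, undefined within 1 s of track
ends. If the exact frames at ±1 s are missing (tracker dropouts), the
sample is undefined rather than computed over a silently shrunken window.
Each defined sample is binned by its central point's signed distance;
per-bin mean and SEM are over samples. Because the chord can only
undershoot the path, the estimator has a small negative bias that grows
with turning: negligible for persistent crawling, but systematic within
one window of a turning point (a wall, or the dead-zone edge where
refused animals turn around). Near-barrier samples are included by
default; `exclude_dead_zone = TRUE` drops them.

**Group comparison** (`compare_profiles()`). One Welch unequal-variance
t-test per bin on per-plate profile values, with Welch–Satterthwaite
degrees of freedom, then Holm–Šídák step-down correction
(adjusted p = 1 − (1 − p)^(m−i+1), running-maximum monotone, capped at 1)
across all tested bins; one profile comparison is treated as one
correction family. Bins with fewer than two finite replicate values on
either side are flagged untested and excluded from the family size m.
Identical constant samples (zero pooled variance) return t = 0, p = 1 —
no evidence of a difference. Significance defaults to adjusted p < 0.05.

## What the simulator emulates — and what it does not

`simulate_experiment()` is not a biophysical worm model; it is the minimal
generative process that gives the pipeline exact ground truth with the
statistical structure the analysis assumes:

- **Movement**: a persistent random walk. Heading carries over with
  wrapped-normal angular noise of SD `(1 − heading_persistence)·π` rad per
  step plus a weak deterministic pull toward the odor (`odor_drift`,
  implemented as a −drift·sin(θ) restoring term, a crude stand-in for
  chemotaxis without odor-gradient physics). Step length is the local mean
  speed — a piecewise-linear function of signed distance from the barrier —
  divided by the frame rate, with multiplicative lognormal noise
  (σ = 0.15, mean-one).
- **Geometry**: billiard reflection at the field-of-view walls (position
  and heading), so no emitted point leaves the field and animals do not
  "hug" walls; no emitted point lies inside the dead zone.
- **Barrier**: on touching the dead-zone boundary an animal crosses with
  probability `crossing_propensity`, decided once per encounter (a new
  decision arms only after retreating 1 mm); refusals reflect off the
  boundary. A crossing truncates the track — exactly the observability the
  real tracker has.
- **Re-emergence**: with probability `reversal_propensity` a crossed
  animal re-appears on the far side after a 5–15 s dwell, at a random
  distance that may fall inside or outside the termination band, and may
  cross back. Ground truth records a truncation as a *crossing* iff the
  track's first point lies outside the termination band, else as a
  *reversal* — the same start-in-band rule the classifier applies, so
  ground-truth equivalence is exact while remaining a separate code path.
- **Degenerate tracks**: `inject_noise_tracks()` plants tracks violating
  exactly one exclusion criterion each, for filter-audit recovery tests.

Defaults state the assay world: 30 tracked animals (the observed average
is ~27), 45-min recordings at 3 frames/s, ~200 μm/s crawling, a start
zone ~2 cm on the origin side. `make_wf_fd_pair()` encodes the
well-fed/food-deprived contrast: per-encounter crossing propensities of
0.015 (WF) versus 0.035 (FD) with odor drift 0.02 versus 0.06 — chosen
once so that, compounded over the many encounters of a 45-min recording,
plate-level 45-min net crossing fractions land at roughly 0.3–0.4 (WF)
and 0.7–0.9 (FD), the ranges real plates occupy — and an FD speed law
depressed to 60% of the well-fed speed far (>10 mm) from the barrier.

A green simulation test therefore establishes that the pipeline measures
what it claims on data with known structure. It does *not* establish
anything about real worm behavior: the simulator has no pirouettes or
weathervaning, no odor gradient, no body posture, and its parameters are
not fitted to recordings.

## Numerical choices and degenerate inputs

- Residence probabilities are exact rational counts; the sum-to-one
  invariant is checked to 1e−9 only to tolerate float division.
- Velocity windows require `window/2` to be a whole number of frames.
- Zero-variance Welch inputs give t = 0, p = 1; Holm–Šídák rejects
  p-values outside (0, 1].
- Empty track sets: animal count 0; filtering returns an empty report;
  residence on zero midpoints is an error (an empty distribution is not a
  distribution); velocity on tracks shorter than the window is all-NA,
  not an error.
- An animal count of 0 makes the crossing fraction undefined — error, not
  NaN.
- Determinism: simulations are reproducible per (config, seed) and the
  RNG state of the caller is restored; CSV writers format with 10
  significant digits so repeated writes are byte-identical.

## Test-suite scaling

Monte-Carlo suites run at reduced scale to keep the default test run
fast: the type-I-error check uses 20 null comparisons of 4 plates per
condition at 300 s / 12 animals (band: per-bin raw rejection fraction
within ±0.05 of α, set a priori from the binomial spread with
within-run correlation; family-wise hits ≤ 4 of 20 runs); the
crossing-propensity monotonicity check uses 600-s recordings over 8
seeds; the well-fed/food-deprived ordering runs the full 45-min pipeline
over 20 seeds per condition. The speed-law recovery test checks bins in
flat stretches of the law, clear of turning boundaries, against 3 SEM
plus a 3% allowance for the chord-vs-arc deficit described above.

## Known limitations

- Forward/reverse classification near the recording end is ambiguous
  without `censor_at`; real analyses should pass the recording length.
- The chemotactic index cannot be computed from tracks alone (crossed
  animals are untrackable), so it takes manual plate counts.
- The chord velocity underestimates speed near turning points by
  construction; profiles within ~0.5 mm of the dead-zone edge inherit
  this.
- The wide-format reader is best-effort for one common per-animal-column
  export layout; the tidy long CSV is the canonical interchange format.
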