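---
title: "Assessing fine motor skills from a sensor-augmented cube: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing fine motor skills from a sensor-augmented cube: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorcube)
```

## The assessment problem

Standardised fine-motor assessments for 6–9-year-olds (the fine subscale of
the Movement Assessment Battery for Children, 2nd edition — "fine MABC-2")
are reliable but slow and need a trained supervisor. A sensor-augmented toy
cube offers a playful alternative: the child plays short games on the cube's
54-LED surface while a tri-axial accelerometer and gyroscope stream at
110 Hz, and the game itself logs events. The question the pipeline answers
is whether features of that stream and of the game state predict the binary
fine-MABC-2 outcome — percentile ≤ 16 flags likely fine-motor development
problems (label 1), percentile ≥ 17 does not (label 0).

Two games probe different demands:

* **Roadrunner (speed).** A dot walks the cube surface at a fixed pace (one
  cell per *d* seconds, *d* ∈ {0.8, 0.6, 0.4} for difficulty levels 0/1/2;
  six 30 s segments, every level twice, starting at level 0, no immediate
  repeats — exactly 10 admissible orderings). The child must keep rotating
  the cube so that the dot stays on top.
* **Maze (precision).** The child steers a dot along a lit track at their
  own pace (levels 0/1 alternate in four 60 s segments); leaving the track
  turns the dot red until it returns. Level 0 turns corners only at side
  middles, level 1 also at edge cells.

Both games open with a 60 s warm-up that is excluded from every feature.

## Cube geometry

Cells are indexed 0–53, face-major (face *f* owns cells 9*f*…9*f*+8,
row-major within the face seen from outside, face order +z, +x, −z, −x,
+y, −y). The commercial toy's true index-to-cell assignment is not public;
any consistent layout gives identical statistics, so the package fixes this
one and documents it. Cell directions are the normalised 3×3 grid-centre
positions on a unit cube; a heading is one of the four in-face directions,
and walking off an edge re-expresses the heading on the neighbouring face.
This makes the forward map a bijection on the 216 (cell, heading) states
whose straight orbits close after 12 steps (4 faces × 3 cells) — an
exhaustive test asserts both. At exact orientation ties (a 45° pose) the
"up face" resolves to the lowest face id so behaviour is deterministic.

## The synthetic child

No public recording of the original cohort exists, so the package ships a
generator whose output has the same shape and label-bearing structure as
the study data: a manifest (id, age 6.5–9, gender, percentile, label), one
110 Hz sensor stream and one event log per child and game.

A latent skill *s* ∈ [0, 1] maps to the test percentile as
round(100·*s*^1.5); only the ≤ 16 threshold matters downstream (the MABC-2
norm tables are not public, so the map is a modelling convenience chosen
once). Cohorts draw the label first (probability = prevalence, default
49/95 as in a screening-enriched sample) and then the skill from a
two-component truncated normal mixture (low: mean 0.18, SD 0.10; typical:
mean 0.62, SD 0.15), so label prevalence is exact in expectation and
percentile is monotone in skill.

The child's hands are a delayed proportional orientation controller run at
the sensor rate: commanded angular velocity = gain × (current direction ×
target direction), the target lagged by a reaction latency and smoothed at
a 1.5 Hz motor bandwidth (hands do not produce step commands when the dot
jumps). Skill moves every parameter monotonically: gain 2→8 s⁻¹, latency
0.35→0.10 s, wobble (2 Hz band-limited angular noise) 0.9→0 rad/s, jitter
1.5→0 m/s². The accelerometer reports gravity in the body frame plus
jitter (so a static cube reads 9.81 m/s²); the gyroscope reports the true
angular velocity plus 0.02 rad/s measurement noise; both clip at the
hardware ranges (±8 G, ±2000 dps).

Two deliberate realism choices bound what the classifiers can achieve:

1. **The games measure a correlated, not identical, ability.** Each child
   gets a `game_skill` = skill + N(0, 0.15). Without it, four minutes of
   110 Hz averaging estimates the control parameters nearly noiselessly
   and every classifier is perfect — unlike any real cohort.
2. **The self-paced maze is a weak skill readout.** In the precision game
   children compensate by slowing down, so the maze control model is
   floor-dominated (wobble 0.25 + 0.20·(1−s) rad/s, slips 0.05 +
   0.08·(1−s) per step) with larger session-to-session multipliers
   (log-SD 0.5–0.6 vs 0.25–0.4 for roadrunner). This reproduces the
   study-level contrast the pipeline is meant to expose: the paced speed
   game discriminates well, the precision game sits near chance.

What the generator does **not** model: real hand anatomy and tremor
spectra, fatigue and learning within a session, age effects on skill, and
any genuine relation of age/gender to the label (both are pure noise
features here). Passing tests therefore show that the pipeline recovers
structure that is present, not that the real effect sizes equal these.

## Feature extraction

Both sensor streams are low-pass filtered per axis — 4th-order Butterworth
at 4 Hz, applied forward–backward for zero phase, with ~1 s odd-reflection
padding so the filter transient does not leak into the session (the plain
two-pass would corrupt the edges). Filtering precedes magnitudes, and
magnitudes precede differentiation: *a* = |accel|, *ω* = |gyro|, jerk =
d*a*/dt, angular jerk α = d*ω*/dt (central differences, one-sided at the
ends). Gravity is deliberately left in *a*: orientation changes then show
up in the accelerometer channel, and the games are entirely about
orientation.

The game channel is the cosine alignment for roadrunner — the cosine
between the current dot cell's direction and "up" estimated as the
negated, normalised filtered acceleration (drift-free, unlike integrating
the gyroscope) — and the on-path indicator for the maze, reconstructed
from the alternating enter/exit events. Warm-up samples are dropped; the
samples of every selected difficulty level (both occurrences pooled, not
mean-of-means) reduce to the mean and SD of each signal: 8 sensor + 2 game
features, plus age and gender (girl = 0, boy = 1) which are always
included. A noise-free simulated session is used as an oracle: alignment
recomputed from the stream must match the simulator's internal truth
within 0.01 everywhere.

## Cross-validation and classifiers

The study design ties the fold count to the class sizes: with 49 label-1
and 46 label-0 children, 49 folds, each test fold one child of either
label, and the first 3 label-0 children (in seed-permuted order) reused in
a second fold. The package generalises this minority-reuse rule to any
split (fold count = larger class) because simulated cohorts draw their
label counts binomially. Standardisation uses training-fold statistics
only; the decision tree skips it (scale-invariant). Hyperparameters are
deliberately conventional and exposed: KNN k = 5, ridge logistic
regression with penalty 1/n, Gini decision tree with unlimited depth,
radial SVM with unit cost. With two-sample test folds, per-fold accuracy
is confined to {0, ½, 1} and F1 is defined as 0 when precision and recall
both vanish.

Both analysis grids share one fold plan so that fold-wise scores are
paired: grid one is 4 classifiers × 2 games on all features; grid two
fixes the best classifier and crosses the 7 level subsets of the speed
game with the 3 feature families (sensor / game / both), general features
always included.

## Paired comparisons

Fold-wise scores are compared with two-sided Wilcoxon signed-rank tests at
α = .05 per test (no multiplicity correction — one comparison grid, read
descriptively). Fold scores are heavily tied and zero-laden, so the
implementation keeps both policies explicit: zero differences are
discarded before ranking (the Pratt variant is selectable), and the null
is evaluated **exactly** — a convolution over sign assignments on doubled
average ranks, which handles ties without approximation — whenever at
most 25 nonzero differences remain, otherwise by normal approximation
with tie-corrected variance (Var W = Σr²/4) and continuity correction.
All-zero differences give p = 1 by definition. The two computations agree
within 0.02 at the reference fold count (49), and the exact route reproduces
`wilcox.test` on tie-free data.

## Numerical and design notes

* Dot moves fall at t = k·delay inside a segment with the boundary move
  belonging to the next segment, fixing the event count (37 moves in a
  30 s level-0 segment). Turn choice at a face middle is uniform over
  left/right/straight — the maximum-entropy reading of an unspecified
  "random" turn.
* The maze engine is driven through an intent-controller interface at the
  0.3 s control cadence (a tilt-threshold law's rate limit); the engine
  validates adjacency, logs enter/exit alternation exactly, and closes an
  open excursion at level resets so the on-path state is always
  reconstructible.
* Maze tracks are frozen instruction walks on the topology: level 0 the
  12-cell equatorial band (crossings at side middles), level 1 a 24-cell
  staircase meander (crossings at edge cells), both verified closed simple
  loops.
* All randomness flows from integer seeds through derived sub-streams
  (cohort, engine, noise, folds), so every artefact is reproducible from
  its seed; rejection sampling inside the truncated mixture preserves
  determinism.
* Problem sizes in the shipped tests: cohorts of 95 children (the study
  size) for the learnability and null-calibration checks, 5 cohort seeds,
  20 label shuffles, 500 Wilcoxon null replicates, 200 children for the
  separation rank test. These sizes make the Monte-Carlo bands in the
  tests comfortably stable.

## Limitations

The acceptance-level performance numbers describe the synthetic cohort,
not children: the generator's effect sizes are configuration, not
measurement — there is no public per-feature reference to fit them to. Conclusions that survive this stand-in are structural — the
protocol constants, the fold-plan combinatorics, the filter and test
oracles, and the relative ordering built into the generator's design
(speed game informative, precision game weak). Real-data accuracies can only be
reproduced with recordings of a physical cohort, which this package cannot
ship.
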