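---
title: "Methods: SEP digital biomarkers, synthetic cohorts and the screening pipeline"
author: "sepalert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEP digital biomarkers, synthetic cohorts and the screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepalert)
```

## The paradigm and its data model

The task is a two-minute human–computer interaction: an inert sphere,
steered by finger on a 2560 × 1600 px tablet, must touch four target cubes
placed left, right, below and above its start position; the top cube lies
behind a transverse (horizontal) obstacle. Two acquisition constants drive
everything: the evaluation cap `T_max_s = 120` s and the sampling rate
`sample_rate_hz = 60`, giving at most `count_max = 7200` position samples
per trial. Only the screen size, the cap and the rate are fixed by the
paradigm; the cube/obstacle coordinates are configurable defaults of this
package (`default_scene()`), because absolute geometry is not part of the
published record. A direct consequence, worth stating plainly: absolute
distance-biomarker magnitudes produced by the *trial simulator* depend on
that chosen geometry and are not comparable with published cohort
magnitudes — which is why cohort-level statistics are driven by the
quartile-calibrated generator instead (below).

Coordinates use a bottom-left origin, y upward; "above the obstacle"
always means the sphere-centre y exceeds `obstacle_y_px`. The per-trial
record (`trajectory_log`) holds the contiguous 60 Hz samples and the 0–4
cube-elimination events; its JSONL serialisation writes coordinates with
round-trip-exact decimal text, so logs can be diffed, schema-checked and
re-read bit-identically.

## The eight biomarkers and their conventions

With `Te` the time of the fourth elimination (or 120 s for an incomplete
trial) and `d_i` the Euclidean distance between consecutive samples:

* `METRtotal = Te / T_max` ∈ (0, 1]; an incomplete trial scores exactly 1.
* `MEDtotal` sums `d_i` up to the Te sample; any drift logged after
  completion is excluded.
* `METfirst` is the first elimination time; `MEEfirst` divides the
  distance travelled before that event by the *contact-adjusted* shortest
  distance ‖cube − start‖ − (r_sphere + half_cube), so an ideal straight
  approach scores exactly 1. Both are missing (never zero) when no cube
  was eliminated.
* The crossing is the first step (i, i+1) with `y_i ≤ obstacle_y <
  y_{i+1}`; `Tcrossing` is the time of sample i+1. Later dips below the
  midline do not reset it, and only the y-coordinate is tested — the
  discriminant is one-dimensional. `ETcrossing = Te − Tcrossing` and
  `EDcrossing` sums the steps from the first above-midline sample to the
  Te sample; both are missing if the sphere never crossed.
* `ETabove`/`EDabove` count whole steps whose **two endpoints** are both
  strictly above the midline: time as steps/60 Hz, distance as the summed
  step lengths.

The both-endpoints step convention is a deliberate package choice. It
makes time and distance share one discretisation rule, avoids sub-sample
boundary interpolation, and — unlike counting above-midline *samples* —
makes the ordering invariants exact identities on every trial:
`ETabove ≤ ETcrossing ≤ Te` and `EDabove ≤ EDcrossing ≤ MEDtotal`.
(Sample counting overshoots `ETcrossing` by one tick whenever every
post-crossing sample is above.) At 60 Hz the two conventions differ by at
most 1/60 s per boundary touch. The test suite enforces the invariants,
and equality with an independently coded brute-force extractor to 1e−9
relative error, on 1,000 randomized simulated trials.

## The trial simulator

`simulate_trial()` emulates the interaction, not the participant: the
sphere is a damped point mass (`v ← (1 − damping·Δt)·v + a·Δt`, ‖a‖ ≤
`max_accel`) accelerated toward the current waypoint with angular noise
per tick, so motion must be anticipated as with the real steering wheel.
The controller routes around the nearer obstacle end when the straight
segment would pierce it, and the obstacle band (inflated by the sphere
radius) blocks vertical passage. Impairment-style knobs — steering noise,
spurious-detour probability, above-obstacle dwell — move the extracted
biomarker medians monotonically (tested over batches), which is what makes
the simulator useful for exercising extraction; it does not model touch
biomechanics, learning, or any fitted patient population. Default
dynamics (`agent_profile()`: accel 550 px/s², damping 1.8 /s, noise 0.6
rad, detour 5%) were chosen once to land trials at realistic magnitudes —
median Te ≈ 33 s and path length ≈ 7,000 px, matching the scale of
reported normal-cognition trials (median Te ≈ 31 s, MEDtotal ≈ 8,700 px)
— and are not tuned to reproduce any specific published value. Each trial
is seeded; identical seeds give bit-identical logs, and batch runs derive
per-trial sub-seeds as `seed + i − 1`.

## Quartile-calibrated synthetic cohorts

Published cohort tables report each variable as `median [P25, P75]` per
group. `calibrate_lognormal()` implements the closed-form symmetric fit
(`mu = ln median`, `sigma = (ln P75 − ln P25)/(2·0.67449)`), which is
exact when the printed quartiles are log-symmetric about the median. Many
printed rows are *not* symmetric (the starkest: an execution-time-rate
row at 0.31 [0.25, 0.50], where the symmetric fit would misplace P25 by
12%). Since the generator's defining requirement is to reproduce the
printed distributions, `sample_cohort()` therefore uses a **two-piece
(split) quantile fit**: separate lower/upper scale parameters
`s_lo = (ln med − ln P25)/z₀.₇₅`, `s_hi = (ln P75 − ln med)/z₀.₇₅`
applied to the negative/positive half of a standard-normal latent. All
three printed quantiles are then matched exactly, and the construction
reduces to the symmetric fit whenever the quartiles are symmetric. The
round-trip (empirical median and both quartiles within 2% of the printed
inputs at n = 10⁴ per group, every variable, both presets) is enforced in
the test suite.

Families: continuous positive markers use the split fit in log space; age
and years of education are additionally rounded to integers; MMSE uses a
split fit on the natural scale, rounded, and **censored** (clamped) to
[0, 30]. Clamping rather than renormalising truncation is deliberate:
censoring leaves the calibrated quartiles untouched (the clamp only
relocates tail mass to the bounds), whereas renormalisation shifts the
median of a wide-tailed group by several percent. The cost is a ceiling
atom: with the published MCI MMSE spread (26 [24, 29]) about a fifth of
simulated MCI scores land exactly at 30. That matters for one empirical
result below.

Dependence is a Gaussian copula over the latent normals. No between-marker
correlations are published, so the presets default to independence; any
nonzero matrix supplied via `cohort_spec()` is an explicit modelling
assumption carried in the spec object. Demographics include per-group
Bernoulli sex draws at the printed female proportions. Everything is
seed-deterministic.

## The screening pipeline

* **Group comparison** uses the two-group Kruskal–Wallis H (tie-corrected,
  chi-square(1) reference; `stats::kruskal.test` underneath), which on two
  groups is the rank-sum comparison the cohort tables quote; sex uses
  Pearson chi-square without continuity correction (switchable). No
  multiple-testing correction is applied — matching the p < 0.05
  convention of the original analysis — and the report records the number
  of tests so readers can discount accordingly.
* **Step-up selection** is forward-only logistic regression: at each step
  the candidate with the smallest likelihood-ratio entry p-value joins if
  p < 0.05; no removal step. The entry-only variant and the 0.05 threshold
  are package conventions (the published description names only "stepwise"
  / "step-up"). Under (quasi-)separation the final coefficients are
  re-estimated by a small-ridge IRLS on standardised predictors (λ = 0.01)
  and the result is flagged; p-values themselves are always plain LRT.
  A property worth knowing: with seven null candidates and entry α = 0.05,
  pure step-up admits *some* spurious marker in ≈ 30% of cohorts (1 −
  0.95⁷, plus a cascade once one enters), i.e. ≈ 5–6% per null marker.
  That is the procedure's intrinsic type-I behaviour, not an
  implementation artefact; the suite measures it at 5.1–5.3%.
* **ROC/AUC** is the empirical curve with ties collapsed; the trapezoidal
  area equals the midrank Mann–Whitney estimator (asserted against
  exhaustive pair counting and against pROC). Orientation: markers whose
  MCI median exceeds the NC median are scored as-is, others negated; MMSE
  is always negated. The combination score is the fitted logistic linear
  predictor of the selected markers.
* The **basic-education subgroup** keeps rows with strictly more than 9
  years of education. (The published subgroup table itself prints an MCI
  education P25 of 6 years despite the >9 definition; the package
  implements the stated rule and reproduces the printed marginals as
  printed — the tension is in the source tables, not resolvable here.)

## What the validation does and does not show

The acceptance-style checks recompute three headline quantities from
scratch on calibrated cohorts: the overall MMSE AUC (500/group, 20
seeds), the basic-education MEDtotal AUC (likewise), and the share of a
46 + 46 cohort finishing within 60 s (50 seeds). The completion share and
the MEDtotal AUC land close to the published 82.6% and 0.79 (the
recomputed MEDtotal AUC runs ≈ 0.83, consistent with the published
*combination* AUC in that subgroup). The recomputed MMSE AUC is ≈ 0.715
against a published 0.77 — a persistent, explainable shortfall: three
quantiles underdetermine a distribution, and the censored ceiling places
a large MCI atom at 30 that erodes exactly the tail separation MMSE
relies on. We report the number honestly rather than re-tuning the
generator, because every calibration choice above was fixed before the
comparison and each alternative (symmetric fit, renormalising truncation)
breaks the quantile round-trip that is the generator's actual contract.

More generally: passing these checks shows the *machinery* is correct and
the generator matches the published summaries; it does not show that
synthetic cohorts capture unpublished features of the real data
(tail shapes, marker correlations, education–marker interactions), and no
claim of clinical validity is implied.

## Numerical and degenerate-input conventions

Times are always derived from sample indices (never stored), so
serialisation cannot drift. Incomplete trials take Te = 120 s; biomarkers
whose defining event is absent are `NA`, and batch extraction never aborts
on a bad log. Ties in ROC scores use midranks; identical pooled samples
give H = 0, p = 1; a zero chi-square marginal reports `NA` rather than a
value. All simulation problem sizes in the suite (1,000 oracle trials,
10⁴-per-group calibration checks, 100-seed selection study) were chosen as
the smallest sizes at which the corresponding Monte-Carlo error is
comfortably below the asserted tolerances.
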