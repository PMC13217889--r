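---
title: "Analyzing two-dimensional tactile localization maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing two-dimensional tactile localization maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

In board-localization experiments, a participant holds a flat square board
(here 23 cm x 23 cm) while taps are delivered to locations on a regular
6 x 6 grid. After each tap, the participant clicks the perceived location on
an on-screen image of the board. Two questions drive the analysis:

1. **Does the layout survive?** Is the configuration of mean judged
   locations — the *perceptual map* — more similar to the actual grid than
   chance clicking would produce?
2. **How is it distorted?** Per-axis regression slopes of judged on actual
   location measure how much of the spatial range is preserved
   (1 = veridical, 0 = no positional information), and per-location
   *variable error* (trial-to-trial SD of judgments) measures precision.
   Differences between the medio-lateral and proximodistal axes of the hand
   quantify anisotropy.

`tactmap` implements this pipeline end to end, together with a generative
model of synthetic participants so that every stage can be validated by
simulation and parameter recovery.

## Coordinates: Bookstein two-point registration

All computation happens in *Bookstein shape coordinates*: the similarity
transform that maps the board's bottom-left corner to (0,0) and bottom-right
corner to (1,0). This removes position, orientation and size, and fixes the
interpretation of the axes: x is medio-lateral, y proximodistal. The board
interior is the unit square; the 36 grid marks sit at spacings of
3.3/23 ≈ 0.143 units.

```{r}
library(tactmap)
grid <- build_grid()
grid
head(grid$points, 3)
```

A note on the grid geometry: the nominal layout (3.3 cm between marks *and*
between the outer marks and the board edge) adds up to 23.1 cm on a 23 cm
board. `build_grid()` centres the grid and absorbs the 1 mm discrepancy into
the outer margins, rejecting only geometries that overfill the board by more
than 2%.

## Map similarity: Procrustes distance

`procrustes_align()` finds the translation, rotation, uniform scaling (and,
optionally, reflection) of one configuration that minimizes the sum of
squared distances to the homologous points of the other — the closed-form
orthogonal-Procrustes solution via the SVD of the 2 x 2 cross-covariance.
The residual is summarized as the **Procrustes distance**: the root mean
square of the homologous point distances after alignment, in Bookstein
units. Note this is the plain RMS residual, *not* the sum-of-squares
dissimilarity statistic some libraries return; the RMS form is what the
per-participant and group distances below are expressed in.

Because the alignment removes uniform scale, a map that is uniformly shrunk
— as real perceptual maps are — scores 0: the distance is sensitive to
*shape* distortion (including axis-specific compression) and residual
scatter, not overall compression.

Whether a reflection should be allowed is genuinely ambiguous in this kind
of analysis; the full-similarity solution (reflection allowed) is the common
default of general-purpose Procrustes routines, so `allow_reflection = TRUE`
is the default here, with the rotation-only variant one flag away. For maps
even loosely resembling the grid the optimal transform is never a
reflection, so the choice matters only deep under the null.

## Chance levels: Monte-Carlo nulls

A participant with no localization ability still produces a map. The null
model draws every click independently and uniformly over the board square,
averages the same number of repetitions per location as the real design
(8 in the one-posture design, 4 per posture in the two-posture design), and
computes the distance of the resulting random map to the grid.
`simulate_null_single()` repeats this `n_sims` times; `empirical_p()`
returns the proportion of null distances *strictly smaller* than an observed
value (ties count as not smaller), so small p means better-than-chance
localization. The group-level null (`simulate_null_group()`) resamples
`group_size` single-participant values with replacement and records their
mean, giving the reference distribution for the grand-mean distance.

Two numerical choices matter here:

* The batch simulator evaluates the minimized residual in closed form —
  for a 2 x 2 cross-covariance the singular values are available as
  `s1 + s2 = sqrt(|M|_F^2 + 2|det M|)` and
  `s1 - s2 = sqrt(|M|_F^2 - 2|det M|)` — which makes 10^6-simulation nulls
  practical in pure R. A unit test pins the vectorized path to a
  per-simulation loop over `procrustes_align()`, which is itself pinned to a
  brute-force rotation-grid minimizer.
* Simulation is chunked with a fixed internal chunk size, so a null is a
  pure function of its seed and parameters; caches written by
  `write_null()` record `n_sims`, reps, seed and level in a plain-text
  header.

The reference analysis uses `n_sims = 10^6`. The package's own validation
suite uses 10^4, which bounds the Monte-Carlo error of a 1st-percentile
estimate well below the separation it needs to resolve (observed maps sit
several null SDs below the null's lower tail).

## Per-participant and group statistics

`analyze_participant()` chains the stages: exclusion of outside-board
clicks, map construction, Procrustes distance and empirical p, per-axis
slopes, and variable error. Decisions fixed here:

* **Exclusion**: a trial is removed only if the judged click is *strictly*
  outside the unit square; boundary clicks are kept. Exclusion is
  order-independent and idempotent, and happens in analysis, not at load
  time.
* **Slopes**: ordinary least squares of judged on actual coordinate over
  all of a participant's valid trials (trial-level). Because the design is
  balanced and the model linear, regressing on per-location means instead
  gives the same estimand; both granularities are exposed since either
  reading of "regressed on actual location" is defensible.
* **Variable error**: sample SD (n − 1 denominator) per location per axis,
  summarized as the unweighted mean over the 36 locations, requiring at
  least 2 valid trials everywhere.
* **Tests**: `one_sample_t()` (slopes vs 0, Cohen's d), `paired_t()`
  (between-axis anisotropy, dz), `pearson_r()` (between-axis correlation,
  df = n − 2); all two-tailed, no multiplicity correction.
  `one_sample_t_summary()` recomputes t and d from a printed (M, SD, n)
  triple, which is how published group statistics are checked without raw
  data.

`analyze_group()` aggregates a cohort and surfaces degenerate situations
(e.g. a correlation over identical participants) as labelled degenerate
records rather than errors.

```{r}
design <- experiment_design(grid, reps_per_location = 8)
null1 <- simulate_null_single(grid, reps_per_location = 8,
                              n_sims = 5000, seed = 11)
models <- sample_cohort_models(6, seed = 7)
trials <- generate_cohort(models, design, seed = 7)
stats <- lapply(split(trials, trials$participant), analyze_participant,
                grid = grid, null_single = null1)
analyze_group(stats, simulate_null_group(null1, 6, 5000, seed = 12))
```

## The synthetic-participant model

`participant_model()` realizes a linear-compression response process:

    judged = center + slope * (actual - center) + noise

with per-axis compression slopes, a convergence point (default the board
centre), and anisotropic Gaussian response noise. With probability
`lapse_rate` the trial is instead a stray click, uniform over a region
extending 0.1 units beyond the board on every side — so roughly 31% of
lapses land off-board (and are later excluded) while the rest contaminate
the data undetectably. The per-axis OLS regression recovers the generating
slopes as its estimand, which is what makes recovery studies
interpretable.

Defaults are anchored to the reported group parameters of a one-posture
session: slopes 0.840 (medio-lateral) and 0.428 (proximodistal) with
between-participant SDs 0.213 and 0.229, response noise SDs 0.121 and 0.137
Bookstein units. `sample_cohort_models()` draws slopes from (untruncated)
normals with those means and SDs; noise and lapse rate are held fixed
across participants because no between-participant spread is reported for
them.

**Bounded responses.** By default the non-lapse response is a
board-truncated Gaussian: noise draws are rejection-sampled until the click
lands on the board. This reflects how people click on an image of a board —
off-board clicks are a fraction of a percent of trials in real sessions —
whereas an unbounded Gaussian at these noise levels would put ~3.5% of
clicks off-board (and occasionally strip an edge location of nearly all its
trials, which the variable-error contract rightly rejects). With bounded
responses, off-board clicks come only from lapses; the default
`lapse_rate = 0.0056` is chosen so that the expected off-board click rate,
`0.0056 x 0.306 ≈ 0.17%`, matches the exclusion rate observed in real
one-posture sessions. The unbounded variant remains available as
`bounded = FALSE`.

**What the generator does not emulate.** Real response distributions need
not be Gaussian (truncated or otherwise); constant-error structure is
limited to linear compression toward a single point, with no local
warping; noise is homogeneous across locations except for the boundary
truncation; and condition order effects (the ABBA posture schedule) are not
modelled — postures are analyzed independently, as in the real pipeline.
Passing recovery tests therefore validates the pipeline's estimators under
a plausible response model, not the model's fidelity to any particular
dataset.

## Known limitations

* **Edge-truncation slope bias.** With a generating medio-lateral slope of
  0.84 and noise SD 0.121, the mean judged position at the outer grid
  columns lies ~1.6 noise SDs from the board edge. Any board-bounded
  response process — truncation in the generator, or outside-board
  exclusion applied to an unbounded one — therefore shifts edge-column
  means inward and compresses the fitted slope, by about 0.03–0.04 at
  these parameter values (about 0.01–0.02 on the proximodistal axis, whose
  compression keeps judgments far from the edges). This is a property of
  the estimand under bounded responses, not an estimator defect: the
  package's study-scale recovery runs measure exactly this gap, and
  inferential conclusions (slopes > 0, medio-lateral > proximodistal) are
  unaffected.
* **SD small-sample bias.** With 8 repetitions per location, the sample SD
  underestimates the generating noise SD by the factor c4(8) ≈ 0.965;
  recovery comparisons correct for it, but reported variable errors are raw
  sample SDs, as is conventional.
* **Monte-Carlo granularity.** Empirical p-values are multiples of
  1/`n_sims`; a reported p of 0 means "smaller than every simulated null
  value".

## Validation problem sizes

The test suite validates the geometry against a brute-force rotation-grid
minimizer on 50 random configurations; p-value calibration and the slope
test's type-I error on 2,000 uniform-responder replicates/cohorts against a
10^4-simulation null; and parameter recovery on 200 study-scale cohorts
(20 participants x 288 trials). The acceptance script
(`scripts/acceptance.R`) recomputes published group statistics from their
printed summaries and re-measures the synthetic recovery quantities on 50
fresh cohorts under a caller-supplied seed.
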