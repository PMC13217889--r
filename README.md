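# tactmap

Analysis of two-dimensional tactile localization experiments: participants
hold a flat board, receive taps on a 6 × 6 grid of locations, and report
each perceived location by clicking an on-screen image of the board. The
package quantifies how well the spatial layout of touch survives into
perception, and how it is distorted, for researchers in somatosensory
psychophysics and related fields.

## What it computes

Working in **Bookstein shape coordinates** (board corners mapped to (0,0)
and (1,0), so x is the medio-lateral and y the proximodistal axis):

* **Procrustes distance** between each participant's perceptual map (the
  per-location mean judged positions) and the actual grid: the
  least-squares similarity superimposition (translation, rotation, uniform
  scale, optional reflection) is found in closed form via the SVD of the
  2 × 2 cross-covariance, and the residual is summarized as
  `D = sqrt(mean_i ||x_i − y_i||²)` over the 36 homologous point pairs —
  0 for perfectly matching configurations.
* **Monte-Carlo nulls**: distances of maps built from uniformly random
  clicks (with the design's repetitions averaged per location), at single
  participant and group-mean level, with one-tailed empirical p-values
  (proportion of null values strictly smaller than the observed distance).
* **Per-axis localization slopes**: OLS of judged on actual coordinate,
  per participant and axis (`β = 1` veridical, `β = 0` uninformative), with
  one-sample t-tests and Cohen's d at the group level, paired t (dz) for
  medio-lateral vs proximodistal anisotropy, and the between-axis Pearson
  correlation.
* **Variable error**: per-location SD of judgments per axis (n − 1
  denominator), averaged over the 36 locations, with the paired anisotropy
  test.
* **Synthetic participants**: a seeded linear-compression generative model
  (`judged = center + β ∘ (actual − center) + noise`, plus lapse clicks)
  for calibration and parameter-recovery studies without raw data.

## Worked example

Simulate a 20-participant cohort at published parameter scales and run the
full analysis:

```r
library(tactmap)
grid   <- build_grid()                                  # 6 x 6, 3.3 cm on 23 cm
design <- experiment_design(grid, reps_per_location = 8)  # 288 trials each
null1  <- simulate_null_single(grid, reps_per_location = 8,
                               n_sims = 10000, seed = 11)
models <- sample_cohort_models(20, seed = 7)
trials <- generate_cohort(models, design, seed = 7)
stats  <- lapply(split(trials, trials$participant), analyze_participant,
                 grid = grid, null_single = null1)
analyze_group(stats, simulate_null_group(null1, 20, 10000, seed = 12))
```

```
Group report: 20 participants, 5760 trials (13 excluded, 0.23%)
medio-lateral slopes vs 0:   statistic = 18.547, df = 19, p = 1.249e-13, d = 4.147
proximodistal slopes vs 0:   statistic = 9.783, df = 19, p = 7.48e-09, d = 2.188
slope anisotropy (ML - PD):  statistic = 6.760, df = 19, p = 1.857e-06, dz = 1.512
between-axis slope corr:     statistic = 0.049, df = 18, p = 0.9614
variable error (ML - PD):    statistic = -6.928, df = 19, p = 1.324e-06, dz = -1.549
grand-mean Procrustes distance 0.1480 (empirical p = 0)
```

Reading the output: both axes' slopes are far above 0 (localization carries
real positional information on the board), medio-lateral slopes exceed
proximodistal ones (the paired anisotropy test), variable error is smaller
medio-laterally (negative dz for ML − PD), and the grand-mean Procrustes
distance of 0.148 is below every one of the 10,000 group-null simulations
(empirical p = 0, i.e. p < 1e-4). The exclusion line counts off-board
clicks removed before analysis.

`run_pipeline()` drives the same analysis from a YAML/list configuration
(real trial CSV or synthetic cohort) and writes a JSON report,
per-participant CSV and null caches; `inst/cli/tactmap.R` exposes
`simulate`, `null` and `analyze` verbs for shell use. Trial CSVs may carry
coordinates in Bookstein units, cm or pixels (the latter two with explicit
landmark positions, converted on load).

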