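Package: tactmap
Title: Two-Dimensional Tactile Localization Maps, Procrustes Statistics, and
    Monte-Carlo Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-dimensional tactile localization
    experiments in which participants judge the location of touches on a held
    board by clicking an on-screen image. Implements Bookstein two-point shape
    registration, least-squares (orthogonal) Procrustes superimposition and the
    root-mean-square Procrustes distance between perceptual maps and the actual
    stimulus layout, Monte-Carlo null distributions for single-participant and
    group-mean distances with empirical p-values, per-axis regression slopes of
    judged on actual location, per-location variable error and its anisotropy
    statistics, and a seeded generative model of synthetic participants for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
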