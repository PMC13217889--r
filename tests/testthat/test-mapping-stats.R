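grid6 <- build_grid()
design1 <- experiment_design(grid6, reps_per_location = 8)

perfect_trials <- function(participant = "P01") {
  m <- participant_model(slope_x = 1, slope_y = 1, noise_sd_x = 0,
                         noise_sd_y = 0, lapse_rate = 0, seed = 1)
  generate_trials(m, design1, participant = participant)
}

test_that("outside-board exclusion counts correctly and keeps the boundary", {
  tr <- perfect_trials()
  n <- nrow(tr)
  tr$judged_x[c(3, 10)] <- c(1.2, -0.01)  # two strictly-outside clicks
  tr$judged_x[5] <- 1.0                   # exactly on the edge: kept
  tr$judged_y[7] <- 0.0
  res <- exclude_outside(tr)
  expect_equal(res$n_excluded, 2L)
  expect_equal(res$exclusion_rate, 2 / n)
  expect_equal(nrow(res$trials), n - 2L)
  expect_true(1.0 %in% res$trials$judged_x)
  # idempotent and order-independent
  res2 <- exclude_outside(res$trials)
  expect_equal(res2$n_excluded, 0L)
  expect_equal(res2$exclusion_rate, 0)
  shuffled <- tr[withr::with_seed(2, sample.int(n)), ]
  res3 <- exclude_outside(shuffled)
  expect_equal(res3$n_excluded, 2L)
  expect_setequal(res3$trials$trial_index, res$trials$trial_index)
  # empty input
  res4 <- exclude_outside(tr[0, ])
  expect_equal(res4$exclusion_rate, 0)
})

test_that("perceptual map is the per-location mean and errors on empty cells", {
  tr <- perfect_trials()
  map <- build_map(tr, grid6)
  expect_equal(map$means, grid6$points, tolerance = 1e-12)
  expect_true(all(map$n_valid == 8L))
  # symmetric +/- delta pairs average back to the point
  tr2 <- tr
  # each location appears once per block: +/- delta in equal numbers
  tr2$judged_x <- tr2$judged_x + ifelse(tr2$block <= 4, 0.03, -0.03)
  map2 <- build_map(tr2, grid6)
  expect_equal(map2$means, grid6$points, tolerance = 1e-12)
  # a location with no trials is an error
  tr3 <- tr[!(tr$loc_row == 1 & tr$loc_col == 1), ]
  expect_error(build_map(tr3, grid6), "r1c1")
})

test_that("per-location means concentrate as sigma/sqrt(reps)", {
  # CLT check on the map means across replicate simulations
  sds <- withr::with_seed(31, {
    replicate(60, {
      m <- participant_model(slope_x = 1, slope_y = 1, noise_sd_x = 0.1,
                             noise_sd_y = 0.1, lapse_rate = 0)
      tr <- generate_trials(m, design1)
      build_map(tr, grid6)$means[1, 1]
    })
  })
  expect_equal(sd(sds), 0.1 / sqrt(8), tolerance = 0.25)
})

test_that("axis slopes recover exact and degenerate response patterns", {
  tr <- perfect_trials()
  sl <- axis_slopes(tr)
  expect_equal(sl$x$slope, 1, tolerance = 1e-12)
  expect_equal(sl$y$slope, 1, tolerance = 1e-12)
  expect_equal(sl$x$intercept, 0, tolerance = 1e-12)
  expect_equal(sl$x$axis, "mediolateral")
  expect_equal(sl$y$axis, "proximodistal")
  tr2 <- tr; tr2$judged_x <- 0.37; tr2$judged_y <- 0.81
  sl2 <- axis_slopes(tr2)
  expect_equal(sl2$x$slope, 0, tolerance = 1e-12)
  expect_equal(sl2$x$intercept, 0.37, tolerance = 1e-12)
  expect_equal(sl2$y$intercept, 0.81, tolerance = 1e-12)
  # zero variance in the actual coordinate is an error
  tr3 <- tr[tr$loc_col == 3, ]
  expect_error(axis_slopes(tr3), "zero variance")
})

test_that("trial-level slope estimates recover a generating slope of 0.84", {
  # direct linear response, no edge handling: OLS is unbiased for the slope
  base <- perfect_trials()
  est <- withr::with_seed(32, {
    replicate(40, {
      tr <- base
      tr$judged_x <- 0.5 + 0.84 * (tr$actual_x - 0.5) + rnorm(288, 0, 0.12)
      tr$judged_y <- 0.5 + 0.84 * (tr$actual_y - 0.5) + rnorm(288, 0, 0.12)
      axis_slopes(tr)$x$slope
    })
  })
  # 288 trials: se of one estimate ~ 0.12 / (sd(actual) * sqrt(288)) ~ 0.029
  expect_lt(abs(mean(est) - 0.84), 3 * sd(est) / sqrt(length(est)) + 0.005)
})

test_that("location-level regression agrees with trial-level for balanced noiseless data", {
  tr <- perfect_trials()
  sl_loc <- axis_slopes(tr, granularity = "location", grid = grid6)
  expect_equal(sl_loc$x$slope, 1, tolerance = 1e-12)
  expect_equal(sl_loc$x$n, 36L)
})

test_that("variable error is the per-location sample SD with n-1 denominator", {
  tr <- perfect_trials()
  ve0 <- variable_error(tr, grid6)
  expect_true(all(ve0$x$per_location_sd == 0))
  expect_equal(ve0$y$mean_sd, 0)
  # two trials per location at p +/- d have SD d * sqrt(2)
  tr2 <- tr[tr$block <= 2, ]
  d <- 0.05
  tr2$judged_x <- tr2$actual_x + ifelse(tr2$block == 1, d, -d)
  ve2 <- variable_error(tr2, grid6)
  expect_equal(unname(ve2$x$per_location_sd),
               rep(d * sqrt(2), 36), tolerance = 1e-12)
  # doubling deviations about the location means doubles the mean SD
  tr3 <- tr2
  tr3$judged_x <- tr2$actual_x + 2 * (tr2$judged_x - tr2$actual_x)
  expect_equal(variable_error(tr3, grid6)$x$mean_sd, 2 * ve2$x$mean_sd,
               tolerance = 1e-12)
  # mean_sd is the unweighted mean over locations
  expect_equal(ve2$x$mean_sd, mean(ve2$x$per_location_sd))
  # < 2 trials anywhere is an error
  expect_error(variable_error(tr[tr$block == 1, ], grid6), "fewer than 2")
})

test_that("one-sample t matches a long-hand textbook computation", {
  x <- c(4.1, 5.6, 3.8, 6.2, 5.3)
  got <- one_sample_t(x, mu0 = 4)
  m <- mean(x); s <- sqrt(sum((x - m)^2) / 4)
  t_hand <- (m - 4) / (s / sqrt(5))
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(got$effect, (m - 4) / s, tolerance = 1e-12)
  # mean equal to mu0 gives t = 0
  z <- c(-1, 0, 1)
  expect_equal(one_sample_t(z, 0)$statistic, 0)
  expect_equal(one_sample_t(z, 0)$effect, 0)
  expect_error(one_sample_t(c(2, 2, 2)), "degenerate")
  # summary-statistic form agrees with the vector form
  gs <- one_sample_t_summary(m, s, 5, mu0 = 4)
  expect_equal(gs$statistic, got$statistic, tolerance = 1e-12)
  expect_equal(gs$p, got$p, tolerance = 1e-12)
  expect_equal(gs$effect, got$effect, tolerance = 1e-12)
})

test_that("paired t is antisymmetric, reports dz, and rejects constant differences", {
  set.seed(33)
  b <- rnorm(20)
  a <- b + rnorm(20, 0.3, 0.1)
  ab <- paired_t(a, b); ba <- paired_t(b, a)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_equal(ab$effect, mean(a - b) / sd(a - b), tolerance = 1e-12)
  expect_equal(ab$effect_type, "dz")
  expect_equal(ab$df, 19)
  # dz near 3 for mu 0.3, sigma 0.1 differences
  dzs <- replicate(40, {
    bb <- rnorm(20); aa <- bb + rnorm(20, 0.3, 0.1)
    paired_t(aa, bb)$effect
  })
  expect_lt(abs(mean(dzs) - 3), 4 * sd(dzs) / sqrt(40) + 0.25)
  expect_error(paired_t(a, a), "degenerate")
})

test_that("pearson_r handles exact, reversed and sampled correlations", {
  a <- c(0.1, 0.4, 0.5, 0.9, 1.3)
  r1 <- pearson_r(a, 2 * a + 1)
  expect_equal(r1$estimate, 1, tolerance = 1e-10)
  r2 <- pearson_r(a, -a)
  expect_equal(r2$estimate, -1, tolerance = 1e-10)
  expect_equal(r1$df, 3)
  expect_error(pearson_r(a, rep(1, 5)), "degenerate")
  set.seed(34)
  rs <- replicate(60, {
    x <- rnorm(20); y <- 0.77 * x + sqrt(1 - 0.77^2) * rnorm(20)
    pearson_r(x, y)$estimate
  })
  fisher_se <- 1 / sqrt(20 - 3)
  expect_lt(abs(mean(atanh(rs)) - atanh(0.77)), 3 * fisher_se / sqrt(60) + 0.05)
})

test_that("analyze_participant bundles the full single-participant pipeline", {
  null1 <- simulate_null_single(grid6, 8, n_sims = 500, seed = 71)
  ps <- analyze_participant(perfect_trials(), grid6, null_single = null1)
  expect_s3_class(ps, "participant_stats")
  expect_equal(ps$procrustes_distance, 0, tolerance = 1e-10)
  expect_equal(ps$p_procrustes, 0)
  expect_equal(ps$slope_x, 1, tolerance = 1e-12)
  expect_equal(ps$slope_y, 1, tolerance = 1e-12)
  expect_equal(ps$n_excluded, 0L)
})

test_that("analyze_group aggregates tests and surfaces degenerate cohorts", {
  null1 <- simulate_null_single(grid6, 8, n_sims = 500, seed = 72)
  nullg <- simulate_null_group(null1, 3, n_sims = 500, seed = 73)
  models <- sample_cohort_models(3, seed = 74)
  trials <- generate_cohort(models, design1, seed = 74)
  stats <- lapply(split(trials, trials$participant), analyze_participant,
                  grid = grid6, null_single = null1)
  rep <- analyze_group(stats, null_group = nullg)
  expect_s3_class(rep, "group_report")
  expect_equal(rep$n_participants, 3L)
  expect_equal(rep$total_trials, 3L * 288L)
  expect_equal(nrow(rep$table), 3L)
  expect_equal(rep$grand_mean_distance, mean(rep$table$procrustes_distance))
  expect_true(is.finite(rep$slope_x_vs_0$statistic))
  # identical participants: correlation degenerates but is surfaced, not thrown
  ident <- lapply(c("A", "B", "C"), function(id)
    analyze_participant(perfect_trials(id), grid6, null_single = null1))
  rep2 <- analyze_group(ident)
  expect_false(is.na(rep2$slope_correlation$note))
  expect_true(is.na(rep2$slope_correlation$statistic))
  expect_error(analyze_group(stats[1]), "at least 2")
})
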