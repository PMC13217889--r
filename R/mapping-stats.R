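#' @keywords internal
check_trials <- function(trials) {
  needed <- c("loc_row", "loc_col", "actual_x", "actual_y", "judged_x", "judged_y")
  missing <- setdiff(needed, names(trials))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  trials
}

#' @keywords internal
loc_label <- function(trials) sprintf("r%dc%d", trials$loc_row, trials$loc_col)

#' Exclude clicks outside the board
#'
#' Removes trials whose judged location falls outside the unit board square
#' (the on-screen image of the board). The boundary is inclusive: a click
#' exactly on the edge is kept; only strictly-outside clicks are excluded.
#'
#' @param trials trial data.frame (Bookstein-unit judged coordinates).
#' @return list with `trials` (kept rows), `n_excluded`, and `exclusion_rate`
#'   (fraction of input rows removed; 0 for empty input).
#' @export
exclude_outside <- function(trials) {
  check_trials(trials)
  n <- nrow(trials)
  if (n == 0L)
    return(list(trials = trials, n_excluded = 0L, exclusion_rate = 0))
  keep <- trials$judged_x >= 0 & trials$judged_x <= 1 &
          trials$judged_y >= 0 & trials$judged_y <= 1
  list(trials = trials[keep, , drop = FALSE],
       n_excluded = sum(!keep),
       exclusion_rate = sum(!keep) / n)
}

#' Build a participant's perceptual map
#'
#' Per-location arithmetic mean of the judged click coordinates: the
#' configuration of mean judged locations that is compared with the actual
#' grid layout by Procrustes superimposition.
#'
#' @param trials trial data.frame, already filtered with [exclude_outside()].
#' @param grid a [build_grid()] object; every grid location must have at
#'   least one contributing trial.
#' @param participant,condition identifiers stored on the map (defaults taken
#'   from the trial table when present).
#' @return An object of class `perceptual_map`: `means` (n_loc x 2 matrix in
#'   grid label order), `n_valid` (trials per location), `participant`,
#'   `condition`.
#' @export
build_map <- function(trials, grid, participant = NULL, condition = NULL) {
  check_trials(trials)
  stopifnot(inherits(grid, "stimulus_grid"))
  lab <- factor(loc_label(trials), levels = grid$labels)
  if (anyNA(lab))
    stop("trials contain locations not on the grid", call. = FALSE)
  n_valid <- as.integer(table(lab))
  if (any(n_valid == 0L))
    stop("no valid trials for location(s): ",
         paste(grid$labels[n_valid == 0L], collapse = ", "), call. = FALSE)
  means <- cbind(
    x = as.numeric(tapply(trials$judged_x, lab, mean)),
    y = as.numeric(tapply(trials$judged_y, lab, mean))
  )
  rownames(means) <- grid$labels
  if (is.null(participant))
    participant <- if ("participant" %in% names(trials)) as.character(trials$participant[1]) else NA_character_
  if (is.null(condition))
    condition <- if ("condition" %in% names(trials)) as.character(trials$condition[1]) else NA_character_
  structure(
    list(participant = participant, condition = condition,
         means = means, n_valid = stats::setNames(n_valid, grid$labels)),
    class = "perceptual_map"
  )
}

#' @export
print.perceptual_map <- function(x, ...) {
  cat(sprintf("Perceptual map: participant %s%s, %d locations, %d-%d trials/location\n",
              x$participant,
              if (!is.na(x$condition) && nzchar(x$condition)) paste0(" (", x$condition, ")") else "",
              nrow(x$means), min(x$n_valid), max(x$n_valid)))
  invisible(x)
}

#' Per-axis localization slopes
#'
#' Ordinary least-squares regression of judged on actual location, fitted
#' separately for the medio-lateral (x) and proximodistal (y) axes of one
#' participant's trials. A slope of 1 is veridical spatial mapping; 0 means
#' the judgments carry no positional information.
#'
#' @param trials trial data.frame (one participant, one condition), filtered.
#' @param granularity `"trial"` (default) fits over all trials; `"location"`
#'   fits over the per-location mean judgments.
#' @param grid required when `granularity = "location"`.
#' @return list with elements `x` and `y`, each of class `axis_regression`:
#'   `axis`, `slope`, `intercept`, `n`.
#' @export
axis_slopes <- function(trials, granularity = c("trial", "location"), grid = NULL) {
  check_trials(trials)
  granularity <- match.arg(granularity)
  if (granularity == "location") {
    if (is.null(grid)) stop("grid is required for location-level regression", call. = FALSE)
    map <- build_map(trials, grid)
    dat <- data.frame(actual_x = grid$points[, 1], actual_y = grid$points[, 2],
                      judged_x = map$means[, 1], judged_y = map$means[, 2])
  } else {
    dat <- trials
  }
  if (nrow(dat) < 2L) stop("need at least 2 trials per axis", call. = FALSE)
  one_axis <- function(actual, judged, axis) {
    if (stats::var(actual) == 0)
      stop("actual ", axis, " coordinate has zero variance; slope undefined",
           call. = FALSE)
    fit <- stats::lm(judged ~ actual)
    structure(list(axis = axis,
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   n = length(judged)),
              class = "axis_regression")
  }
  list(x = one_axis(dat$actual_x, dat$judged_x, "mediolateral"),
       y = one_axis(dat$actual_y, dat$judged_y, "proximodistal"))
}

#' Per-location variable error
#'
#' Trial-to-trial dispersion of the judgments: the sample standard deviation
#' (n - 1 denominator) of the judged coordinate, computed separately for each
#' grid location and each axis, summarized as the unweighted mean over
#' locations. A precision measure, distinct from constant error (bias).
#'
#' @param trials filtered trial data.frame; every location needs >= 2 trials.
#' @param grid a [build_grid()] object.
#' @return list with elements `x` and `y`, each of class `variable_error`:
#'   `axis`, `per_location_sd` (named vector over grid labels), `mean_sd`.
#' @export
variable_error <- function(trials, grid) {
  check_trials(trials)
  stopifnot(inherits(grid, "stimulus_grid"))
  lab <- factor(loc_label(trials), levels = grid$labels)
  if (anyNA(lab))
    stop("trials contain locations not on the grid", call. = FALSE)
  counts <- table(lab)
  if (any(counts < 2L))
    stop("fewer than 2 valid trials at location(s): ",
         paste(grid$labels[counts < 2L], collapse = ", "), call. = FALSE)
  one_axis <- function(judged, axis) {
    sds <- as.numeric(tapply(judged, lab, stats::sd))
    names(sds) <- grid$labels
    structure(list(axis = axis, per_location_sd = sds, mean_sd = mean(sds)),
              class = "variable_error")
  }
  list(x = one_axis(trials$judged_x, "mediolateral"),
       y = one_axis(trials$judged_y, "proximodistal"))
}

#' @keywords internal
new_group_test <- function(statistic, df, p, effect = NA_real_,
                           effect_type = NA_character_, estimate = NA_real_,
                           note = NA_character_) {
  structure(
    list(statistic = statistic, df = df, p = p, effect = effect,
         effect_type = effect_type, estimate = estimate, note = note),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  if (!is.na(x$note)) {
    cat("degenerate test:", x$note, "\n")
  } else {
    eff <- if (is.na(x$effect)) "" else sprintf(", %s = %.3f", x$effect_type, x$effect)
    cat(sprintf("statistic = %.3f, df = %g, p = %.4g%s\n", x$statistic, x$df, x$p, eff))
  }
  invisible(x)
}

#' One-sample t-test with Cohen's d
#'
#' Two-tailed one-sample t-test of a set of per-participant values against
#' `mu0`, reporting Cohen's d = (mean - mu0) / SD. Used to test mean
#' localization slopes against 0 (no ability) or 1 (veridical mapping).
#'
#' @param values numeric vector, n >= 2, nonzero SD.
#' @param mu0 null value (default 0).
#' @return A `group_test` with `statistic` (t), `df`, `p`, `effect` (d) and
#'   `estimate` (sample mean).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  ht <- stats::t.test(values, mu = mu0)
  new_group_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                 effect = (mean(values) - mu0) / stats::sd(values),
                 effect_type = "d", estimate = mean(values))
}

#' One-sample t statistic from summary statistics
#'
#' Recomputes t, two-tailed p and Cohen's d from a reported (mean, SD, n)
#' triple: t = (M - mu0) / (SD / sqrt(n)), d = (M - mu0) / SD, df = n - 1.
#' Useful for checking published group statistics against their printed
#' summaries.
#'
#' @param mean,sd,n summary statistics (sd > 0, n >= 2).
#' @param mu0 null value (default 0).
#' @return A `group_test`.
#' @export
one_sample_t_summary <- function(mean, sd, n, mu0 = 0) {
  stopifnot(sd > 0, n >= 2)
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  new_group_test(t, df, 2 * stats::pt(-abs(t), df),
                 effect = (mean - mu0) / sd, effect_type = "d",
                 estimate = mean)
}

#' Paired t-test with Cohen's dz
#'
#' Two-tailed paired t-test (a one-sample test on the differences a - b),
#' reporting dz = mean difference / SD of differences. Used for the
#' between-axis anisotropy comparisons of slopes and variable errors.
#'
#' @param a,b equal-length numeric vectors (n >= 2); the differences must
#'   not be constant.
#' @return A `group_test` with `effect_type = "dz"` and `estimate` the mean
#'   difference.
#' @export
paired_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate sample: differences have zero standard deviation", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  new_group_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                 effect = mean(d) / stats::sd(d), effect_type = "dz",
                 estimate = mean(d))
}

#' Pearson correlation with df = n - 2
#'
#' Two-tailed Pearson correlation via the t transform, reporting r as the
#' statistic's companion estimate. Used for the between-axis correlation of
#' localization slopes across participants.
#'
#' @param a,b equal-length numeric vectors (n >= 3), both nonconstant.
#' @return A `group_test` with `statistic` the t value, `estimate` the
#'   correlation r, and `df = n - 2`.
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate sample: constant input", call. = FALSE)
  ht <- stats::cor.test(a, b, method = "pearson")
  new_group_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                 estimate = unname(ht$estimate))
}

#' Full per-participant analysis
#'
#' Runs the whole single-participant pipeline: outside-board exclusion,
#' perceptual-map construction, Procrustes distance to the grid (with
#' empirical p against a Monte-Carlo null when one is supplied), per-axis
#' regression slopes, and per-location variable error.
#'
#' @param trials one participant's (and condition's) trial data.frame,
#'   unfiltered.
#' @param grid a [build_grid()] object.
#' @param null_single optional single-level `null_distribution`.
#' @param allow_reflection passed to the Procrustes step.
#' @param granularity slope regression granularity, see [axis_slopes()].
#' @return An object of class `participant_stats`.
#' @export
analyze_participant <- function(trials, grid, null_single = NULL,
                                allow_reflection = TRUE,
                                granularity = "trial") {
  check_trials(trials)
  excl <- exclude_outside(trials)
  kept <- excl$trials
  map <- build_map(kept, grid)
  dist <- procrustes_distance(map, grid, allow_reflection = allow_reflection)
  p <- if (is.null(null_single)) NA_real_ else empirical_p(null_single, dist)
  slopes <- axis_slopes(kept, granularity = granularity, grid = grid)
  ve <- variable_error(kept, grid)
  structure(
    list(participant = map$participant, condition = map$condition,
         n_trials = nrow(trials), n_excluded = excl$n_excluded,
         exclusion_rate = excl$exclusion_rate,
         map = map,
         procrustes_distance = dist, p_procrustes = p,
         slope_x = slopes$x$slope, slope_y = slopes$y$slope,
         intercept_x = slopes$x$intercept, intercept_y = slopes$y$intercept,
         ve_x = ve$x$mean_sd, ve_y = ve$y$mean_sd),
    class = "participant_stats"
  )
}

#' @export
print.participant_stats <- function(x, ...) {
  cat(sprintf("Participant %s%s: slopes (ML %.3f, PD %.3f), VE (ML %.3f, PD %.3f)\n",
              x$participant,
              if (!is.na(x$condition) && nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              x$slope_x, x$slope_y, x$ve_x, x$ve_y))
  cat(sprintf("Procrustes distance %.4f%s; excluded %d/%d trials (%.2f%%)\n",
              x$procrustes_distance,
              if (is.na(x$p_procrustes)) "" else sprintf(" (empirical p = %.4g)", x$p_procrustes),
              x$n_excluded, x$n_trials, 100 * x$exclusion_rate))
  invisible(x)
}

#' Group-level analysis of a cohort of participants
#'
#' Aggregates per-participant statistics into the group-level report: a
#' one-sample t-test of each axis's slopes against 0, the paired
#' medio-lateral vs proximodistal slope comparison, the between-axis slope
#' correlation, the paired variable-error anisotropy test, and the grand-mean
#' Procrustes distance with its empirical p against a group-level null.
#' Degenerate inputs (e.g. identical participants making the correlation
#' undefined) are surfaced as degenerate `group_test` records, not errors.
#'
#' @param stats list of `participant_stats` (>= 2).
#' @param null_group optional group-level `null_distribution` whose
#'   `group_size` should equal the number of participants.
#' @return An object of class `group_report`: per-participant `table`
#'   (data.frame) and the test objects.
#' @export
analyze_group <- function(stats, null_group = NULL) {
  if (length(stats) < 2L) stop("need at least 2 participants", call. = FALSE)
  stopifnot(all(vapply(stats, inherits, logical(1), "participant_stats")))
  tab <- data.frame(
    participant = vapply(stats, `[[`, character(1), "participant"),
    condition = vapply(stats, `[[`, character(1), "condition"),
    slope_x = vapply(stats, `[[`, numeric(1), "slope_x"),
    slope_y = vapply(stats, `[[`, numeric(1), "slope_y"),
    ve_x = vapply(stats, `[[`, numeric(1), "ve_x"),
    ve_y = vapply(stats, `[[`, numeric(1), "ve_y"),
    procrustes_distance = vapply(stats, `[[`, numeric(1), "procrustes_distance"),
    p_procrustes = vapply(stats, `[[`, numeric(1), "p_procrustes"),
    n_trials = vapply(stats, `[[`, numeric(1), "n_trials"),
    n_excluded = vapply(stats, `[[`, numeric(1), "n_excluded"),
    stringsAsFactors = FALSE
  )
  safe <- function(expr) {
    tryCatch(expr, error = function(e)
      new_group_test(NA_real_, NA_real_, NA_real_, note = conditionMessage(e)))
  }
  grand <- mean(tab$procrustes_distance)
  p_grand <- if (is.null(null_group)) NA_real_ else {
    if (!is.na(null_group$group_size) && null_group$group_size != nrow(tab))
      warning("group null was built for group size ", null_group$group_size,
              " but the cohort has ", nrow(tab), " participants")
    empirical_p(null_group, grand)
  }
  structure(
    list(table = tab,
         n_participants = nrow(tab),
         slope_x_vs_0 = safe(one_sample_t(tab$slope_x, 0)),
         slope_y_vs_0 = safe(one_sample_t(tab$slope_y, 0)),
         slope_x_vs_y = safe(paired_t(tab$slope_x, tab$slope_y)),
         slope_correlation = safe(pearson_r(tab$slope_x, tab$slope_y)),
         ve_x_vs_y = safe(paired_t(tab$ve_x, tab$ve_y)),
         grand_mean_distance = grand,
         p_grand_mean = p_grand,
         total_trials = sum(tab$n_trials),
         total_excluded = sum(tab$n_excluded)),
    class = "group_report"
  )
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("Group report: %d participants, %d trials (%d excluded, %.2f%%)\n",
              x$n_participants, x$total_trials, x$total_excluded,
              100 * x$total_excluded / x$total_trials))
  cat("medio-lateral slopes vs 0:   "); print(x$slope_x_vs_0)
  cat("proximodistal slopes vs 0:   "); print(x$slope_y_vs_0)
  cat("slope anisotropy (ML - PD):  "); print(x$slope_x_vs_y)
  cat("between-axis slope corr:     "); print(x$slope_correlation)
  cat("variable error (ML - PD):    "); print(x$ve_x_vs_y)
  cat(sprintf("grand-mean Procrustes distance %.4f%s\n", x$grand_mean_distance,
              if (is.na(x$p_grand_mean)) "" else sprintf(" (empirical p = %.4g)", x$p_grand_mean)))
  invisible(x)
}
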