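#' Write a trial table to CSV
#'
#' Comma-separated, header row, '.' decimal separator, UTF-8; one row per
#' trial in the schema produced by [generate_trials()].
#'
#' @param trials trial data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads and validates a trial CSV. Coordinates are expected in Bookstein
#' units by default; with `units = "cm"` or `units = "px"` the four
#' coordinate columns are converted on load by Bookstein registration with
#' the supplied landmark positions (in the same raw units). When a grid is
#' given, each row's `(loc_row, loc_col)` is checked against its
#' `(actual_x, actual_y)` to within `tol`, and offending rows are reported
#' with their line numbers.
#'
#' @param path CSV file with the [generate_trials()] schema.
#' @param grid optional [build_grid()] used for consistency validation.
#' @param units `"bookstein"` (default), `"cm"` or `"px"`.
#' @param landmark_a,landmark_b landmark coordinates in the raw units;
#'   required unless `units = "bookstein"`.
#' @param tol tolerance for the grid-consistency check (Bookstein units).
#' @return validated trial data.frame.
#' @export
read_trials <- function(path, grid = NULL,
                        units = c("bookstein", "cm", "px"),
                        landmark_a = NULL, landmark_b = NULL,
                        tol = 1e-6) {
  units <- match.arg(units)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  needed <- c("participant", "condition", "loc_row", "loc_col",
              "actual_x", "actual_y", "judged_x", "judged_y")
  missing <- setdiff(needed, names(trials))
  if (length(missing))
    stop("'", path, "' is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num_cols <- c("loc_row", "loc_col", "actual_x", "actual_y",
                "judged_x", "judged_y")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(trials[[cn]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("'", path, "': unparseable numbers in column '", cn, "' at line(s) ",
           paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
    trials[[cn]] <- v
  }
  if (units != "bookstein") {
    if (is.null(landmark_a) || is.null(landmark_b))
      stop("landmark_a and landmark_b are required for ", units, " coordinates",
           call. = FALSE)
    act <- bookstein_register(cbind(trials$actual_x, trials$actual_y),
                              landmark_a, landmark_b)
    jud <- bookstein_register(cbind(trials$judged_x, trials$judged_y),
                              landmark_a, landmark_b)
    trials$actual_x <- unname(act[, 1]); trials$actual_y <- unname(act[, 2])
    trials$judged_x <- unname(jud[, 1]); trials$judged_y <- unname(jud[, 2])
  }
  if (any(trials$actual_x < -1e-9 | trials$actual_x > 1 + 1e-9 |
          trials$actual_y < -1e-9 | trials$actual_y > 1 + 1e-9))
    stop("'", path, "': actual coordinates outside the unit board square",
         call. = FALSE)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "stimulus_grid"))
    lab <- sprintf("r%dc%d", trials$loc_row, trials$loc_col)
    unknown <- which(!lab %in% grid$labels)
    if (length(unknown))
      stop("'", path, "': grid indices off the grid at line(s) ",
           paste(utils::head(unknown + 1L, 10), collapse = ", "), call. = FALSE)
    exp_pts <- grid$points[lab, , drop = FALSE]
    off <- which(abs(exp_pts[, 1] - trials$actual_x) > tol |
                 abs(exp_pts[, 2] - trials$actual_y) > tol)
    if (length(off))
      stop("'", path, "': actual coordinates inconsistent with (loc_row, loc_col) at line(s) ",
           paste(utils::head(off + 1L, 10), collapse = ", "), call. = FALSE)
  }
  trials$valid <- trials$judged_x >= 0 & trials$judged_x <= 1 &
                  trials$judged_y >= 0 & trials$judged_y <= 1
  trials
}

#' @keywords internal
group_test_json <- function(gt) {
  if (!is.na(gt$note)) return(list(degenerate = gt$note))
  out <- list(statistic = gt$statistic, df = gt$df, p = gt$p)
  if (!is.na(gt$effect)) { out[[gt$effect_type]] <- gt$effect }
  if (!is.na(gt$estimate)) out$estimate <- gt$estimate
  out
}

#' @keywords internal
report_json <- function(report) {
  list(
    n_participants = report$n_participants,
    total_trials = report$total_trials,
    total_excluded = report$total_excluded,
    exclusion_rate = report$total_excluded / report$total_trials,
    slope_mediolateral_vs_0 = group_test_json(report$slope_x_vs_0),
    slope_proximodistal_vs_0 = group_test_json(report$slope_y_vs_0),
    slope_anisotropy_paired = group_test_json(report$slope_x_vs_y),
    slope_between_axis_correlation = group_test_json(report$slope_correlation),
    variable_error_anisotropy_paired = group_test_json(report$ve_x_vs_y),
    mean_slope_mediolateral = mean(report$table$slope_x),
    mean_slope_proximodistal = mean(report$table$slope_y),
    mean_variable_error_mediolateral = mean(report$table$ve_x),
    mean_variable_error_proximodistal = mean(report$table$ve_y),
    grand_mean_procrustes_distance = report$grand_mean_distance,
    p_grand_mean = report$p_grand_mean,
    n_participants_below_chance = sum(report$table$p_procrustes < 0.05)
  )
}

#' Run the full analysis pipeline from a configuration
#'
#' End-to-end driver: obtains trial data (from a CSV or by simulating a
#' synthetic cohort), builds or reuses cached Monte-Carlo nulls, analyzes
#' every participant and condition, and writes a JSON group report plus a
#' per-participant CSV table and the null caches to the output directory.
#' All randomness is governed by the seeds in the configuration, so reruns
#' with the same configuration are byte-identical.
#'
#' @param config named list, or path to a YAML file with the same keys:
#'   \describe{
#'     \item{input}{path to a trial CSV (omit to simulate).}
#'     \item{synthetic}{list: `n_participants`, `slope_mean`, `slope_sd`,
#'       `noise_sd`, `lapse_rate`, `seed` — passed to
#'       [sample_cohort_models()] / [generate_cohort()].}
#'     \item{experiment}{label (default `"exp1"`).}
#'     \item{conditions}{condition labels (default `"none"`).}
#'     \item{reps_per_location}{reps per condition (default 8).}
#'     \item{nulls}{list: `n_sims` (default 10000), `seed` (default 1),
#'       `allow_reflection` (default TRUE).}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @return the list of per-condition `group_report`s, invisibly; side
#'   effects: `report.json`, `participants.csv`, `null_single_*.csv`,
#'   `null_group_*.csv` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  conditions <- if (is.null(config$conditions)) "none" else as.character(config$conditions)
  reps <- if (is.null(config$reps_per_location)) 8L else as.integer(config$reps_per_location)
  grid <- build_grid()
  design <- experiment_design(grid, reps_per_location = reps,
                              conditions = conditions)
  experiment <- if (is.null(config$experiment)) "exp1" else config$experiment

  if (!is.null(config$input)) {
    trials <- read_trials(config$input, grid = grid)
  } else {
    syn <- config$synthetic
    if (is.null(syn)) stop("config needs either 'input' or 'synthetic'", call. = FALSE)
    arg <- function(key, default) if (is.null(syn[[key]])) default else syn[[key]]
    models <- sample_cohort_models(
      n = arg("n_participants", 20L),
      slope_mean = unlist(arg("slope_mean", c(0.840, 0.428))),
      slope_sd = unlist(arg("slope_sd", c(0.213, 0.229))),
      noise_sd = unlist(arg("noise_sd", c(0.121, 0.137))),
      lapse_rate = arg("lapse_rate", 0.0056),
      seed = arg("seed", 1L)
    )
    trials <- generate_cohort(models, design, experiment = experiment)
    write_trials(trials, file.path(out_dir, "trials.csv"))
  }

  null_cfg <- if (is.null(config$nulls)) list() else config$nulls
  n_sims <- if (is.null(null_cfg$n_sims)) 10000L else as.integer(null_cfg$n_sims)
  null_seed <- if (is.null(null_cfg$seed)) 1L else as.integer(null_cfg$seed)
  allow_reflection <- if (is.null(null_cfg$allow_reflection)) TRUE else isTRUE(null_cfg$allow_reflection)

  participants <- unique(trials$participant)
  reports <- list()
  per_part_rows <- list()
  for (cond in conditions) {
    sub <- if (length(conditions) == 1L && identical(cond, "none") &&
               !"condition" %in% names(trials)) trials
           else trials[trials$condition == cond, , drop = FALSE]
    null_path <- file.path(out_dir, sprintf("null_single_%s.csv", cond))
    null_single <- simulate_null_single(grid, reps_per_location = reps,
                                        n_sims = n_sims, seed = null_seed,
                                        allow_reflection = allow_reflection)
    write_null(null_single, null_path)
    null_group <- simulate_null_group(null_single,
                                      group_size = length(participants),
                                      n_sims = n_sims, seed = null_seed + 1L)
    write_null(null_group, file.path(out_dir, sprintf("null_group_%s.csv", cond)))
    stats <- lapply(participants, function(p)
      analyze_participant(sub[sub$participant == p, , drop = FALSE], grid,
                          null_single = null_single,
                          allow_reflection = allow_reflection))
    reports[[cond]] <- analyze_group(stats, null_group = null_group)
    tab <- reports[[cond]]$table
    per_part_rows[[cond]] <- tab
  }

  doc <- list(
    experiment = experiment,
    settings = list(
      reps_per_location = reps, conditions = conditions,
      null = list(n_sims = n_sims, seed = null_seed,
                  allow_reflection = allow_reflection),
      synthetic_seed = if (!is.null(config$synthetic)) {
        if (is.null(config$synthetic$seed)) 1L else config$synthetic$seed
      } else NULL
    ),
    results = lapply(reports, report_json)
  )
  jsonlite::write_json(doc, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(do.call(rbind, per_part_rows),
                   file.path(out_dir, "participants.csv"), row.names = FALSE)
  invisible(reports)
}
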