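#' Generative model of one participant's localization behaviour
#'
#' Linear-compression response model: a judged click is the actual location
#' pulled toward a convergence point by per-axis compression factors, plus
#' anisotropic Gaussian response noise, with occasional lapse trials in which
#' the click is instead uniform over an extended region that can fall outside
#' the board. The per-axis regression of judged on actual location recovers
#' `slope_x` / `slope_y` as its slopes, which makes parameter-recovery
#' studies directly interpretable.
#'
#' By default (`bounded = TRUE`) the non-lapse response is a board-truncated
#' Gaussian: noise draws are rejection-sampled until the click lands on the
#' unit board square, mirroring clicking behaviour on an on-screen image of
#' the board, where off-board clicks are rare (a fraction of a percent of
#' trials) even though per-location response noise is sizeable. Only lapse
#' trials can then fall outside the board. With `bounded = FALSE` the
#' Gaussian is unbounded and off-board tails are excluded downstream instead.
#'
#' Defaults are anchored to the group means reported for a one-posture
#' 288-trial board session: medio-lateral slope 0.840, proximodistal slope
#' 0.428, response noise SD 0.121 / 0.137 Bookstein units; the default lapse
#' rate 0.0056 makes the expected off-board click rate under the bounded
#' model equal the 0.17% exclusion rate observed in such sessions (the lapse
#' region extends 0.1 beyond the board on each side, so 30.6% of lapses land
#' off-board).
#'
#' @param slope_x,slope_y per-axis compression factors (1 = veridical,
#'   0 = everything judged at the convergence point).
#' @param center (x, y) convergence point in Bookstein units.
#' @param noise_sd_x,noise_sd_y Gaussian response noise SD per axis,
#'   Bookstein units (>= 0).
#' @param lapse_rate probability, in \[0, 1\], that a trial is a stray click
#'   uniform over `lapse_region`.
#' @param lapse_region (lo, hi) of the square lapse region on both axes;
#'   default \[-0.1, 1.1\] so some lapses land on-board and are undetectable.
#' @param bounded if `TRUE` (default), non-lapse clicks are truncated to the
#'   board by rejection sampling.
#' @param seed optional per-participant integer seed.
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(slope_x = 0.840, slope_y = 0.428,
                              center = c(0.5, 0.5),
                              noise_sd_x = 0.121, noise_sd_y = 0.137,
                              lapse_rate = 0.0056,
                              lapse_region = c(-0.1, 1.1),
                              bounded = TRUE,
                              seed = NULL) {
  stopifnot(is.finite(slope_x), is.finite(slope_y),
            length(center) == 2L, all(is.finite(center)))
  if (noise_sd_x < 0 || noise_sd_y < 0) stop("noise SDs must be >= 0", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1) stop("lapse_rate must be in [0, 1]", call. = FALSE)
  if (length(lapse_region) != 2L || lapse_region[1] >= lapse_region[2])
    stop("lapse_region must be (lo, hi) with lo < hi", call. = FALSE)
  structure(
    list(slope_x = slope_x, slope_y = slope_y, center = as.numeric(center),
         noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
         lapse_rate = lapse_rate, lapse_region = as.numeric(lapse_region),
         bounded = isTRUE(bounded),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "participant_model"
  )
}

#' Experimental design of a localization session
#'
#' Fixes the stimulus grid, the conditions (e.g. arm postures) and the number
#' of repetitions of each location per condition. One block presents every
#' location once in random order, so `reps_per_location` equals the number of
#' blocks per condition. The defaults describe a one-condition session of 8
#' blocks x 36 locations = 288 trials; the two-posture design uses 4
#' repetitions in each of two conditions (also 288 trials).
#'
#' @param grid a [build_grid()] object.
#' @param reps_per_location repetitions of each location per condition.
#' @param conditions character vector of condition labels.
#' @param n_participants cohort size (used by [generate_cohort()] defaults).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(grid = build_grid(), reps_per_location = 8L,
                              conditions = "none", n_participants = 20L) {
  stopifnot(inherits(grid, "stimulus_grid"))
  reps_per_location <- as.integer(reps_per_location)
  if (reps_per_location < 1L) stop("reps_per_location must be >= 1", call. = FALSE)
  if (!length(conditions)) stop("need at least one condition", call. = FALSE)
  if (anyDuplicated(conditions)) stop("condition labels must be unique", call. = FALSE)
  structure(
    list(grid = grid, reps_per_location = reps_per_location,
         conditions = as.character(conditions),
         n_participants = as.integer(n_participants)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  n_loc <- length(x$grid$labels)
  cat(sprintf("Design: %d locations x %d reps x %d condition(s) = %d trials/participant; n = %d\n",
              n_loc, x$reps_per_location, length(x$conditions),
              n_loc * x$reps_per_location * length(x$conditions),
              x$n_participants))
  invisible(x)
}

#' Simulate one participant's trials
#'
#' Generates the full trial table of one synthetic session: for each
#' condition, `reps_per_location` blocks each presenting all grid locations
#' in a freshly randomized order, with judged clicks drawn from the
#' participant's response model. Fully reproducible from the model's seed.
#'
#' @param model a [participant_model()].
#' @param design an [experiment_design()].
#' @param participant,experiment identifier labels for the output table.
#' @return data.frame with one row per trial: `participant`, `experiment`,
#'   `condition`, `block`, `trial_index`, `loc_row`, `loc_col`, `actual_x`,
#'   `actual_y`, `judged_x`, `judged_y`, `valid`.
#' @export
generate_trials <- function(model, design, participant = "P01",
                            experiment = "exp1") {
  stopifnot(inherits(model, "participant_model"),
            inherits(design, "experiment_design"))
  grid <- design$grid
  n_loc <- length(grid$labels)
  gen <- function() {
    rows <- list()
    block_no <- 0L
    for (cond in design$conditions) {
      for (b in seq_len(design$reps_per_location)) {
        block_no <- block_no + 1L
        ord <- sample.int(n_loc)   # random presentation order within block
        rows[[block_no]] <- data.frame(
          condition = cond, block = block_no, order = ord,
          stringsAsFactors = FALSE
        )
      }
    }
    d <- do.call(rbind, rows)
    idx <- d$order
    ax <- grid$points[idx, 1]; ay <- grid$points[idx, 2]
    n <- nrow(d)
    mu_x <- model$center[1] + model$slope_x * (ax - model$center[1])
    mu_y <- model$center[2] + model$slope_y * (ay - model$center[2])
    jx <- mu_x + stats::rnorm(n, 0, model$noise_sd_x)
    jy <- mu_y + stats::rnorm(n, 0, model$noise_sd_y)
    if (model$bounded) {
      # truncate the response to the board: redraw off-board noise
      for (iter in 1:1000) {
        off <- which(jx < 0 | jx > 1 | jy < 0 | jy > 1)
        if (!length(off)) break
        jx[off] <- mu_x[off] + stats::rnorm(length(off), 0, model$noise_sd_x)
        jy[off] <- mu_y[off] + stats::rnorm(length(off), 0, model$noise_sd_y)
      }
      # pathological models (mean far off-board): clamp the stragglers
      jx <- pmin(pmax(jx, 0), 1)
      jy <- pmin(pmax(jy, 0), 1)
    }
    lapse <- stats::runif(n) < model$lapse_rate
    if (any(lapse)) {
      lo <- model$lapse_region[1]; hi <- model$lapse_region[2]
      jx[lapse] <- stats::runif(sum(lapse), lo, hi)
      jy[lapse] <- stats::runif(sum(lapse), lo, hi)
    }
    data.frame(
      participant = participant, experiment = experiment,
      condition = d$condition, block = d$block,
      trial_index = seq_len(n),
      loc_row = (idx - 1L) %/% grid$cols + 1L,
      loc_col = (idx - 1L) %% grid$cols + 1L,
      actual_x = unname(ax), actual_y = unname(ay),
      judged_x = jx, judged_y = jy,
      valid = jx >= 0 & jx <= 1 & jy >= 0 & jy <= 1,
      stringsAsFactors = FALSE
    )
  }
  if (is.na(model$seed)) gen() else withr::with_seed(model$seed, gen())
}

#' Draw a heterogeneous cohort of participant models
#'
#' Samples per-participant compression slopes from normal distributions with
#' the given means and between-participant SDs; response noise and lapse rate
#' are held fixed across participants. Defaults match the reported group
#' slope means/SDs for a one-posture session (medio-lateral 0.840 +- 0.213,
#' proximodistal 0.428 +- 0.229).
#'
#' @param n cohort size.
#' @param slope_mean,slope_sd length-2 (x, y) means and between-participant
#'   SDs of the compression slopes.
#' @param noise_sd length-2 (x, y) response noise SDs, shared by everyone.
#' @param lapse_rate shared lapse probability.
#' @param center shared convergence point.
#' @param seed integer seed for the cohort draw (also used to derive the
#'   per-participant simulation seeds).
#' @return named list of `participant_model`s (`P01`, `P02`, ...).
#' @export
sample_cohort_models <- function(n = 20L,
                                 slope_mean = c(0.840, 0.428),
                                 slope_sd = c(0.213, 0.229),
                                 noise_sd = c(0.121, 0.137),
                                 lapse_rate = 0.0056,
                                 center = c(0.5, 0.5),
                                 seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, length(slope_mean) == 2L, length(slope_sd) == 2L,
            length(noise_sd) == 2L)
  withr::with_seed(seed, {
    bx <- stats::rnorm(n, slope_mean[1], slope_sd[1])
    by <- stats::rnorm(n, slope_mean[2], slope_sd[2])
    seeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  models <- lapply(seq_len(n), function(i)
    participant_model(slope_x = bx[i], slope_y = by[i], center = center,
                      noise_sd_x = noise_sd[1], noise_sd_y = noise_sd[2],
                      lapse_rate = lapse_rate, seed = seeds[i]))
  names(models) <- sprintf("P%02d", seq_len(n))
  models
}

#' Simulate a full cohort dataset
#'
#' Concatenates the trial tables of a list of participant models. When a
#' cohort `seed` is given, per-participant seeds are derived from it
#' deterministically (models that already carry a seed keep it), so the same
#' cohort seed always yields the identical dataset.
#'
#' @param models named list of [participant_model()]s; names are the
#'   participant identifiers and must be unique.
#' @param design an [experiment_design()].
#' @param experiment experiment label for the output table.
#' @param seed optional cohort-level integer seed.
#' @return data.frame of all trials (schema of [generate_trials()]).
#' @export
generate_cohort <- function(models, design, experiment = "exp1", seed = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- sprintf("P%02d", seq_along(models))
  if (anyDuplicated(names(models)))
    stop("duplicate participant identifiers", call. = FALSE)
  if (!is.null(seed)) {
    sub_seeds <- withr::with_seed(seed,
      sample.int(.Machine$integer.max - 1L, length(models)))
    for (i in seq_along(models)) {
      if (is.na(models[[i]]$seed)) models[[i]]$seed <- sub_seeds[i]
    }
  }
  out <- lapply(seq_along(models), function(i)
    generate_trials(models[[i]], design, participant = names(models)[i],
                    experiment = experiment))
  do.call(rbind, out)
}
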