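#' @keywords internal
new_null_distribution <- function(values, n_sims, reps_per_location, level,
                                  group_size = NA_integer_, seed = NA_integer_,
                                  allow_reflection = TRUE) {
  structure(
    list(values = sort(values), n_sims = as.integer(n_sims),
         reps_per_location = as.integer(reps_per_location),
         level = level, group_size = as.integer(group_size),
         seed = as.integer(seed), allow_reflection = allow_reflection),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte-Carlo null (%s%s): %d simulations, %d reps/location, seed %s\n",
              x$level,
              if (identical(x$level, "group")) sprintf(", group size %d", x$group_size) else "",
              x$n_sims, x$reps_per_location,
              if (is.na(x$seed)) "NA" else as.character(x$seed)))
  q <- stats::quantile(x$values, c(0.01, 0.05, 0.5))
  cat(sprintf("quantiles: 1%% %.4f, 5%% %.4f, median %.4f\n", q[1], q[2], q[3]))
  invisible(x)
}

# Minimum-residual Procrustes distance of many source maps onto one fixed
# target, vectorized. For each source X (rows of the chunk), the minimized
# sum of squares over translation, rotation, uniform scale (and optionally
# reflection) is ||Yc||^2 - tr(Sigma)^2 / ||Xc||^2, where tr(Sigma) is the
# sum (or difference, when a reflection would be needed but is disallowed)
# of the singular values of the 2x2 cross-covariance, obtained in closed
# form: s1 + s2 = sqrt(||M||_F^2 + 2|det M|), s1 - s2 = sqrt(||M||_F^2 - 2|det M|).
#' @keywords internal
procrustes_distance_batch <- function(Xx, Xy, target, allow_reflection = TRUE) {
  n_pts <- ncol(Xx)
  cy <- colMeans(target)
  Ycx <- target[, 1] - cy[1]
  Ycy <- target[, 2] - cy[2]
  ssy <- sum(Ycx^2 + Ycy^2)
  Xcx <- Xx - rowMeans(Xx)
  Xcy <- Xy - rowMeans(Xy)
  ssx <- rowSums(Xcx^2) + rowSums(Xcy^2)
  a <- drop(Xcx %*% Ycx); b <- drop(Xcx %*% Ycy)
  cc <- drop(Xcy %*% Ycx); d <- drop(Xcy %*% Ycy)
  fro2 <- a^2 + b^2 + cc^2 + d^2
  dt <- a * d - b * cc
  ssum <- sqrt(fro2 + 2 * abs(dt))
  sdiff <- sqrt(pmax(fro2 - 2 * abs(dt), 0))
  trace_sigma <- if (allow_reflection) ssum else ifelse(dt >= 0, ssum, sdiff)
  ss <- pmax(ssy - trace_sigma^2 / ssx, 0)
  sqrt(ss / n_pts)
}

#' Single-participant Monte-Carlo null for the Procrustes distance
#'
#' Simulates the Procrustes distance expected from a participant with no
#' localization ability: for each simulation, every grid location receives
#' `reps_per_location` independent clicks uniform on the unit board square,
#' the clicks are averaged per location exactly as in the real pipeline, and
#' the resulting random map is superimposed on the grid. The sorted distances
#' form the null distribution against which observed per-participant
#' distances are assessed with [empirical_p()].
#'
#' @param grid a [build_grid()] object.
#' @param reps_per_location clicks simulated per location before averaging
#'   (8 for a one-posture 288-trial session, 4 per posture in the two-posture
#'   design; 1 reproduces one-random-point-per-location nulls).
#' @param n_sims number of simulated maps (the reference analysis uses 1e6;
#'   1e4 is adequate for desk-scale work).
#' @param seed integer seed; the simulation stream is fully determined by it.
#' @param allow_reflection passed to the distance computation.
#' @return A `null_distribution` with sorted `values` and provenance fields.
#' @export
simulate_null_single <- function(grid, reps_per_location = 8L, n_sims = 10000L,
                                 seed = 1L, allow_reflection = TRUE) {
  stopifnot(inherits(grid, "stimulus_grid"))
  reps_per_location <- as.integer(reps_per_location)
  n_sims <- as.integer(n_sims)
  if (n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  if (reps_per_location < 1L) stop("reps_per_location must be >= 1", call. = FALSE)
  n_loc <- length(grid$labels)
  target <- grid$points
  chunk <- 4000L   # fixed so the random stream is reproducible from the seed alone
  values <- numeric(n_sims)
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_sims) {
      k <- min(chunk, n_sims - done)
      # columns iterate location fastest, then simulation
      mx <- colMeans(matrix(stats::runif(k * n_loc * reps_per_location),
                            nrow = reps_per_location))
      my <- colMeans(matrix(stats::runif(k * n_loc * reps_per_location),
                            nrow = reps_per_location))
      Xx <- matrix(mx, nrow = k, ncol = n_loc, byrow = TRUE)
      Xy <- matrix(my, nrow = k, ncol = n_loc, byrow = TRUE)
      values[done + seq_len(k)] <-
        procrustes_distance_batch(Xx, Xy, target, allow_reflection)
      done <- done + k
    }
  })
  new_null_distribution(values, n_sims, reps_per_location, "single",
                        seed = seed, allow_reflection = allow_reflection)
}

#' Group-mean Monte-Carlo null for the Procrustes distance
#'
#' Null distribution of the grand-mean Procrustes distance of a sample of
#' participants: each simulation draws `group_size` values with replacement
#' from a single-participant null and records their mean.
#'
#' @param single_null a `null_distribution` from [simulate_null_single()].
#' @param group_size number of participants in the group (20 and 18 in the
#'   one- and two-posture experiments respectively).
#' @param n_sims number of simulated group means.
#' @param seed integer seed.
#' @return A `null_distribution` with `level = "group"`.
#' @export
simulate_null_group <- function(single_null, group_size, n_sims = 10000L,
                                seed = 1L) {
  stopifnot(inherits(single_null, "null_distribution"))
  if (length(single_null$values) == 0L)
    stop("single_null is empty", call. = FALSE)
  group_size <- as.integer(group_size)
  n_sims <- as.integer(n_sims)
  if (group_size < 1L) stop("group_size must be >= 1", call. = FALSE)
  if (n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  src <- single_null$values
  chunk <- 50000L
  values <- numeric(n_sims)
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_sims) {
      k <- min(chunk, n_sims - done)
      draws <- matrix(sample(src, k * group_size, replace = TRUE),
                      nrow = k, ncol = group_size)
      values[done + seq_len(k)] <- rowMeans(draws)
      done <- done + k
    }
  })
  new_null_distribution(values, n_sims, single_null$reps_per_location, "group",
                        group_size = group_size, seed = seed,
                        allow_reflection = single_null$allow_reflection)
}

#' Empirical p-value against a Monte-Carlo null
#'
#' Proportion of null values strictly smaller than the observed distance
#' (one-tailed: small distances mean better-than-chance localization). Ties
#' with null values count as not smaller.
#'
#' @param null a `null_distribution`.
#' @param observed observed distance(s); vectorized.
#' @return numeric in \[0, 1\], same length as `observed`.
#' @export
empirical_p <- function(null, observed) {
  stopifnot(inherits(null, "null_distribution"))
  if (length(null$values) == 0L) stop("null distribution is empty", call. = FALSE)
  if (!all(is.finite(observed))) stop("observed must be finite", call. = FALSE)
  # values are sorted; left-open intervals make findInterval count strict <
  findInterval(observed, null$values, left.open = TRUE) / null$n_sims
}

#' Write / read a null-distribution cache
#'
#' Plain-text cache so large nulls are computed once: `#`-prefixed header
#' lines carry the provenance metadata, followed by one value per line.
#'
#' @param null a `null_distribution`.
#' @param path file path.
#' @return `write_null` returns `path` invisibly; `read_null` returns the
#'   `null_distribution`.
#' @export
write_null <- function(null, path) {
  stopifnot(inherits(null, "null_distribution"))
  hdr <- c(
    sprintf("# level=%s", null$level),
    sprintf("# n_sims=%d", null$n_sims),
    sprintf("# reps_per_location=%d", null$reps_per_location),
    sprintf("# group_size=%s", ifelse(is.na(null$group_size), "NA", null$group_size)),
    sprintf("# seed=%s", ifelse(is.na(null$seed), "NA", null$seed)),
    sprintf("# allow_reflection=%s", null$allow_reflection)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(formatC(null$values, format = "g", digits = 17), con)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  values <- as.numeric(grep("^#", lines, value = TRUE, invert = TRUE))
  new_null_distribution(
    values,
    n_sims = as.integer(meta$n_sims),
    reps_per_location = as.integer(meta$reps_per_location),
    level = meta$level,
    group_size = if (identical(meta$group_size, "NA")) NA_integer_ else as.integer(meta$group_size),
    seed = if (identical(meta$seed, "NA")) NA_integer_ else as.integer(meta$seed),
    allow_reflection = identical(meta$allow_reflection, "TRUE")
  )
}
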