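# Independent brute-force Procrustes minimizer: no SVD anywhere.
# Translation is removed by centering both configurations; for each rotation
# angle on a fine grid (optionally composed with a reflection), the scale is
# found by 1-D numerical minimization; the smallest RMS over the grid wins.
brute_procrustes_distance <- function(source, target, allow_reflection = TRUE,
                                      n_theta = 7200L, refine = TRUE) {
  X <- sweep(source, 2, colMeans(source))
  Y <- sweep(target, 2, colMeans(target))
  n <- nrow(Y)
  rms_at <- function(theta, flip) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    Xr <- X %*% R
    if (flip) Xr[, 2] <- -Xr[, 2]
    ss_of_s <- function(s) sum((s * Xr - Y)^2)
    opt <- stats::optimize(ss_of_s, interval = c(0, 100))
    sqrt(opt$objective / n)
  }
  flips <- if (allow_reflection) c(FALSE, TRUE) else FALSE
  thetas <- seq(-pi, pi, length.out = n_theta + 1L)[-1L]
  best <- Inf; best_theta <- NA; best_flip <- FALSE
  for (flip in flips) {
    vals <- vapply(thetas, rms_at, numeric(1), flip = flip)
    i <- which.min(vals)
    if (vals[i] < best) { best <- vals[i]; best_theta <- thetas[i]; best_flip <- flip }
  }
  if (refine) {
    step <- 2 * pi / n_theta
    opt <- stats::optimize(function(th) rms_at(th, best_flip),
                           interval = best_theta + c(-step, step))
    best <- min(best, opt$objective)
  }
  best
}

# random labelled configuration on roughly unit scale
random_config <- function(n_pts) {
  m <- cbind(x = stats::runif(n_pts), y = stats::runif(n_pts))
  rownames(m) <- as.character(seq_len(n_pts))
  m
}

similarity_transform <- function(points, theta = 0, s = 1, shift = c(0, 0),
                                 reflect = FALSE) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  out <- points %*% R
  if (reflect) out[, 2] <- -out[, 2]
  out <- sweep(s * out, 2, shift, "+")
  rownames(out) <- rownames(points)
  out
}
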