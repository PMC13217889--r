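#' Validate and normalize a 2-D point set
#'
#' Internal helper: coerces input to an n x 2 numeric matrix with row-name
#' labels, checking finiteness.
#'
#' @param points matrix-like with 2 columns (x, y), or data.frame.
#' @param labels optional character vector of location labels, recycled to
#'   rownames; if `NULL`, existing rownames (or `1..n`) are used.
#' @param what name used in error messages.
#' @return numeric matrix, n x 2, with rownames.
#' @keywords internal
as_points <- function(points, labels = NULL, what = "points") {
  m <- as.matrix(points)
  if (ncol(m) != 2L)
    stop(what, " must have exactly two columns (x, y)", call. = FALSE)
  storage.mode(m) <- "double"
  if (!all(is.finite(m)))
    stop(what, " contains non-finite coordinates", call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != nrow(m))
      stop("labels and ", what, " have different lengths", call. = FALSE)
    rownames(m) <- as.character(labels)
  } else if (is.null(rownames(m))) {
    rownames(m) <- as.character(seq_len(nrow(m)))
  }
  colnames(m) <- c("x", "y")
  m
}

#' Board geometry specification
#'
#' Describes the physical response surface: a square (or rectangular) board
#' with two registration landmarks, by convention the bottom-left and
#' bottom-right corners. The landmarks anchor the Bookstein coordinate frame:
#' the bottom-left corner maps to (0,0) and the bottom-right to (1,0), so x is
#' the medio-lateral axis and y the proximodistal axis of the held board.
#'
#' @param side_cm board edge length in cm (default 23, a 23 x 23 cm board).
#' @param landmark_a (x, y) of the first landmark in cm; maps to (0,0).
#' @param landmark_b (x, y) of the second landmark in cm; maps to (1,0).
#' @return An object of class `board_spec`.
#' @examples
#' board_spec()
#' @export
board_spec <- function(side_cm = 23,
                       landmark_a = c(0, 0),
                       landmark_b = c(side_cm, 0)) {
  stopifnot(is.numeric(side_cm), length(side_cm) == 1L, is.finite(side_cm))
  if (side_cm <= 0) stop("side_cm must be positive", call. = FALSE)
  landmark_a <- as.numeric(landmark_a)
  landmark_b <- as.numeric(landmark_b)
  if (length(landmark_a) != 2L || length(landmark_b) != 2L)
    stop("landmarks must be length-2 (x, y)", call. = FALSE)
  if (isTRUE(all.equal(landmark_a, landmark_b)))
    stop("landmarks must be distinct points", call. = FALSE)
  structure(
    list(side_cm = side_cm, landmark_a = landmark_a, landmark_b = landmark_b),
    class = "board_spec"
  )
}

#' @export
print.board_spec <- function(x, ...) {
  cat(sprintf("Board: %g x %g cm; landmarks (%g, %g) -> (0,0), (%g, %g) -> (1,0)\n",
              x$side_cm, x$side_cm,
              x$landmark_a[1], x$landmark_a[2],
              x$landmark_b[1], x$landmark_b[2]))
  invisible(x)
}

#' Bookstein two-point registration
#'
#' Maps a 2-D configuration into Bookstein shape coordinates: the similarity
#' transform (translation, rotation, uniform scaling) that sends
#' `landmark_a` to (0,0) and `landmark_b` to (1,0), with the second axis
#' orthogonal to the first. This removes position, orientation and size,
#' leaving shape coordinates in which, for the board convention used here,
#' x is the medio-lateral axis and y the proximodistal axis.
#'
#' @param points point set (n x 2 matrix-like); see [as_points()].
#' @param landmark_a,landmark_b distinct (x, y) landmark positions in the
#'   same units as `points`.
#' @return n x 2 matrix of registered coordinates, labels preserved.
#' @examples
#' # board centre of a 23 cm board registers to (0.5, 0.5)
#' bookstein_register(rbind(c(11.5, 11.5)), c(0, 0), c(23, 0))
#' @export
bookstein_register <- function(points, landmark_a, landmark_b) {
  m <- as_points(points)
  a <- as.numeric(landmark_a)
  b <- as.numeric(landmark_b)
  if (length(a) != 2L || length(b) != 2L)
    stop("landmarks must be length-2 (x, y)", call. = FALSE)
  if (!all(is.finite(c(a, b))))
    stop("landmarks must be finite", call. = FALSE)
  if (isTRUE(all.equal(a, b)))
    stop("landmarks must be distinct points", call. = FALSE)
  # complex-plane form: z -> (z - a) / (b - a)
  z <- complex(real = m[, 1], imaginary = m[, 2])
  base <- complex(real = b[1] - a[1], imaginary = b[2] - a[2])
  w <- (z - complex(real = a[1], imaginary = a[2])) / base
  out <- cbind(x = Re(w), y = Im(w))
  rownames(out) <- rownames(m)
  out
}

#' Construct the stimulus grid
#'
#' Builds the layout of tap locations: a regular rows x cols grid of marks
#' with equal spacing and equal outer margins, centred on the board, together
#' with its Bookstein-registered coordinates (board corners as landmarks).
#' The default is the 6 x 6 grid of 36 locations at 3.3 cm spacing on the
#' 23 cm board. The nominal layout (margins equal to the spacing) overfills a
#' 23 cm board by 1 mm; the grid is therefore centred and the discrepancy
#' absorbed into the margins, with a 2% slack allowed before the geometry is
#' rejected as not fitting.
#'
#' @param board a [board_spec()].
#' @param rows,cols grid dimensions (each >= 2).
#' @param spacing_cm inter-mark distance in cm.
#' @return An object of class `stimulus_grid` with elements `rows`, `cols`,
#'   `spacing_cm`, `board`, `labels`, `points_cm` (board coordinates) and
#'   `points` (Bookstein coordinates). Rows are labelled `r<i>c<j>`, row 1 /
#'   column 1 at the bottom-left (proximal, medial) corner.
#' @examples
#' g <- build_grid()
#' nrow(g$points)  # 36
#' @export
build_grid <- function(board = board_spec(), rows = 6L, cols = 6L,
                       spacing_cm = 3.3) {
  stopifnot(inherits(board, "board_spec"))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("rows and cols must each be >= 2", call. = FALSE)
  if (!is.finite(spacing_cm) || spacing_cm <= 0)
    stop("spacing_cm must be positive", call. = FALSE)
  side <- board$side_cm
  span_x <- (cols - 1L) * spacing_cm
  span_y <- (rows - 1L) * spacing_cm
  # nominal footprint counts outer margins equal to the spacing
  slack <- 1.02
  if (span_x + 2 * spacing_cm > side * slack ||
      span_y + 2 * spacing_cm > side * slack)
    stop("grid does not fit on the board (spacing x (rows+1) exceeds the side by more than 2%)",
         call. = FALSE)
  x0 <- (side - span_x) / 2
  y0 <- (side - span_y) / 2
  xs <- x0 + (seq_len(cols) - 1L) * spacing_cm
  ys <- y0 + (seq_len(rows) - 1L) * spacing_cm
  # row-major, row 1 at the bottom (proximal edge)
  pts <- cbind(x = rep(xs, times = rows), y = rep(ys, each = cols))
  labels <- sprintf("r%dc%d", rep(seq_len(rows), each = cols),
                    rep(seq_len(cols), times = rows))
  rownames(pts) <- labels
  bk <- bookstein_register(pts, board$landmark_a, board$landmark_b)
  structure(
    list(rows = rows, cols = cols, spacing_cm = spacing_cm, board = board,
         labels = labels, points_cm = pts, points = bk),
    class = "stimulus_grid"
  )
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("Stimulus grid: %d x %d = %d locations, %g cm spacing on a %g cm board\n",
              x$rows, x$cols, length(x$labels), x$spacing_cm, x$board$side_cm))
  cat(sprintf("Bookstein x range [%.4f, %.4f], y range [%.4f, %.4f]\n",
              min(x$points[, 1]), max(x$points[, 1]),
              min(x$points[, 2]), max(x$points[, 2])))
  invisible(x)
}

#' Least-squares Procrustes superimposition of two point sets
#'
#' Finds the similarity transform (translation, rotation, uniform scaling,
#' and optionally reflection) of `source` that minimizes the sum of squared
#' distances to the homologous points of `target`, via the closed-form
#' orthogonal-Procrustes solution (SVD of the 2 x 2 cross-covariance). The
#' residual is summarized as the Procrustes distance: the root mean square of
#' the distances between homologous points after alignment, in the units of
#' `target` (Bookstein units throughout this package). Perfectly matching
#' configurations give distance 0.
#'
#' @param source,target point sets (n x 2, matching labels). If both carry
#'   labels, `source` rows are matched to `target` by label.
#' @param allow_reflection if `TRUE` (default) the optimal orthogonal map may
#'   include a reflection; if `FALSE` it is constrained to a pure rotation.
#' @return An object of class `procrustes_fit`: list with `distance`, `scale`,
#'   `rotation_deg` (counter-clockwise), `translation`, `reflected`, `aligned`
#'   (transformed source) and `target`.
#' @examples
#' g <- build_grid()
#' fit <- procrustes_align(g$points, g$points)
#' fit$distance  # 0
#' @export
procrustes_align <- function(source, target, allow_reflection = TRUE) {
  X <- as_points(source, what = "source")
  Y <- as_points(target, what = "target")
  if (nrow(X) != nrow(Y))
    stop("source and target must have the same number of points", call. = FALSE)
  if (nrow(X) < 2L)
    stop("need at least 2 points to align", call. = FALSE)
  if (!setequal(rownames(X), rownames(Y)))
    stop("source and target labels do not match", call. = FALSE)
  X <- X[rownames(Y), , drop = FALSE]

  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ssx <- sum(Xc^2); ssy <- sum(Yc^2)
  if (ssx <= .Machine$double.eps * nrow(X))
    stop("degenerate configuration: all source points coincide", call. = FALSE)
  if (ssy <= .Machine$double.eps * nrow(Y))
    stop("degenerate configuration: all target points coincide", call. = FALSE)

  M <- crossprod(Xc, Yc)                  # 2 x 2 cross-covariance
  sv <- svd(M)
  sgn <- sign(det(sv$u %*% t(sv$v)))      # -1 if unconstrained optimum reflects
  if (allow_reflection || sgn >= 0) {
    R <- sv$u %*% t(sv$v)
    trace_sigma <- sum(sv$d)
    reflected <- sgn < 0
  } else {
    # restrict to rotations: flip the direction of the smallest singular value
    D <- diag(c(1, -1))
    R <- sv$u %*% D %*% t(sv$v)
    trace_sigma <- sv$d[1] - sv$d[2]
    reflected <- FALSE
  }
  s <- trace_sigma / ssx
  aligned <- s * (Xc %*% R)
  aligned <- sweep(aligned, 2, cy, "+")
  rownames(aligned) <- rownames(Y)
  colnames(aligned) <- c("x", "y")
  resid2 <- rowSums((aligned - Y)^2)
  # row-vector convention: x' = x R, counter-clockwise angle from R
  rot <- atan2(R[1, 2], R[1, 1]) * 180 / pi
  structure(
    list(distance = sqrt(mean(resid2)),
         scale = s,
         rotation_deg = rot,
         translation = cy - as.numeric(s * (cx %*% R)),
         reflected = reflected,
         aligned = aligned,
         target = Y),
    class = "procrustes_fit"
  )
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes fit: distance %.5f, scale %.4f, rotation %.2f deg%s\n",
              x$distance, x$scale, x$rotation_deg,
              if (x$reflected) ", reflected" else ""))
  invisible(x)
}

#' Procrustes distance between a perceptual map and the stimulus grid
#'
#' Convenience wrapper: superimposes a map of mean judged locations onto the
#' grid's Bookstein coordinates and returns the root-mean-square residual
#' (the Procrustes distance, in Bookstein units).
#'
#' @param judged a `perceptual_map` (see [build_map()]) or an n x 2 matrix of
#'   per-location means labelled like the grid.
#' @param grid a [build_grid()] object.
#' @param allow_reflection passed to [procrustes_align()].
#' @return scalar Procrustes distance (>= 0).
#' @export
procrustes_distance <- function(judged, grid, allow_reflection = TRUE) {
  stopifnot(inherits(grid, "stimulus_grid"))
  m <- if (inherits(judged, "perceptual_map")) judged$means else judged
  procrustes_align(m, grid$points, allow_reflection = allow_reflection)$distance
}
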