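#' Point cloud constructor
#'
#' A point cloud is an N x 3 numeric matrix of x, y, z coordinates in
#' metres with columns named `x`, `y`, `z` and class `point_cloud`. All
#' geometric operations in the package consume and produce this carrier.
#'
#' @param coords numeric matrix (or data.frame) with three columns.
#' @return a `point_cloud` matrix.
#' @export
point_cloud <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) .invalid_argument("a point cloud needs exactly 3 columns")
  if (!is.numeric(coords)) .invalid_argument("coordinates must be numeric")
  if (anyNA(coords) || any(!is.finite(coords)))
    .invalid_argument("coordinates must be finite")
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- NULL
  class(coords) <- c("point_cloud", class(matrix()))
  coords
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points\n", nrow(x)))
  rng <- apply(x, 2, range)
  cat(sprintf("  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

.as_cloud_matrix <- function(cloud) {
  m <- unclass(cloud)
  if (!is.matrix(m) || ncol(m) != 3L) .invalid_argument("not a point cloud")
  m
}

#' Centre a cloud and scale it to the unit ball
#'
#' Subtracts the centroid and divides by the maximum point norm so that
#' the farthest point sits exactly on the unit sphere. Idempotent; a
#' single-point cloud is centred but not rescaled.
#'
#' @param cloud a `point_cloud`.
#' @return the normalized `point_cloud`.
#' @export
normalize_unit_ball <- function(cloud) {
  m <- .as_cloud_matrix(cloud)
  if (nrow(m) < 1L) .invalid_argument("empty cloud")
  ctr <- colMeans(m)
  m <- sweep(m, 2, ctr)
  r <- sqrt(max(rowSums(m^2)))
  if (r > 0) m <- m / r
  point_cloud(m)
}

#' Resample a cloud to a fixed size
#'
#' Draws a uniformly random subset of `n` points without replacement when
#' the cloud has at least `n` points, and with replacement otherwise, so
#' the output always has exactly `n` rows. Deterministic under `seed`.
#'
#' @param cloud a `point_cloud`.
#' @param n target number of points.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `cloud` (the resampled `point_cloud`) and `idx`
#'   (the drawn row indices, usable to carry labels along).
#' @export
resample_fixed <- function(cloud, n, seed = NULL) {
  m <- .as_cloud_matrix(cloud)
  if (nrow(m) < 1L) .invalid_argument("empty cloud")
  if (n < 1L) .invalid_argument("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(m), n, replace = n > nrow(m))
  list(cloud = point_cloud(m[idx, , drop = FALSE]), idx = idx)
}

#' Training-time augmentation: random vertical rotation plus jitter
#'
#' Rotates the cloud by an angle drawn uniformly in \[0, 2pi) about the
#' vertical (z) axis, then adds i.i.d. Gaussian jitter to every
#' coordinate. The default jitter standard deviation of 0.02 is in
#' unit-ball units and is meant for clouds that have already been
#' normalized with [normalize_unit_ball()].
#'
#' @param cloud a `point_cloud`.
#' @param jitter_sd standard deviation of the per-coordinate jitter.
#' @param rotate apply the random rotation.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return the augmented `point_cloud`.
#' @export
augment_cloud <- function(cloud, jitter_sd = 0.02, rotate = TRUE, seed = NULL) {
  m <- .as_cloud_matrix(cloud)
  if (!is.null(seed)) set.seed(seed)
  if (rotate) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    m <- m %*% R
  }
  if (jitter_sd > 0) m <- m + rnorm(length(m), 0, jitter_sd)
  point_cloud(m)
}

#' Drop duplicate frames from an ordered sequence of clouds
#'
#' Adjacent frames with the same point count are treated as duplicates;
#' the first frame of each run is kept.
#'
#' @param frames list of `point_cloud` objects in acquisition order.
#' @return the deduplicated list.
#' @export
drop_duplicate_frames <- function(frames) {
  if (length(frames) == 0L) return(frames)
  n <- vapply(frames, nrow, integer(1))
  keep <- c(TRUE, n[-1] != n[-length(n)])
  frames[keep]
}

# Rotate a cloud about the vertical axis by theta (radians), then translate.
.rigid_xy <- function(m, theta = 0, tx = 0, ty = 0) {
  if (theta != 0) {
    R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
    m <- m %*% R
  }
  m[, 1] <- m[, 1] + tx
  m[, 2] <- m[, 2] + ty
  m
}
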