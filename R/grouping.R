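#' Farthest point sampling
#'
#' Greedy maximin subset selection: starting from `start`, each new index
#' maximizes its distance to the already selected set, which spreads the
#' selected centroids evenly over the cloud. Ties are broken by the lowest
#' index, so the result is deterministic given the start point.
#'
#' @param cloud a `point_cloud`.
#' @param m number of points to select (`1 <= m <= N`).
#' @param start 1-based index of the first selected point; `"random"`
#'   draws it from the current RNG state.
#' @return integer vector of `m` selected row indices.
#' @export
farthest_point_sampling <- function(cloud, m, start = 1L) {
  x <- .as_cloud_matrix(cloud)
  if (m < 1 || m > nrow(x)) .invalid_argument("m must be in [1, N]")
  if (identical(start, "random")) start <- sample.int(nrow(x), 1)
  fps_cpp(x, as.integer(m), as.integer(start))
}

#' Adaptive global radius of a sampled point set
#'
#' The farthest distance between the sampled centroids, i.e. their maximum
#' pairwise Euclidean distance. Used as the global grouping radius of the
#' local-global grouping strategy; because it is recomputed per sample
#' (and per abstraction level), the global neighbourhood adapts itself to
#' each input cloud.
#'
#' @param sampled a `point_cloud` (or matrix) of at least two points,
#'   typically the centroids selected by [farthest_point_sampling()].
#' @return the maximum pairwise distance (same units as the coordinates).
#' @export
compute_rfst <- function(sampled) {
  x <- if (inherits(sampled, "point_cloud")) .as_cloud_matrix(sampled)
       else as.matrix(sampled)
  if (nrow(x) < 2) .invalid_argument("need at least two sampled points")
  max_pairwise_dist_cpp(x)
}

#' Ball-query neighbourhoods
#'
#' For each centroid, returns up to `cap` indices of cloud points within
#' `radius`, in ascending input-index order. Groups with fewer than `cap`
#' members are padded by repeating the first found index; a centroid with
#' no point in range is given its nearest neighbour, repeated.
#'
#' @param cloud a `point_cloud`.
#' @param centroids a `point_cloud`/matrix of query centres.
#' @param radius ball radius (> 0).
#' @param cap maximum group size (>= 1).
#' @return integer matrix (centroids x cap) of 1-based indices.
#' @export
ball_query <- function(cloud, centroids, radius, cap) {
  x <- .as_cloud_matrix(cloud)
  if (nrow(x) < 1) .invalid_argument("empty cloud")
  if (radius <= 0) .invalid_argument("radius must be positive")
  if (cap < 1) .invalid_argument("cap must be >= 1")
  ctr <- if (inherits(centroids, "point_cloud")) .as_cloud_matrix(centroids)
         else matrix(as.numeric(centroids), ncol = 3)
  ball_query_cpp(x, ctr, radius, as.integer(cap))
}

#' Grouping configuration for one set-abstraction level
#'
#' Radii are in unit-ball units; the symbolic adaptive global radius is
#' written `NA` and is resolved at run time from the farthest pairwise
#' distance of the level's own centroids. A single numeric radius is the
#' single-scale grouping (SSG), several numeric radii the multi-scale
#' grouping (MSG), and numeric radii plus the trailing `NA` the
#' local-global grouping (LGG).
#'
#' @param radii numeric vector, strictly increasing among numeric
#'   entries; a trailing `NA` denotes the adaptive global radius.
#' @param caps integer vector of per-radius neighbour caps (>= 1), same
#'   length as `radii`.
#' @return a `grouping_config` list.
#' @export
grouping_config <- function(radii, caps) {
  if (length(radii) != length(caps))
    .invalid_argument("radii and caps must have the same length")
  num <- radii[!is.na(radii)]
  if (any(num <= 0)) .invalid_argument("numeric radii must be positive")
  if (is.unsorted(num, strictly = TRUE))
    .invalid_argument("numeric radii must be strictly increasing")
  if (any(is.na(radii[-length(radii)])))
    .invalid_argument("the global radius must be the last entry")
  if (any(caps < 1)) .invalid_argument("caps must be >= 1")
  structure(list(radii = as.numeric(radii), caps = as.integer(caps)),
            class = "grouping_config")
}

#' Group neighbourhoods with relative coordinates
#'
#' For every centroid and every radius of the grouping configuration
#' (numeric radii first, then the adaptive global radius when present),
#' builds a padded ball-query neighbourhood and the members' coordinates
#' relative to the centroid. This is the geometric half of a
#' set-abstraction level; the shared MLP and max-pooling consume its
#' output.
#'
#' @param cloud a `point_cloud`.
#' @param centroid_idx integer indices of the centroids (rows of `cloud`),
#'   e.g. from [farthest_point_sampling()].
#' @param cfg a [grouping_config()].
#' @param rfst the adaptive global radius; required when `cfg` contains
#'   the symbolic global radius, ignored otherwise.
#' @return list with one element per radius: `radius` (resolved numeric
#'   value), `cap`, `idx` (centroids x cap index matrix) and `rel`
#'   ((centroids*cap) x 3 matrix of relative coordinates, the cap rows of
#'   each centroid contiguous).
#' @export
group_neighborhoods <- function(cloud, centroid_idx, cfg, rfst = NULL) {
  x <- .as_cloud_matrix(cloud)
  stopifnot(inherits(cfg, "grouping_config"))
  cent <- x[centroid_idx, , drop = FALSE]
  m <- nrow(cent)
  lapply(seq_along(cfg$radii), function(b) {
    r <- cfg$radii[b]
    if (is.na(r)) {
      if (is.null(rfst))
        .invalid_argument("rfst must be supplied for the global radius")
      r <- rfst
    }
    cap <- cfg$caps[b]
    idx <- ball_query_cpp(x, cent, r, cap)
    flat <- as.vector(t(idx))
    rel <- x[flat, , drop = FALSE] - cent[rep(seq_len(m), each = cap), ,
                                          drop = FALSE]
    list(radius = r, cap = cap, idx = idx, rel = rel)
  })
}

#' Dump grouped neighbourhoods to JSON for inspection
#'
#' @param groups result of [group_neighborhoods()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_neighborhoods <- function(groups, path) {
  out <- lapply(groups, function(g)
    list(radius = g$radius, cap = g$cap, idx = g$idx))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
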