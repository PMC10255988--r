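#' Body-shape parameters of one pig
#'
#' Five lengths parameterize the synthetic back surface: chest width (CW),
#' hip width (HW), chest height (CH), hip height (HH) and body length
#' (BL), all in centimetres as a tape measure would record them. Body
#' weight is carried as metadata only and does not shape the geometry.
#'
#' @param chest_width,hip_width transverse widths at the chest and hip (cm).
#' @param chest_height,hip_height back heights above ground at the chest
#'   and hip (cm).
#' @param body_length chest-to-hip length along the spine (cm).
#' @param identity 0-based class index, unique within a roster.
#' @param weight optional body weight (kg), metadata only.
#' @return a `pig_shape` list (lengths converted to metres).
#' @export
pig_shape <- function(chest_width, hip_width, chest_height, hip_height,
                      body_length, identity = 0L, weight = NA_real_) {
  lens <- c(chest_width, hip_width, chest_height, hip_height, body_length)
  if (any(!is.finite(lens)) || any(lens <= 0))
    .invalid_argument("all body lengths must be positive")
  structure(list(cw = chest_width / 100, hw = hip_width / 100,
                 ch = chest_height / 100, hh = hip_height / 100,
                 bl = body_length / 100,
                 identity = as.integer(identity), weight = weight),
            class = "pig_shape")
}

#' Bundled ten-pig roster
#'
#' Body measurements of ten crossbred fattening pigs (around 60-90 kg)
#' used as the default identification roster. Pigs 1, 2, 6 and 7 are
#' similar in size, as are pigs 3, 4 and 5, and pigs 8, 9 and 10, which
#' makes the individuals deliberately hard to tell apart by bulk size
#' alone.
#'
#' @param ids which pigs to include (1-based positions in the roster).
#' @return a list of [pig_shape()] objects with identities `0..K-1`.
#' @export
pig_roster <- function(ids = 1:10) {
  bw <- c(89.0, 87.5, 75.0, 76.5, 77.5, 88.0, 89.5, 63.5, 69.0, 60.5)
  cw <- c(30.6, 32.1, 30.3, 27.7, 29.6, 31.5, 30.56, 25.9, 27.6, 25.9)
  hw <- c(29.0, 30.1, 25.5, 28.1, 26.0, 28.5, 31.28, 23.8, 23.6, 28.0)
  ch <- c(67.5, 66.4, 56.6, 57.5, 57.8, 63.6, 60.9, 53.2, 54.4, 52.1)
  hh <- c(68.1, 68.3, 56.9, 57.9, 58.9, 65.6, 62.7, 55.3, 55.7, 56.2)
  bl <- c(97.7, 95.4, 82.8, 86.8, 86.6, 96.7, 90.6, 85.9, 89.2, 77.4)
  stopifnot(all(ids %in% 1:10))
  lapply(seq_along(ids), function(k) {
    i <- ids[k]
    pig_shape(cw[i], hw[i], ch[i], hh[i], bl[i], identity = k - 1L,
              weight = bw[i])
  })
}

#' Scene generation settings
#'
#' @param ground_extent side length of the square ground plane (m).
#' @param point_density sampled points per square metre of surface. Real
#'   overhead depth frames are roughly an order of magnitude denser;
#'   clouds are resampled to a fixed size before modelling, so density
#'   mainly controls generation cost.
#' @param noise_sd Gaussian sensor noise, per coordinate (m).
#' @param crack_count number of thin deletion stripes emulating the
#'   missing-data cracks a structured-light sensor leaves at
#'   high-curvature ridges of the back.
#' @param include_head attach a head (labelled as background, like the
#'   ground) at the chest end.
#' @param surface_detail relative amplitude of the per-identity surface
#'   relief of the back shell (see [make_back_surface()]).
#' @param seed integer seed driving all sampling in the scene.
#' @return a `scene_config` list.
#' @export
scene_config <- function(ground_extent = 2, point_density = 2000,
                         noise_sd = 0.003, crack_count = 2,
                         include_head = TRUE, surface_detail = 0.02,
                         seed = 1L) {
  if (point_density <= 0) .invalid_argument("point_density must be positive")
  if (noise_sd < 0) .invalid_argument("noise_sd must be >= 0")
  if (crack_count < 0) .invalid_argument("crack_count must be >= 0")
  structure(list(ground_extent = ground_extent,
                 point_density = point_density, noise_sd = noise_sd,
                 crack_count = as.integer(crack_count),
                 include_head = isTRUE(include_head),
                 surface_detail = surface_detail,
                 seed = as.integer(seed)), class = "scene_config")
}

# Half-width (m) of the body at fractional position t in [0, 1]
# (t = 0 chest end, t = 1 hip end).
.half_width <- function(p, t) ((1 - t) * p$cw + t * p$hw) / 2

# Apex height (m) of the back at fractional position t.
.apex_height <- function(p, t) (1 - t) * p$ch + t * p$hh

# Superellipse exponent of the transverse cross-section: > 2 gives the
# flat-topped, round-shouldered profile of a well-fed pig.
.XSECT_EXP <- 2.5

.shell_z <- function(p, t, y) {
  w <- .half_width(p, t)
  u <- pmin(abs(y) / w, 1)
  .apex_height(p, t) * (1 - u^.XSECT_EXP)^(1 / .XSECT_EXP)
}

# Stable per-individual surface relief: a low-order harmonic height
# modulation whose coefficients are a deterministic function of the
# identity. Emulates the idiosyncratic muscle/fat distribution that makes
# one animal's back differ from another's beyond the tape-measure
# dimensions; without it, same-breed pigs are near scale-copies of each
# other and carry almost no identity signal once clouds are normalized to
# the unit ball. Bounded: |result| <= 1.
.surface_relief <- function(id, t, u) {
  s <- 0
  tot <- 0
  for (i in 1:3) for (j in 0:1) {
    a <- sin(1 + id * 12.9898 + i * 78.233 + j * 37.719)
    ph <- 3.883 * id + 2.1 * i + 0.7 * j
    s <- s + a * cos(2 * pi * i * t + ph) * cos(pi * j * u / 2)
    tot <- tot + abs(a)
  }
  s / tot
}

#' Sample the top shell of a pig's back
#'
#' Points are sampled uniformly over the body footprint and lifted onto a
#' tapered, convex-upward shell: transverse cross-sections are
#' superellipse arcs whose half-width interpolates chest to hip width and
#' whose apex height interpolates chest to hip height along the spine.
#' The chest end sits at x = 0, the hip end at x = body length; only the
#' top-visible surface (what an overhead camera sees) is produced.
#'
#' @param params a [pig_shape()].
#' @param density points per square metre of footprint.
#' @param seed integer seed.
#' @param detail relative amplitude of the per-identity surface relief
#'   (0 disables it); the height field is scaled by at most `1 + detail`.
#' @return a `point_cloud`.
#' @export
make_back_surface <- function(params, density = 2000, seed = 1L,
                              detail = 0.02) {
  stopifnot(inherits(params, "pig_shape"))
  if (density <= 0) .invalid_argument("density must be positive")
  set.seed(seed)
  area <- params$bl * (params$cw + params$hw) / 2  # integral of 2*w(t) dx
  n <- max(4L, round(density * area))
  # x with density proportional to local width (uniform over the footprint)
  wmax <- max(params$cw, params$hw) / 2
  t <- numeric(0)
  while (length(t) < n) {
    cand <- runif(2 * n)
    acc <- runif(2 * n) * wmax <= .half_width(params, cand)
    t <- c(t, cand[acc])
  }
  t <- t[seq_len(n)]
  w <- .half_width(params, t)
  y <- runif(n, -w, w)
  z <- .shell_z(params, t, y)
  if (detail > 0)
    z <- z * (1 + detail * .surface_relief(params$identity, t, y / w))
  point_cloud(cbind(t * params$bl, y, z))
}

# Head shell: a half-ellipsoid cap attached at the chest end, protruding
# forward (negative x in body frame, chest at x = 0). Returns a matrix.
.head_dims <- function(p) {
  list(len = 0.28 * p$bl, hw = 0.30 * p$cw, base = 0.45 * p$ch,
       rise = 0.38 * p$ch)
}

.make_head <- function(p, density) {
  hd <- .head_dims(p)
  n <- max(4L, round(density * (pi / 2) * hd$len * hd$hw))
  s <- y <- numeric(0)
  while (length(s) < n) {
    cs <- runif(2 * n); cy <- runif(2 * n, -hd$hw, hd$hw)
    ok <- cs^2 + (cy / hd$hw)^2 <= 1
    s <- c(s, cs[ok]); y <- c(y, cy[ok])
  }
  s <- s[seq_len(n)]; y <- y[seq_len(n)]
  z <- hd$base + hd$rise * sqrt(pmax(0, 1 - s^2 - (y / hd$hw)^2))
  cbind(-s * hd$len, y, z)
}

# TRUE for (x, y) rows inside the body (+ head) footprint, body frame
# (chest at x = 0, spine along +x).
.in_footprint <- function(p, xy, include_head) {
  x <- xy[, 1]; y <- xy[, 2]
  t <- x / p$bl
  body <- t >= 0 & t <= 1 & abs(y) <= .half_width(p, pmin(pmax(t, 0), 1))
  if (include_head) {
    hd <- .head_dims(p)
    s <- -x / hd$len
    body <- body | (s >= 0 & s <= 1 & (s^2 + (y / hd$hw)^2) <= 1)
  }
  body
}

#' Generate one labelled overhead scene
#'
#' Assembles a ground plane at height 0, the pig's back shell placed above
#' it, and optionally a head, then applies the acquisition artifacts the
#' segmentation stage has to live with: ground points inside the vertical
#' projection of the animal are removed (the occlusion shadow an overhead
#' sensor produces), thin crack stripes are deleted along the back's
#' ridge, and Gaussian positional noise is added everywhere. Back points
#' are labelled 1; ground and head points are labelled 0.
#'
#' @param params a [pig_shape()].
#' @param cfg a [scene_config()].
#' @param pose optional list `(theta, tx, ty)`: rotation about the
#'   vertical axis (radians) and horizontal translation (m) applied to the
#'   animal within the scene.
#' @return a `synthetic_scene`: list with `cloud`, `part_labels` (0/1),
#'   `identity` and `params`.
#' @export
make_scene <- function(params, cfg, pose = list(theta = 0, tx = 0, ty = 0)) {
  stopifnot(inherits(params, "pig_shape"), inherits(cfg, "scene_config"))
  g <- cfg$ground_extent
  hd_len <- if (cfg$include_head) .head_dims(params)$len else 0
  span <- params$bl + hd_len
  if (span >= g || max(params$cw, params$hw) >= g)
    .invalid_argument("animal footprint larger than the ground extent")
  set.seed(cfg$seed)

  back <- .as_cloud_matrix(make_back_surface(params, cfg$point_density,
                                             seed = cfg$seed + 1L,
                                             detail = cfg$surface_detail))
  # cracks: thin stripes parallel to the spine near the ridge, deleted
  if (cfg$crack_count > 0) {
    keep <- rep(TRUE, nrow(back))
    wmid <- .half_width(params, 0.5)
    for (k in seq_len(cfg$crack_count)) {
      yc <- runif(1, -0.3, 0.3) * wmid
      wc <- runif(1, 0.01, 0.02)
      x0 <- runif(1, 0, params$bl)
      len <- runif(1, 0.2, 0.4) * params$bl
      keep <- keep & !(abs(back[, 2] - yc) <= wc / 2 &
                       back[, 1] >= x0 & back[, 1] <= x0 + len)
    }
    back <- back[keep, , drop = FALSE]
  }
  animal <- back
  nback <- nrow(back)
  if (cfg$include_head) animal <- rbind(animal, .make_head(params,
                                                           cfg$point_density))
  # centre the body in its own frame, then apply the pose
  animal[, 1] <- animal[, 1] - params$bl / 2
  animal <- .rigid_xy(animal, pose$theta, pose$tx, pose$ty)
  if (max(abs(animal[, 1])) >= g / 2 || max(abs(animal[, 2])) >= g / 2)
    .invalid_argument("posed animal does not fit on the ground plane")

  # ground plane with the occlusion shadow cut out
  ng <- round(cfg$point_density * g^2)
  gx <- runif(ng, -g / 2, g / 2)
  gy <- runif(ng, -g / 2, g / 2)
  # undo the pose to test the footprint in the body frame
  ca <- cos(pose$theta); sa <- sin(pose$theta)
  ux <- gx - pose$tx; uy <- gy - pose$ty
  bx <- ca * ux - sa * uy + params$bl / 2
  by <- sa * ux + ca * uy
  shadow <- .in_footprint(params, cbind(bx, by), cfg$include_head)
  ground <- cbind(gx[!shadow], gy[!shadow], 0)

  cloud <- rbind(animal, ground)
  labels <- c(rep(1L, nback), rep(0L, nrow(animal) - nback),
              rep(0L, nrow(ground)))
  if (cfg$noise_sd > 0)
    cloud <- cloud + rnorm(length(cloud), 0, cfg$noise_sd)
  structure(list(cloud = point_cloud(cloud), part_labels = labels,
                 identity = params$identity, params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: identity %d, %d points (%d back, %d background)\n",
              x$identity, length(x$part_labels), sum(x$part_labels == 1L),
              sum(x$part_labels == 0L)))
  invisible(x)
}

#' Generate a labelled multi-pig scan dataset
#'
#' Produces `frames_per_pig` scenes per roster entry with per-frame pose
#' jitter (rotation uniform in +/-15 degrees about the vertical axis,
#' translation uniform in +/-0.1 m per horizontal axis) and a stratified
#' train/validation split at ratio 3:1. Fully deterministic under
#' `cfg$seed`.
#'
#' @param roster non-empty list of [pig_shape()] objects.
#' @param frames_per_pig scenes per identity (>= 1).
#' @param cfg a [scene_config()]; its seed drives everything.
#' @return a `scan_dataset`: list with `scenes` (list of
#'   `synthetic_scene`), `identity` (integer vector), `split` (0 train,
#'   1 validation), `roster` and `cfg`.
#' @export
make_dataset <- function(roster, frames_per_pig, cfg) {
  if (length(roster) == 0L) .invalid_argument("roster must be non-empty")
  if (frames_per_pig < 1L) .invalid_argument("frames_per_pig must be >= 1")
  stopifnot(all(vapply(roster, inherits, logical(1), "pig_shape")))
  set.seed(cfg$seed)
  K <- length(roster)
  total <- K * frames_per_pig
  frame_seed <- sample.int(2^31 - 2, total)
  theta <- runif(total, -15, 15) * pi / 180
  tx <- runif(total, -0.1, 0.1)
  ty <- runif(total, -0.1, 0.1)
  split_perm <- lapply(seq_len(K), function(k) sample.int(frames_per_pig))
  scenes <- vector("list", total)
  identity <- integer(total)
  split <- integer(total)
  i <- 0L
  for (k in seq_len(K)) {
    ntrain <- round(0.75 * frames_per_pig)
    for (f in seq_len(frames_per_pig)) {
      i <- i + 1L
      fcfg <- cfg
      fcfg$seed <- frame_seed[i]
      scenes[[i]] <- make_scene(roster[[k]], fcfg,
                                pose = list(theta = theta[i], tx = tx[i],
                                            ty = ty[i]))
      identity[i] <- roster[[k]]$identity
      split[i] <- if (split_perm[[k]][f] <= ntrain) 0L else 1L
    }
  }
  structure(list(scenes = scenes, identity = identity, split = split,
                 roster = roster, cfg = cfg), class = "scan_dataset")
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat(sprintf("scan_dataset: %d scenes, %d identities (%d train / %d val)\n",
              length(x$scenes), length(unique(x$identity)),
              sum(x$split == 0L), sum(x$split == 1L)))
  invisible(x)
}

#' Save or load a scan dataset archive
#'
#' Datasets are serialized with R's native serialization; the roster can
#' additionally be exported to JSON and individual scenes to labelled PLY
#' with [write_cloud()].
#'
#' @param dataset a `scan_dataset`.
#' @param path file path.
#' @return `load_dataset` returns the `scan_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "scan_dataset"))
  saveRDS(dataset, path, version = 3)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "scan_dataset")) .format_error("not a scan_dataset archive")
  x
}

#' Read or write a roster JSON file
#'
#' The JSON roster lists one record per pig with the five body lengths in
#' centimetres, the 0-based identity and optionally the weight.
#'
#' @param roster list of [pig_shape()] objects.
#' @param path file path.
#' @return `read_roster` returns a list of [pig_shape()] objects.
#' @export
write_roster <- function(roster, path) {
  recs <- lapply(roster, function(p)
    list(chest_width = p$cw * 100, hip_width = p$hw * 100,
         chest_height = p$ch * 100, hip_height = p$hh * 100,
         body_length = p$bl * 100, identity = p$identity,
         weight = p$weight))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("chest_width", "hip_width", "chest_height", "hip_height",
            "body_length", "identity")
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    missing <- setdiff(need, names(r))
    if (length(missing) > 0)
      .format_error(sprintf("roster record %d lacks field(s): %s", i,
                            paste(missing, collapse = ", ")))
    pig_shape(r$chest_width, r$hip_width, r$chest_height, r$hip_height,
              r$body_length, identity = r$identity,
              weight = if (is.null(r$weight)) NA_real_ else r$weight)
  })
}
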