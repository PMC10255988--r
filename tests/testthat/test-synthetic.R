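# The synthetic overhead-scan generator: back-surface geometry, scene
# assembly with occlusion shadow and artifacts, dataset splits, and the
# depth rendering roundtrip.

test_that("back surface recovers the prescribed body dimensions", {
  p1 <- pig_roster(1)[[1]]  # BL 97.7 cm
  cl <- unclass(make_back_surface(p1, density = 6000, seed = 2, detail = 0))
  expect_equal(diff(range(cl[, 1])), 0.977, tolerance = 0.02)
  expect_equal(diff(range(cl[, 2])), max(0.306, 0.290), tolerance = 0.02)
  expect_equal(max(cl[, 3]), max(0.675, 0.681), tolerance = 0.02)
  # per-identity relief stays within its stated bound
  cl2 <- unclass(make_back_surface(p1, density = 6000, seed = 2,
                                   detail = 0.02))
  expect_lte(max(cl2[, 3]), max(0.675, 0.681) * 1.02 + 1e-9)
})

test_that("point count scales with density and sampling is deterministic", {
  p <- pig_roster(4)[[1]]
  a <- make_back_surface(p, density = 2000, seed = 5)
  b <- make_back_surface(p, density = 4000, seed = 5)
  expect_equal(nrow(b) / nrow(a), 2, tolerance = 0.1)
  expect_equal(make_back_surface(p, density = 2000, seed = 5), a)
  expect_false(isTRUE(all.equal(make_back_surface(p, 2000, seed = 6), a)))
  expect_error(make_back_surface(p, density = 0), class = "invalid_argument")
})

test_that("scenes carry an occlusion shadow and consistent labels", {
  p <- pig_roster(2)[[1]]
  cfg <- scene_config(noise_sd = 0, crack_count = 0, include_head = FALSE,
                      seed = 7)
  sc <- make_scene(p, cfg)
  cl <- unclass(sc$cloud)
  expect_equal(length(sc$part_labels), nrow(cl))
  expect_setequal(unique(sc$part_labels), c(0L, 1L))
  # no ground point (z == 0) inside the body footprint
  ground <- cl[sc$part_labels == 0L, , drop = FALSE]
  back <- cl[sc$part_labels == 1L, , drop = FALSE]
  in_fp <- ground[, 1] >= min(back[, 1]) & ground[, 1] <= max(back[, 1]) &
    abs(ground[, 2]) <= min(p$cw, p$hw) / 2   # conservative inner box
  expect_equal(sum(in_fp), 0L)
  # label fractions recounted independently
  expect_equal(mean(sc$part_labels == 1L), nrow(back) / nrow(cl))
})

test_that("the head is an elevated background blob at the chest end", {
  p <- pig_roster(6)[[1]]
  sc <- make_scene(p, scene_config(noise_sd = 0, crack_count = 0,
                                   include_head = TRUE, seed = 8))
  cl <- unclass(sc$cloud)
  elevated_bg <- sc$part_labels == 0L & cl[, 3] > 0.1
  expect_gt(sum(elevated_bg), 20)
  # head sits beyond the chest end of the back
  back_x <- range(cl[sc$part_labels == 1L, 1])
  expect_lt(median(cl[elevated_bg, 1]), back_x[1])
})

test_that("cracks delete points along the ridge", {
  p <- pig_roster(5)[[1]]
  n0 <- sum(make_scene(p, scene_config(noise_sd = 0, crack_count = 0,
                                       seed = 9))$part_labels == 1L)
  n3 <- sum(make_scene(p, scene_config(noise_sd = 0, crack_count = 3,
                                       seed = 9))$part_labels == 1L)
  expect_lt(n3, n0)
})

test_that("scene generation is rigid-motion consistent", {
  p <- pig_roster(3)[[1]]
  cfg <- scene_config(noise_sd = 0, crack_count = 0, include_head = FALSE,
                      seed = 10)
  s0 <- make_scene(p, cfg)
  s1 <- make_scene(p, cfg, pose = list(theta = 0.6, tx = 0.05, ty = -0.08))
  b0 <- unclass(s0$cloud)[s0$part_labels == 1L, ]
  b1 <- unclass(s1$cloud)[s1$part_labels == 1L, ]
  expect_equal(nrow(b0), nrow(b1))
  expect_equal(as.numeric(dist(b0)), as.numeric(dist(b1)), tolerance = 1e-9)
})

test_that("footprints larger than the ground plane are rejected", {
  big <- pig_shape(40, 40, 70, 70, 300, identity = 0L)
  expect_error(make_scene(big, scene_config(ground_extent = 2, seed = 1)),
               class = "invalid_argument")
})

test_that("datasets split 3:1 stratified and are seed-deterministic", {
  roster <- pig_roster(c(1, 4))
  ds <- make_dataset(roster, 8, scene_config(seed = 11, point_density = 800))
  expect_length(ds$scenes, 16L)
  for (k in unique(ds$identity)) {
    expect_equal(sum(ds$identity == k & ds$split == 0L), 6L)
    expect_equal(sum(ds$identity == k & ds$split == 1L), 2L)
  }
  ds2 <- make_dataset(roster, 8, scene_config(seed = 11, point_density = 800))
  expect_identical(serialize(ds, NULL, version = 3),
                   serialize(ds2, NULL, version = 3))
  ds3 <- make_dataset(roster, 8, scene_config(seed = 12, point_density = 800))
  expect_false(identical(ds$scenes[[1]]$cloud, ds3$scenes[[1]]$cloud))
  expect_error(make_dataset(list(), 5, scene_config(seed = 1)),
               class = "invalid_argument")
})

test_that("roster JSON roundtrips and malformed records are named", {
  f <- tempfile(fileext = ".json")
  roster <- pig_roster(c(2, 9))
  write_roster(roster, f)
  back <- read_roster(f)
  expect_equal(back, roster)
  jsonlite::write_json(list(list(chest_width = 30)), f, auto_unbox = TRUE)
  expect_error(read_roster(f), "record 1", class = "format_error")
  unlink(f)
})

test_that("depth rendering is a z-buffer inverse of the back-projection", {
  p <- pig_roster(7)[[1]]
  sc <- make_scene(p, scene_config(noise_sd = 0, crack_count = 0, seed = 13,
                                   point_density = 1200))
  intr <- camera_intrinsics(cx = 320, cy = 240)
  img <- render_depth(sc, intr, camera_height = 2.5)
  expect_equal(img$width, 640L)
  cl <- unclass(depth_to_cloud(img, intr))
  cl[, 3] <- 2.5 - cl[, 3]  # back to heights above ground
  # every recovered point lies near an original: nearest-neighbour error
  # bounded by one depth-quantization step plus the pixel footprint
  orig <- unclass(sc$cloud)
  kn <- interpolate_features(cl, orig, matrix(orig[, 3], ncol = 1), k = 1)
  expect_lt(median(abs(kn[, 1] - cl[, 3])), 0.005)

  # empty scene renders to an all-invalid frame
  empty <- render_depth(point_cloud(matrix(numeric(0), 0, 3)), intr, 2.5)
  expect_equal(sum(empty$values), 0)

  # nearest surface wins per pixel: stacked point pairs on two planes
  g <- expand.grid(x = seq(-0.2, 0.2, 0.05), y = seq(-0.2, 0.2, 0.05))
  planes <- point_cloud(rbind(cbind(g$x, g$y, 1), cbind(g$x, g$y, 0.5)))
  di <- render_depth(planes, intr, 2.5)
  got <- di$values[di$values > 0] * intr$depth_scale
  # every pixel hit by a stacked pair shows the upper plane (D = 1.5);
  # pixels where the two projections separate may show the lower one
  px_up <- render_depth(point_cloud(cbind(g$x, g$y, 1)), intr, 2.5)$values
  both <- px_up > 0 & di$values > 0
  expect_true(all(di$values[both] == px_up[both]))
  expect_equal(min(got), 1.5)
})
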