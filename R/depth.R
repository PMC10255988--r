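#' Pinhole camera intrinsics
#'
#' Focal lengths are in pixels, `depth_scale` converts sensor depth units
#' to metres (1 unit = 1 mm by default). The image-to-world model has no
#' principal-point offset by default; `cx`/`cy` are an optional offset for
#' real sensors whose pixel origin is not on the optical axis.
#'
#' @param fx,fy focal lengths (pixels).
#' @param depth_scale metres per sensor depth unit.
#' @param cx,cy optional principal point (pixels, corner-origin
#'   coordinates); 0 reproduces the plain projection model.
#' @return a `camera_intrinsics` list.
#' @export
camera_intrinsics <- function(fx = 601.9267, fy = 603.3360,
                              depth_scale = 0.001, cx = 0, cy = 0) {
  if (fx <= 0 || fy <= 0 || depth_scale <= 0)
    .invalid_argument("fx, fy and depth_scale must be positive")
  structure(list(fx = fx, fy = fy, depth_scale = depth_scale,
                 cx = cx, cy = cy), class = "camera_intrinsics")
}

#' Depth frame container
#'
#' @param values numeric matrix (height x width) of depth values in sensor
#'   units; 0 marks an invalid pixel.
#' @return a `depth_image` object.
#' @export
depth_image <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0)) .invalid_argument("depth values must be >= 0")
  structure(list(values = values, width = ncol(values),
                 height = nrow(values)), class = "depth_image")
}

#' @export
print.depth_image <- function(x, ...) {
  cat(sprintf("depth_image: %d x %d, %d valid pixels\n",
              x$width, x$height, sum(x$values > 0)))
  invisible(x)
}

#' Convert a depth frame to a point cloud
#'
#' Back-projects every valid pixel through the pinhole model
#' `x = D * x' / fx`, `y = D * y' / fy`, `z = D`, where `(x', y')` are the
#' corner-origin pixel coordinates (column - 1, row - 1, minus the
#' optional principal point) and `D` is the metric depth
#' (`value * depth_scale`). Invalid pixels (value 0) are dropped.
#'
#' @param img a [depth_image()].
#' @param intr a [camera_intrinsics()].
#' @return a `point_cloud`.
#' @export
depth_to_cloud <- function(img, intr) {
  stopifnot(inherits(img, "depth_image"), inherits(intr, "camera_intrinsics"))
  v <- img$values
  valid <- which(v > 0, arr.ind = TRUE)
  if (nrow(valid) == 0L) .invalid_argument("all pixels invalid")
  D <- v[valid] * intr$depth_scale
  xp <- valid[, 2] - 1 - intr$cx
  yp <- valid[, 1] - 1 - intr$cy
  point_cloud(cbind(D * xp / intr$fx, D * yp / intr$fy, D))
}

#' Render a scene to a depth frame (z-buffer)
#'
#' Projects scene points through the inverse of the back-projection model
#' used by [depth_to_cloud()]. The camera sits at the world origin at
#' height `camera_height`, looking straight down; the optical axis depth
#' of a point at height z is `camera_height - z`. Each point lands on the
#' pixel `round(fx * x / D + cx)`, the nearest surface wins per pixel
#' (z-buffer), and depth is quantized to integer sensor units. Pixels with
#' no surface get value 0. Points outside the frame or behind the camera
#' are silently excluded.
#'
#' @param scene a `synthetic_scene` or a `point_cloud`.
#' @param intr a [camera_intrinsics()].
#' @param camera_height camera height above the ground plane (m); must be
#'   above the tallest point.
#' @param width,height frame size in pixels.
#' @return a [depth_image()].
#' @export
render_depth <- function(scene, intr, camera_height, width = 640L,
                         height = 480L) {
  m <- if (inherits(scene, "synthetic_scene")) .as_cloud_matrix(scene$cloud)
       else .as_cloud_matrix(scene)
  vals <- matrix(0, height, width)
  if (nrow(m) > 0L) {
    if (camera_height <= max(m[, 3]))
      .invalid_argument("camera_height must be above the tallest point")
    D <- camera_height - m[, 3]
    keep <- D > 0
    D <- D[keep]
    col <- round(intr$fx * m[keep, 1] / D + intr$cx) + 1L
    row <- round(intr$fy * m[keep, 2] / D + intr$cy) + 1L
    units <- pmax(1, round(D / intr$depth_scale))
    inside <- col >= 1L & col <= width & row >= 1L & row <= height
    col <- col[inside]; row <- row[inside]; units <- units[inside]
    # z-buffer: keep the smallest depth per pixel
    pix <- (col - 1L) * height + row
    o <- order(pix, units)
    first <- !duplicated(pix[o])
    vals[pix[o][first]] <- units[o][first]
  }
  depth_image(vals)
}

#' Read and write 16-bit depth frames
#'
#' Depth frames are stored as 16-bit PGM (portable graymap, `P2` ASCII or
#' `P5` binary big-endian), with 0 encoding an invalid pixel. 16-bit
#' grayscale PNG frames can additionally be read when the `png` package is
#' available.
#'
#' @param img a [depth_image()]; values must fit in 16 bits.
#' @param path file path.
#' @param ascii write the ASCII (`P2`) variant.
#' @return `read_depth` returns a [depth_image()]; `write_depth` returns
#'   `path` invisibly.
#' @export
write_depth <- function(img, path, ascii = FALSE) {
  stopifnot(inherits(img, "depth_image"))
  v <- round(img$values)
  if (any(v > 65535)) .invalid_argument("depth exceeds 16-bit range")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("%s\n%d %d\n65535\n", if (ascii) "P2" else "P5",
                 img$width, img$height)
  writeChar(hdr, con, eos = NULL)
  if (ascii) {
    writeLines(apply(v, 1, function(r) paste(as.integer(r), collapse = " ")),
               con)
  } else {
    writeBin(as.integer(t(v)), con, size = 2, endian = "big")
  }
  invisible(path)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      .format_error("reading PNG depth frames requires the 'png' package")
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    return(depth_image(round(x * 65535)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!magic %in% c("P2", "P5")) .format_error("not a P2/P5 PGM file")
  # header tokens: width height maxval (comments not supported)
  toks <- integer(0)
  while (length(toks) < 3) {
    ln <- readLines(con, 1)
    if (length(ln) == 0) .format_error("truncated PGM header")
    toks <- c(toks, as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1)
    .format_error("malformed PGM header")
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = if (maxval > 255) 2 else 1,
                   signed = FALSE, endian = "big")
  } else {
    raw <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(raw) < w * h) .format_error("truncated PGM pixel data")
  depth_image(matrix(raw, nrow = h, ncol = w, byrow = TRUE))
}
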