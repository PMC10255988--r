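#' Read and write point-cloud files (PLY, PCD)
#'
#' Supported formats are PLY (ASCII and binary little-endian 1.0) and PCD
#' (v0.7, ASCII and binary). Coordinates are stored as 32-bit floats; an
#' optional integer per-vertex `label` property carries part labels or
#' identities and survives a write/read roundtrip exactly. The format is
#' chosen from the file extension.
#'
#' @param path file path ending in `.ply` or `.pcd`.
#' @param cloud a `point_cloud`.
#' @param labels optional integer per-point labels.
#' @param binary write the binary variant.
#' @return `read_cloud` returns a list with `cloud` and `labels` (`NULL`
#'   when absent); writers return `path` invisibly.
#' @export
write_cloud <- function(cloud, path, labels = NULL, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(cloud, path, labels, binary),
         pcd = write_pcd(cloud, path, labels, binary),
         .invalid_argument(sprintf("unsupported cloud format '.%s'", ext)))
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         pcd = read_pcd(path),
         .invalid_argument(sprintf("unsupported cloud format '.%s'", ext)))
}

#' @rdname write_cloud
#' @export
write_ply <- function(cloud, path, labels = NULL, binary = FALSE) {
  m <- .as_cloud_matrix(cloud)
  if (!is.null(labels) && length(labels) != nrow(m))
    .invalid_argument("labels length must match point count")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(m)),
           "property float x", "property float y", "property float z",
           if (!is.null(labels)) "property int label",
           "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    # interleave per vertex: 3 floats (+ 1 int32)
    for (i in seq_len(nrow(m))) {
      writeBin(as.numeric(m[i, ]), con, size = 4, endian = "little")
      if (!is.null(labels))
        writeBin(as.integer(labels[i]), con, size = 4, endian = "little")
    }
  } else {
    rows <- apply(m, 1, function(r) paste(format(r, digits = 9, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
    if (!is.null(labels)) rows <- paste(rows, as.integer(labels))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  line1 <- readLines(con, 1)
  if (length(line1) == 0 || line1 != "ply") .format_error("missing 'ply' magic")
  fmt <- NULL; nvert <- NULL; props <- character(0); ptypes <- character(0)
  in_vertex <- FALSE
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) .format_error("truncated header (no end_header)")
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (toks[1] == "format") {
      fmt <- toks[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        .format_error(sprintf("unsupported PLY format '%s'", fmt))
    } else if (toks[1] == "element") {
      in_vertex <- toks[2] == "vertex"
      if (in_vertex) nvert <- as.integer(toks[3])
      else .format_error(sprintf("unsupported element '%s'", toks[2]))
    } else if (toks[1] == "property" && in_vertex) {
      ptypes <- c(ptypes, toks[2])
      props <- c(props, toks[3])
    } else if (toks[1] == "end_header") break
  }
  if (is.null(fmt) || is.null(nvert)) .format_error("incomplete PLY header")
  if (!all(c("x", "y", "z") %in% props))
    .format_error("vertex element lacks x/y/z properties")
  sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
             int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
             float = 4, float32 = 4, double = 8, float64 = 8)
  if (!all(ptypes %in% names(sizes)))
    .format_error(sprintf("unsupported property type '%s'",
                          setdiff(ptypes, names(sizes))[1]))
  np <- length(props)
  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = nvert * np, quiet = TRUE)
    if (length(vals) < nvert * np) .format_error("truncated vertex data")
    M <- matrix(vals, nrow = nvert, ncol = np, byrow = TRUE)
  } else {
    M <- matrix(0, nvert, np)
    for (i in seq_len(nvert)) for (j in seq_len(np)) {
      sz <- sizes[[ptypes[j]]]
      isfloat <- ptypes[j] %in% c("float", "float32", "double", "float64")
      v <- if (isfloat) readBin(con, "double", 1, size = sz, endian = "little")
           else readBin(con, "integer", 1, size = sz, endian = "little",
                        signed = !(sz <= 2 && grepl("^u", ptypes[j])))
      if (length(v) == 0) .format_error("truncated vertex data")
      M[i, j] <- v
    }
  }
  lab <- if ("label" %in% props) as.integer(M[, match("label", props)])
  list(cloud = point_cloud(M[, match(c("x", "y", "z"), props), drop = FALSE]),
       labels = lab)
}

#' @rdname write_cloud
#' @export
write_pcd <- function(cloud, path, labels = NULL, binary = FALSE) {
  m <- .as_cloud_matrix(cloud)
  if (!is.null(labels) && length(labels) != nrow(m))
    .invalid_argument("labels length must match point count")
  con <- file(path, "wb")
  on.exit(close(con))
  flds <- c("x", "y", "z", if (!is.null(labels)) "label")
  nf <- length(flds)
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(flds, collapse = " ")),
           paste("SIZE", paste(rep(4, nf), collapse = " ")),
           paste("TYPE", paste(c("F", "F", "F", if (nf == 4) "I"),
                               collapse = " ")),
           paste("COUNT", paste(rep(1, nf), collapse = " ")),
           sprintf("WIDTH %d", nrow(m)), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", nrow(m)),
           sprintf("DATA %s", if (binary) "binary" else "ascii"))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    for (i in seq_len(nrow(m))) {
      writeBin(as.numeric(m[i, ]), con, size = 4, endian = "little")
      if (!is.null(labels))
        writeBin(as.integer(labels[i]), con, size = 4, endian = "little")
    }
  } else {
    rows <- apply(m, 1, function(r) paste(format(r, digits = 9, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
    if (!is.null(labels)) rows <- paste(rows, as.integer(labels))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_pcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  flds <- NULL; npts <- NULL; data_mode <- NULL; types <- NULL
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) .format_error("truncated PCD header (no DATA line)")
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- toupper(toks[1])
    if (key == "FIELDS") flds <- toks[-1]
    else if (key == "TYPE") types <- toks[-1]
    else if (key == "POINTS") npts <- as.integer(toks[2])
    else if (key == "DATA") { data_mode <- toks[2]; break }
  }
  if (is.null(flds) || is.null(npts))
    .format_error("PCD header lacks FIELDS or POINTS")
  if (!all(c("x", "y", "z") %in% flds))
    .format_error("PCD lacks x/y/z fields")
  nf <- length(flds)
  if (data_mode == "ascii") {
    vals <- scan(con, what = numeric(), n = npts * nf, quiet = TRUE)
    if (length(vals) < npts * nf) .format_error("truncated PCD data")
    M <- matrix(vals, nrow = npts, ncol = nf, byrow = TRUE)
  } else if (data_mode == "binary") {
    M <- matrix(0, npts, nf)
    for (i in seq_len(npts)) for (j in seq_len(nf)) {
      isint <- !is.null(types) && types[j] %in% c("I", "U")
      v <- if (isint) readBin(con, "integer", 1, size = 4, endian = "little")
           else readBin(con, "double", 1, size = 4, endian = "little")
      if (length(v) == 0) .format_error("truncated PCD data")
      M[i, j] <- v
    }
  } else .format_error(sprintf("unsupported PCD data mode '%s'", data_mode))
  lab <- if ("label" %in% flds) as.integer(M[, match("label", flds)])
  list(cloud = point_cloud(M[, match(c("x", "y", "z"), flds), drop = FALSE]),
       labels = lab)
}
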