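# Point clouds, rigid transforms, multi-view fusion, PLY/XYZ I/O.
# Internal unit is meters throughout; measurements convert to cm at the
# reporting boundary (see measure_animal).

#' Construct a point cloud
#'
#' A point cloud is an n x 3 numeric matrix of (x, y, z) coordinates in
#' meters, with class `"point_cloud"` and an optional per-point source-view
#' tag kept in the `"view"` attribute.
#'
#' @param points numeric matrix (or data.frame) with 3 columns, coordinates in
#'   meters. May have zero rows, but must be passed explicitly; coordinates
#'   must all be finite.
#' @param view optional character or integer vector of per-point source-view
#'   tags, recycled if length 1.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, view = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 3L)
    stop("`points` must be an n x 3 matrix of coordinates")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("point cloud contains non-finite coordinates")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  if (!is.null(view)) {
    if (length(view) == 1L) view <- rep(view, nrow(points))
    if (length(view) != nrow(points))
      stop("`view` must have one tag per point")
    attr(points, "view") <- view
  }
  class(points) <- c("point_cloud", class(points))
  points
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points>\n", nrow(x)))
  if (nrow(x) > 0L) {
    rg <- apply(x, 2L, range)
    cat(sprintf("  extent [m]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
                rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  }
  v <- attr(x, "view")
  if (!is.null(v)) cat("  views:", paste(unique(v), collapse = ", "), "\n")
  invisible(x)
}

is_point_cloud <- function(x) inherits(x, "point_cloud")

as_point_cloud <- function(x) {
  if (is_point_cloud(x)) x else point_cloud(x)
}

#' Construct a rigid transform
#'
#' A rigid transform is a 4 x 4 homogeneous matrix whose rotation block is
#' orthonormal with determinant +1 and whose translation is in meters.
#'
#' @param m 4 x 4 numeric matrix.
#' @param tol tolerance on `||R'R - I||` (Frobenius) for the rigidity check.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L)) || !all(is.finite(m)))
    stop("a rigid transform must be a finite 4 x 4 matrix")
  R <- m[1:3, 1:3]
  if (sqrt(sum((crossprod(R) - diag(3))^2)) > tol)
    stop("rotation block is not orthonormal: matrix is not rigid")
  if (det(R) <= 0)
    stop("rotation block has non-positive determinant: reflections are not rigid motions")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > tol))
    stop("bottom row of a homogeneous rigid transform must be (0, 0, 0, 1)")
  m[4, ] <- c(0, 0, 0, 1)
  class(m) <- c("rigid_transform", class(m))
  m
}

#' Elementary rigid transforms
#'
#' Helpers building rigid transforms from a translation vector or a rotation
#' about a coordinate axis.
#'
#' @param v length-3 translation in meters.
#' @param angle rotation angle in radians.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return a [rigid_transform()].
#' @export
transform_translate <- function(v) {
  m <- diag(4)
  m[1:3, 4] <- v
  rigid_transform(m)
}

#' @rdname transform_translate
#' @export
transform_rotate <- function(angle, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c0, -s0), c(0, s0, c0)),
    y = rbind(c(c0, 0, s0), c(0, 1, 0), c(-s0, 0, c0)),
    z = rbind(c(c0, -s0, 0), c(s0, c0, 0), c(0, 0, 1)))
  m <- diag(4)
  m[1:3, 1:3] <- R
  rigid_transform(m)
}

#' Compose rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform that applies `t1` first and
#' `t2` second (matrix product `t2 %*% t1`).
#'
#' @param t2,t1 rigid transforms.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(unclass(t2) %*% unclass(t1))
}

#' Invert a rigid transform
#'
#' @param t a rigid transform.
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  R <- t[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -crossprod(R, t[1:3, 4])
  rigid_transform(m)
}

#' Apply a rigid transform to a point cloud
#'
#' Each point p is mapped to R p + t. Lengths and angles are preserved.
#'
#' @param cloud a [point_cloud()].
#' @param transform a [rigid_transform()].
#' @return the transformed [point_cloud()]; view tags are retained.
#' @export
apply_transform <- function(cloud, transform) {
  cloud <- as_point_cloud(cloud)
  if (!inherits(transform, "rigid_transform"))
    transform <- rigid_transform(transform)
  R <- transform[1:3, 1:3]
  tr <- transform[1:3, 4]
  pts <- unclass(cloud) %*% t(R)
  pts <- sweep(pts, 2L, tr, "+")
  point_cloud(pts, view = attr(cloud, "view"))
}

#' Fuse multiple views into one world-frame cloud
#'
#' Maps each per-view cloud into the world frame by its transform and
#' concatenates the results, retaining source-view tags. Optionally
#' de-duplicates points on a voxel grid (one representative point, the first
#' encountered, per occupied voxel).
#'
#' @param views list of [point_cloud()]s, one per camera view.
#' @param transforms list of [rigid_transform()]s of the same length
#'   (camera-to-world).
#' @param voxel optional voxel edge length in meters for de-duplication;
#'   `NULL` (default) keeps all points.
#' @return the fused world-frame [point_cloud()].
#' @export
fuse_views <- function(views, transforms, voxel = NULL) {
  if (!is.list(views) || !is.list(transforms))
    stop("`views` and `transforms` must be lists")
  if (length(views) != length(transforms))
    stop(sprintf("length mismatch: %d views but %d transforms",
                 length(views), length(transforms)))
  if (length(views) < 1L) stop("at least one view is required")
  mapped <- vector("list", length(views))
  tags <- vector("list", length(views))
  for (i in seq_along(views)) {
    w <- apply_transform(views[[i]], transforms[[i]])
    mapped[[i]] <- unclass(w)
    tg <- attr(views[[i]], "view")
    if (is.null(tg)) tg <- rep(i, nrow(w))
    tags[[i]] <- tg
  }
  pts <- do.call(rbind, mapped)
  tag <- unlist(tags, use.names = FALSE)
  if (!is.null(voxel)) {
    if (!is.numeric(voxel) || voxel <= 0) stop("`voxel` must be a positive length in meters")
    key <- paste(floor(pts[, 1] / voxel), floor(pts[, 2] / voxel),
                 floor(pts[, 3] / voxel))
    keep <- !duplicated(key)
    pts <- pts[keep, , drop = FALSE]
    tag <- tag[keep]
  }
  point_cloud(pts, view = tag)
}

# ---- file formats -----------------------------------------------------------

#' Read and write point clouds (PLY and XYZ)
#'
#' PLY support covers the `ascii 1.0` and `binary_little_endian 1.0` dialects
#' with float or double `x`, `y`, `z` vertex properties (other scalar vertex
#' properties are skipped; list properties and non-vertex elements are
#' tolerated after the vertex element only). XYZ files are plain
#' whitespace-delimited rows of three coordinates. Round-tripping preserves
#' point order and coordinates to at least float32 precision (exactly, for
#' the default ascii writer).
#'
#' @param path file path.
#' @param format `"ply"` or `"xyz"`; default guesses from the file extension.
#' @param cloud a [point_cloud()].
#' @param binary for `write_cloud` with PLY: write binary-little-endian
#'   instead of the default ascii.
#' @return `read_cloud` returns a [point_cloud()]; `write_cloud` returns
#'   `path` invisibly.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), ply = "ply", "xyz")
  }
  if (format == "ply") read_ply(path) else read_xyz(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("%s: empty XYZ file (no coordinate rows)", path))
  pts <- matrix(NA_real_, length(lines), 3L)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(tok) < 3L)
      stop(sprintf("%s: line %d: expected 3 coordinates, got %d tokens",
                   path, i, length(tok)))
    v <- suppressWarnings(as.numeric(tok[1:3]))
    if (any(is.na(v)))
      stop(sprintf("%s: line %d: non-numeric coordinate '%s'",
                   path, i, tok[which(is.na(v))[1]]))
    pts[i, ] <- v
  }
  point_cloud(pts)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (length(magic) == 0L) stop(sprintf("%s: empty file, not a PLY", path))
  if (!identical(trimws(magic), "ply"))
    stop(sprintf("%s: line 1: missing 'ply' magic", path))
  fmt <- NULL; n_vertex <- NULL
  props <- character(); prop_types <- character()
  in_vertex <- FALSE; seen_other_element_after <- FALSE
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(ln) == 0L) stop(sprintf("%s: header ended before end_header", path))
    ln <- trimws(ln)
    if (ln == "end_header") break
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (tok[1] == "format") {
      if (!tok[2] %in% c("ascii", "binary_little_endian"))
        stop(sprintf("%s: line %d: unsupported PLY format '%s'", path, lineno, tok[2]))
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (tok[2] == "vertex") {
        in_vertex <- TRUE
        n_vertex <- suppressWarnings(as.integer(tok[3]))
        if (is.na(n_vertex)) stop(sprintf("%s: line %d: bad vertex count", path, lineno))
      } else {
        if (is.null(n_vertex))
          stop(sprintf("%s: line %d: element '%s' precedes the vertex element",
                       path, lineno, tok[2]))
        in_vertex <- FALSE
        seen_other_element_after <- TRUE
      }
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list")
        stop(sprintf("%s: line %d: list vertex properties are unsupported", path, lineno))
      props <- c(props, tok[3])
      prop_types <- c(prop_types, tok[2])
    }
  }
  if (is.null(fmt)) stop(sprintf("%s: header has no format line", path))
  if (is.null(n_vertex)) stop(sprintf("%s: header has no vertex element", path))
  ix <- match(c("x", "y", "z"), props)
  if (any(is.na(ix)))
    stop(sprintf("%s: vertex element lacks x, y, z properties", path))
  if (fmt == "ascii") {
    rows <- readLines(con, n = n_vertex)
    if (length(rows) < n_vertex)
      stop(sprintf("%s: expected %d vertex rows, found %d", path, n_vertex, length(rows)))
    pts <- matrix(NA_real_, n_vertex, 3L)
    for (i in seq_len(n_vertex)) {
      tok <- strsplit(trimws(rows[[i]]), "[ \t]+")[[1]]
      if (length(tok) < length(props))
        stop(sprintf("%s: vertex row %d: expected %d fields, got %d",
                     path, i, length(props), length(tok)))
      v <- suppressWarnings(as.numeric(tok[ix]))
      if (any(is.na(v)))
        stop(sprintf("%s: vertex row %d: non-numeric coordinate", path, i))
      pts[i, ] <- v
    }
  } else {
    sizes <- ply_type_size[prop_types]
    if (any(is.na(sizes)))
      stop(sprintf("%s: unknown property type '%s'",
                   path, prop_types[which(is.na(sizes))[1]]))
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n_vertex * stride)
    if (length(raw) < n_vertex * stride)
      stop(sprintf("%s: truncated binary vertex data (offset %d of %d bytes)",
                   path, length(raw), n_vertex * stride))
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    pts <- matrix(NA_real_, n_vertex, 3L)
    for (k in 1:3) {
      j <- ix[k]
      ty <- prop_types[j]
      base <- offs[j]
      idx <- as.vector(outer(seq_len(sizes[j]), (seq_len(n_vertex) - 1L) * stride + base, "+"))
      bytes <- raw[idx]
      pts[, k] <- if (ty %in% c("float", "float32"))
        readBin(bytes, "double", n = n_vertex, size = 4L, endian = "little")
      else if (ty %in% c("double", "float64"))
        readBin(bytes, "double", n = n_vertex, size = 8L, endian = "little")
      else
        stop(sprintf("%s: coordinate property '%s' must be float or double", path, props[j]))
    }
  }
  point_cloud(pts)
}

#' @rdname read_cloud
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "xyz"),
                        binary = FALSE) {
  cloud <- as_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), ply = "ply", "xyz")
  pts <- unclass(cloud)
  if (format == "xyz") {
    writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), path)
  } else if (!binary) {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(pts)),
             "property double x", "property double y", "property double z",
             "end_header")
    writeLines(c(hdr, sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply", "format binary_little_endian 1.0",
             sprintf("element vertex %d", nrow(pts)),
             "property float x", "property float y", "property float z",
             "end_header")
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.vector(t(pts)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read and write 4 x 4 transform files
#'
#' Transforms are stored as plain text: 4 whitespace-delimited rows of 4
#' numbers.
#'
#' @param path file path.
#' @param transform a [rigid_transform()].
#' @return `read_transform` returns a [rigid_transform()]; `write_transform`
#'   returns `path` invisibly.
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (any(dim(m) != c(4L, 4L)))
    stop(sprintf("%s: expected a 4 x 4 matrix, got %d x %d", path, nrow(m), ncol(m)))
  dimnames(m) <- NULL
  rigid_transform(m)
}

#' @rdname read_transform
#' @export
write_transform <- function(transform, path) {
  m <- unclass(transform)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), path)
  invisible(path)
}
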