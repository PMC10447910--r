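#' Triangle mesh constructor
#'
#' A `mesh3` is the package's surface container: an `n x 3` numeric matrix of
#' vertex coordinates in millimetres and an `m x 3` integer matrix of 1-based
#' vertex indices, one row per triangle. Faces may be absent (a point cloud),
#' but when present every index must address an existing vertex and no
#' triangle may repeat a vertex.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices, or a matrix
#'   with zero rows for a point cloud.
#' @return An object of class `mesh3`.
#' @export
mesh3 <- function(vertices, faces = matrix(integer(), 0L, 3L)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) < 3L) stop("a mesh needs at least 3 vertices")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  if (length(faces) == 0L) faces <- matrix(integer(), 0L, 3L)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face index out of range [1, ", nrow(vertices), "]")
    degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
      faces[, 2L] == faces[, 3L]
    if (any(degen)) stop("degenerate face repeating a vertex at row ",
                         which(degen)[1L])
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  structure(list(vertices = vertices, faces = faces), class = "mesh3")
}

#' @export
print.mesh3 <- function(x, ...) {
  cat("<mesh3> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

#' Read a Wavefront OBJ triangle mesh
#'
#' Parses `v` and `f` records of an ASCII OBJ file. Texture/normal indices
#' (`f 1/2/3` syntax) are stripped; `vn`, `vt`, materials and groups are
#' ignored. Polygonal faces are fan-triangulated around their first vertex,
#' the convention 3D scanners' exporters assume for convex facets. Negative
#' (relative) indices are resolved against the vertices read so far.
#'
#' @param path path to an OBJ file.
#' @return A [mesh3].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(v|f)[ \t]", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  toks <- strsplit(trimws(lines), "[ \t]+")
  is_v <- vapply(toks, function(t) t[[1L]] == "v", logical(1L))

  vparts <- toks[is_v]
  vl <- lineno[is_v]
  verts <- matrix(NA_real_, length(vparts), 3L)
  for (i in seq_along(vparts)) {
    t <- vparts[[i]]
    if (length(t) < 4L)
      stop("malformed vertex line ", vl[i], ": fewer than 3 coordinates")
    xyz <- suppressWarnings(as.numeric(t[2:4]))
    if (any(is.na(xyz)))
      stop("malformed vertex line ", vl[i], ": non-numeric coordinate")
    verts[i, ] <- xyz
  }

  fparts <- toks[!is_v]
  fl <- lineno[!is_v]
  tri <- vector("list", length(fparts))
  for (i in seq_along(fparts)) {
    t <- fparts[[i]][-1L]
    if (length(t) < 3L)
      stop("malformed face line ", fl[i], ": fewer than 3 indices")
    idx <- suppressWarnings(as.integer(sub("/.*$", "", t)))
    if (any(is.na(idx)))
      stop("malformed face line ", fl[i], ": non-integer index")
    idx <- ifelse(idx < 0L, nrow(verts) + 1L + idx, idx)
    if (any(idx < 1L) || any(idx > nrow(verts)))
      stop("face index out of range on line ", fl[i])
    # fan triangulation for polygons with > 3 sides
    k <- length(idx)
    tri[[i]] <- cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
  }
  faces <- if (length(tri)) do.call(rbind, tri) else matrix(integer(), 0L, 3L)
  mesh3(verts, faces)
}

#' Write a mesh as Wavefront OBJ
#'
#' Coordinates are written with 6 decimals, so a write/read round trip
#' reproduces vertices to 1e-6 mm and faces exactly.
#'
#' @param mesh a [mesh3].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh3"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]),
               con)
  invisible(path)
}

#' Crop a mesh to the slab between two planes
#'
#' Used to restrict a reference scan to the clinically relevant region (below
#' the eyes, above the thyroid cartilage) programmatically. Each plane is a
#' `list(point =, normal =)` in mesh coordinates; a vertex is kept when it
#' lies strictly on the positive side of *both* normals, so the two normals
#' must face each other across the slab to be retained. Faces survive only if
#' all three vertices do, and the result is reindexed with no dangling
#' vertices.
#'
#' @param mesh a [mesh3].
#' @param lower_plane,upper_plane lists with elements `point` (length-3) and
#'   `normal` (length-3, pointing into the kept region).
#' @return The cropped [mesh3].
#' @export
crop_region <- function(mesh, lower_plane, upper_plane) {
  stopifnot(inherits(mesh, "mesh3"))
  side <- function(pl) {
    n <- as.numeric(pl$normal); p <- as.numeric(pl$point)
    drop(sweep(mesh$vertices, 2L, p) %*% n) > 0
  }
  keep <- side(lower_plane) & side(upper_plane)
  if (!any(keep)) stop("crop removed all geometry")
  new_id <- cumsum(keep)
  f <- mesh$faces
  fk <- f[keep[f[, 1L]] & keep[f[, 2L]] & keep[f[, 3L]], , drop = FALSE]
  fk <- matrix(new_id[fk], ncol = 3L)
  out_v <- mesh$vertices[keep, , drop = FALSE]
  if (nrow(out_v) < 3L) stop("crop removed all geometry")
  mesh3(out_v, fk)
}

#' Anchor landmark names, in the fixed digitisation order
#'
#' Eight anchoring landmarks drive the initial similarity alignment of the
#' reference mesh onto each scan. Their order is fixed so that files and
#' point sets are comparable across scans.
#'
#' @return Character vector of length 8.
#' @export
anchor_names <- function() {
  c("pronasale", "right_earlobe", "left_earlobe", "right_cheilion",
    "left_cheilion", "tip_of_chin", "hyoid_bone", "thyroid_notch")
}

#' Validate an anchor set
#'
#' @param x a data frame with columns `name, x, y, z` (8 rows, fixed order) or
#'   an 8 x 3 numeric matrix taken to be in the fixed order.
#' @return A tibble with columns `name, x, y, z`.
#' @export
anchor_set <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 8L, ncol(x) == 3L)
    m <- unname(x)
    x <- tibble::tibble(name = anchor_names(),
                        x = m[, 1L], y = m[, 2L], z = m[, 3L])
  }
  x <- tibble::as_tibble(x)
  if (!all(c("name", "x", "y", "z") %in% names(x)))
    stop("anchor table needs columns name, x, y, z")
  if (nrow(x) != 8L) stop("an anchor set has exactly 8 points, got ", nrow(x))
  if (!identical(as.character(x$name), anchor_names()))
    stop("anchor names/order must be: ", paste(anchor_names(), collapse = ", "))
  if (!all(is.finite(c(x$x, x$y, x$z)))) stop("anchor coordinates must be finite")
  x
}

#' Read / write anchor landmark CSV files
#'
#' The on-disk format is a plain CSV with header `name,x,y,z`, coordinates in
#' mm, rows in the fixed anchor order.
#'
#' @param path CSV path.
#' @return [read_anchors()] returns a validated anchor tibble;
#'   [write_anchors()] returns `path` invisibly.
#' @export
read_anchors <- function(path) {
  anchor_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_anchors
#' @param anchors an anchor table accepted by [anchor_set()].
#' @export
write_anchors <- function(anchors, path) {
  utils::write.csv(anchor_set(anchors), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# anchor coordinates as a bare 8x3 matrix
anchor_matrix <- function(anchors) {
  a <- anchor_set(anchors)
  cbind(a$x, a$y, a$z)
}
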