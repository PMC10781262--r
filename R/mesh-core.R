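#' Triangle mesh container
#'
#' The universal geometry carrier of the package: a set of 3D vertices in
#' millimetres (world frame, +Y up along the body, +X subject-left, +Z toward
#' the default camera) and counter-clockwise triangular faces given as 1-based
#' vertex index triples.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `trimesh` with elements `vertices` and `faces`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' n_vertices(m)
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  obj <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  validate_trimesh(obj)
  obj
}

#' Validate triangle-mesh invariants
#'
#' Checks that all coordinates are finite, every face index is in range and
#' no face repeats a vertex index.
#'
#' @param mesh a `trimesh`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_trimesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L)
    stop("trimesh: vertices must be an n x 3 matrix", call. = FALSE)
  if (!is.matrix(f) || ncol(f) != 3L)
    stop("trimesh: faces must be an m x 3 matrix", call. = FALSE)
  if (!all(is.finite(v)))
    stop("trimesh: non-finite vertex coordinate", call. = FALSE)
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("trimesh: face index out of range [1, ", nrow(v), "]", call. = FALSE)
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("trimesh: face repeats a vertex index", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `trimesh`.
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Axis-aligned bounding box
#' @param mesh a `trimesh`.
#' @return 2 x 3 matrix, rows = min/max, columns x/y/z (mm).
#' @export
mesh_bbox <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}

#' Vertical extent of a mesh (body height), mm
#' @param mesh a `trimesh`.
#' @return Height in mm.
#' @export
mesh_height <- function(mesh) diff(range(mesh$vertices[, 2]))

#' Merge coincident vertices
#'
#' STL stores three loose vertices per triangle; downstream normal averaging
#' and edge collapse need shared connectivity, so vertices whose coordinates
#' agree within `tol` are merged into one.
#'
#' @param mesh a `trimesh`.
#' @param tol weld tolerance in mm (default 1e-6).
#' @return A `trimesh` with welded vertices; degenerate faces dropped.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- match(key, key)           # index of first occurrence
  keep <- !duplicated(key)
  newid <- cumsum(keep)              # new index for each first occurrence
  map <- newid[first]
  f <- matrix(map[mesh$faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  trimesh(v[keep, , drop = FALSE], f[!degen, , drop = FALSE])
}

#' Unit face normals
#' @param mesh a `trimesh`.
#' @return m x 3 matrix of unit normals; zero rows mark degenerate faces.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  ok <- len > 1e-12
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

# internal rigid/scaling helpers -------------------------------------------

mesh_translate <- function(mesh, delta) {
  trimesh(sweep(mesh$vertices, 2, delta, "+"), mesh$faces)
}

# rotate about the vertical axis through (cx, cz); positive deg
# counter-clockwise when viewed from +Y
mesh_rotate_y <- function(mesh, deg, center = NULL) {
  v <- mesh$vertices
  if (is.null(center)) {
    bb <- mesh_bbox(mesh)
    center <- c(mean(bb[, 1]), mean(bb[, 3]))
  }
  th <- deg * pi / 180
  x <- v[, 1] - center[1]
  z <- v[, 3] - center[2]
  v2 <- cbind(cos(th) * x + sin(th) * z,
              v[, 2],
              -sin(th) * x + cos(th) * z)
  v2[, 1] <- v2[, 1] + center[1]
  v2[, 3] <- v2[, 3] + center[2]
  trimesh(v2, mesh$faces)
}

mesh_scale_about <- function(mesh, s, center) {
  v <- sweep(mesh$vertices, 2, center)
  trimesh(sweep(v * s, 2, center, "+"), mesh$faces)
}

# concatenate closed parts (no weld across parts)
mesh_concat <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  vs <- lapply(parts, `[[`, "vertices")
  fs <- lapply(parts, `[[`, "faces")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  f <- do.call(rbind, Map(function(fi, o) fi + o, fs, off[seq_along(fs)]))
  trimesh(do.call(rbind, vs), f)
}
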