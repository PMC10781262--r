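# STL (binary + ASCII) and Wavefront OBJ readers/writers, geometry only.
# Colors, textures, normals and materials are deliberately ignored: only the
# 3D geometry is needed to derive body values, which is why the scan archive
# is converted to STL in the first place.

.unit_scale <- function(unit = c("mm", "cm", "m")) {
  switch(match.arg(unit), mm = 1, cm = 10, m = 1000)
}

#' Read an STL mesh (binary or ASCII)
#'
#' The dialect is detected from the file itself: a file whose size matches
#' the binary layout (80-byte header + uint32 triangle count + 50 bytes per
#' triangle) is read as binary, otherwise a leading `solid` token selects the
#' ASCII dialect. Per-triangle vertices are welded into shared connectivity
#' (tolerance 1e-6 mm) so that vertex-normal averaging and decimation work.
#'
#' @param path file path.
#' @param unit unit of the stored coordinates; rescaled to mm on load.
#' @return A [trimesh].
#' @export
read_stl <- function(path, unit = "mm") {
  if (!file.exists(path)) stop("read_stl: no such file: ", path, call. = FALSE)
  size <- file.size(path)
  if (size < 15) stop("read_stl: file too short (", size, " bytes)", call. = FALSE)
  head_raw <- readBin(path, "raw", n = min(size, 84))
  is_binary <- FALSE
  if (size >= 84) {
    count <- readBin(head_raw[81:84], "integer", size = 4, endian = "little")
    if (!is.na(count) && count >= 0 && size == 84 + 50 * as.double(count))
      is_binary <- TRUE
  }
  if (is_binary) return(.read_stl_binary(path, size, unit))
  lead <- rawToChar(head_raw[1:5])
  if (identical(tolower(lead), "solid")) return(.read_stl_ascii(path, unit))
  stop("read_stl: not an STL file (no 'solid' token and size ", size,
       " does not match the binary layout)", call. = FALSE)
}

.read_stl_binary <- function(path, size, unit) {
  ntri <- readBin(readBin(path, "raw", n = 84)[81:84], "integer",
                  size = 4, endian = "little")
  expected <- 84 + 50 * as.double(ntri)
  if (size != expected)
    stop("read_stl: truncated binary record at byte ", size,
         " (expected ", expected, " bytes for ", ntri, " triangles)",
         call. = FALSE)
  raw <- readBin(path, "raw", n = size)
  body <- raw[-(1:84)]
  # 50-byte records: 12 float32 (normal + 3 vertices) + uint16 attribute
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                    n = 12L * ntri, size = 4, endian = "little")
  fm <- matrix(floats, nrow = 12)           # col = triangle
  verts <- matrix(as.vector(fm[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  m <- weld_vertices(trimesh(verts * .unit_scale(unit), faces))
  m
}

.read_stl_ascii <- function(path, unit) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0)
    stop("read_stl: no vertex records in ASCII STL", call. = FALSE)
  if (length(vl) %% 3 != 0)
    stop("read_stl: malformed facet block near line ", vl[length(vl)],
         " (vertex count ", length(vl), " is not a multiple of 3)",
         call. = FALSE)
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(lengths(toks) != 4)
  if (length(bad))
    stop("read_stl: malformed vertex record at line ", vl[bad[1]], call. = FALSE)
  nums <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3, byrow = TRUE))
  if (any(!is.finite(nums))) {
    bad <- which(rowSums(!is.finite(nums)) > 0)[1]
    stop("read_stl: non-numeric vertex at line ", vl[bad], call. = FALSE)
  }
  ntri <- length(vl) %/% 3
  faces <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  weld_vertices(trimesh(nums * .unit_scale(unit), faces))
}

#' Write a mesh as STL
#'
#' @param mesh a [trimesh].
#' @param path output file path.
#' @param dialect `"binary"` (84 + 50 bytes/triangle, float32 coordinates,
#'   the conventional precision) or `"ascii"`.
#' @return Invisibly `path`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  validate_trimesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  if (dialect == "ascii") {
    blocks <- sprintf(
      paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
             "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
             "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
      n[, 1], n[, 2], n[, 3],
      v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
      v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
      v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
    ok <- tryCatch({
      writeLines(c("solid anthromesh", blocks, "endsolid anthromesh"), path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("write_stl: cannot write ", path, call. = FALSE)
    return(invisible(path))
  }
  header <- raw(80)
  tag <- charToRaw("anthromesh binary STL")
  header[seq_along(tag)] <- tag
  # 12 float32 per triangle: normal, v1, v2, v3 (row-per-triangle layout)
  dat <- t(cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE]))
  fr <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
  rec <- rbind(matrix(fr, nrow = 48), as.raw(0), as.raw(0))
  ok <- tryCatch({
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(header, con)
    writeBin(nrow(f), con, size = 4, endian = "little")
    writeBin(as.vector(rec), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("write_stl: cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (geometry only)
#'
#' Loads `v` and `f` records; texture (`vt`), normal (`vn`), material and
#' color records are ignored. Faces may use `v`, `v/vt`, `v/vt/vn` or
#' `v//vn` syntax; polygons are fan-triangulated and negative indices are
#' resolved relative to the vertices defined so far, per the OBJ convention.
#'
#' @param path file path.
#' @param unit unit of the stored coordinates; rescaled to mm on load.
#' @return A [trimesh].
#' @export
read_obj <- function(path, unit = "mm") {
  if (!file.exists(path)) stop("read_obj: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  is_v <- grepl("^v\\s", lines)
  is_f <- grepl("^f\\s", lines)
  if (!any(is_v)) stop("read_obj: no vertex records", call. = FALSE)
  if (!any(is_f)) stop("read_obj: zero faces (empty mesh)", call. = FALSE)
  vtok <- strsplit(trimws(lines[is_v]), "\\s+")
  verts <- matrix(as.numeric(unlist(lapply(vtok, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
  if (any(!is.finite(verts)))
    stop("read_obj: non-numeric vertex record", call. = FALSE)
  # vertices defined before each f line, for negative-index resolution
  vcount_at <- cumsum(is_v)
  f_lines <- which(is_f)
  ftok <- strsplit(trimws(lines[f_lines]), "\\s+")
  faces_list <- vector("list", length(ftok))
  for (i in seq_along(ftok)) {
    refs <- ftok[[i]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", refs)))
    if (any(is.na(idx)))
      stop("read_obj: malformed face record at line ", f_lines[i], call. = FALSE)
    before <- vcount_at[f_lines[i]]
    idx <- ifelse(idx < 0, before + idx + 1L, idx)
    if (any(idx < 1L | idx > nrow(verts)))
      stop("read_obj: face index out of range at line ", f_lines[i],
           call. = FALSE)
    k <- length(idx)
    if (k < 3)
      stop("read_obj: face with fewer than 3 vertices at line ", f_lines[i],
           call. = FALSE)
    faces_list[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])  # fan rule
  }
  trimesh(verts * .unit_scale(unit), do.call(rbind, faces_list))
}

#' Write a mesh as Wavefront OBJ (geometry only)
#' @param mesh a [trimesh].
#' @param path output file path.
#' @return Invisibly `path`.
#' @export
write_obj <- function(mesh, path) {
  validate_trimesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}
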