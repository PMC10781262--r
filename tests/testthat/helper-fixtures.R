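# fixtures shared across test files; everything is generated in code

unit_triangle_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

cylinder_fixture <- function(r = 100, h = 300, sides = 256, rings = 2) {
  make_primitive("cylinder", c(r, h), profile_sides = sides, rings = rings)
}

# hand-written ASCII STL of a single unit triangle (independent of write_stl)
write_ascii_stl_triangle <- function(path) {
  writeLines(c(
    "solid tri",
    "facet normal 0 0 1",
    " outer loop",
    "  vertex 0 0 0",
    "  vertex 1 0 0",
    "  vertex 0 1 0",
    " endloop",
    "endfacet",
    "endsolid tri"), path)
  path
}

# hand-written binary STL of a unit cube (12 triangles, duplicated vertices)
write_binary_stl_cube <- function(path) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(5, 6, 7), c(5, 7, 8), c(2, 1, 4), c(2, 4, 3),
             c(1, 5, 8), c(1, 8, 4), c(6, 2, 3), c(6, 3, 7),
             c(8, 7, 3), c(8, 3, 4), c(1, 2, 6), c(1, 6, 5))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(nrow(f), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    writeBin(as.numeric(c(0, 0, 0, t(tri))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  path
}

read_obj_text <- function(lines) {
  path <- tempfile(fileext = ".obj")
  on.exit(unlink(path))
  writeLines(lines, path)
  read_obj(path)
}

cube_obj_lines <- function() {
  c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
    "f 5 6 7", "f 5 7 8", "f 2 1 4", "f 2 4 3",
    "f 1 5 8", "f 1 8 4", "f 6 2 3", "f 6 3 7",
    "f 8 7 3", "f 8 3 4", "f 1 2 6", "f 1 6 5")
}

# a rectangle mask depth map (for width-profile phantoms)
mask_depth_map <- function(mask, cfg = camera_config()) {
  depth_map(ifelse(mask, 200L, 0L), camera = cfg)
}

# hand-built seeds for a cylinder "torso" phantom (r ~ 150, h = 1000 mm)
synthetic_cylinder_seeds <- function() {
  nms <- anthromesh:::SEED_POINT_NAMES
  world <- matrix(0, 11, 3, dimnames = list(nms, NULL))
  world["head_top", ] <- c(0, 1000, 0)
  world["neck", ] <- c(0, 800, 0)
  world["left_shoulder", ] <- c(-100, 780, 0)
  world["right_shoulder", ] <- c(100, 780, 0)
  world["left_armpit", ] <- c(-120, 750, 0)
  world["right_armpit", ] <- c(120, 750, 0)
  world["left_fingertip", ] <- c(-120, 400, 0)
  world["right_fingertip", ] <- c(120, 400, 0)
  world["left_toe", ] <- c(-50, 0, 0)
  world["right_toe", ] <- c(50, 0, 0)
  world["crotch", ] <- c(0, 300, 0)
  structure(list(points = NULL, world = world,
                 world_heights = stats::setNames(world[, 2], nms)),
            class = "seed_points")
}

scale_seeds <- function(seeds, s) {
  seeds$world <- seeds$world * s
  seeds$world_heights <- seeds$world_heights * s
  seeds
}

# default humanoid + frontal render, built once per test run
default_humanoid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      h <- make_humanoid(body_params())
      dm <- render_depth_map(h$mesh, camera_config(), 512, 512)
      cache <<- list(body = h, dm = dm, seeds = detect_seed_points(dm))
    }
    cache
  }
})
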