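# Perspective camera model, depth-map rendering and the 8-view snapshot
# generator. The camera sits at a configurable height above the floor and
# horizontal distance from the subject, looks along -Z, and maps camera-space
# depth into grayscale: near = bright, background = 0, so the subject stands
# out bright on black.

#' Perspective camera configuration
#'
#' @param fovy vertical field of view, degrees (0 < fovy < 180).
#' @param aspect width/height ratio of the image plane.
#' @param near_n near clipping distance, mm.
#' @param far_f far clipping distance, mm (> near_n).
#' @param cam_height camera height above the floor, metres.
#' @param cam_distance horizontal camera-to-subject distance, metres. The
#'   default placement (1 m, 3 m) is the error-minimizing placement on the
#'   reference camera grid; see [select_camera()].
#' @param yaw subject rotation about the vertical axis, degrees (0 = frontal).
#' @return A `camera_config` object.
#' @export
camera_config <- function(fovy = 40, aspect = 1, near_n = 1000, far_f = 6000,
                          cam_height = 1, cam_distance = 3, yaw = 0) {
  if (!(fovy > 0 && fovy < 180))
    stop("camera_config: fovy must be in (0, 180) degrees", call. = FALSE)
  if (aspect <= 0) stop("camera_config: aspect must be positive", call. = FALSE)
  if (!(near_n > 0 && near_n < far_f))
    stop("camera_config: need 0 < near_n < far_f", call. = FALSE)
  if (cam_distance <= 0)
    stop("camera_config: cam_distance must be positive", call. = FALSE)
  structure(list(fovy = fovy, aspect = aspect, near_n = near_n, far_f = far_f,
                 cam_height = cam_height, cam_distance = cam_distance,
                 yaw = yaw),
            class = "camera_config")
}

#' Perspective projection matrix
#'
#' The symmetric frustum matrix mapping camera-frame homogeneous points
#' (looking along -Z) to clip space. `m[1,1] = cot(fovy/2)/aspect`,
#' `m[2,2] = cot(fovy/2)` and the bottom row is `(0, 0, -1, 0)`; the
#' canonical projection plane therefore sits at `z = -cot(fovy/2)` for a
#' unit-height view volume.
#'
#' @param cfg a [camera_config()].
#' @return 4 x 4 numeric matrix.
#' @export
perspective_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "camera_config"))
  ct <- 1 / tan(cfg$fovy * pi / 360)    # cot(fovy/2)
  if (!is.finite(ct) || ct <= 0)
    stop("perspective_matrix: degenerate fovy", call. = FALSE)
  n <- cfg$near_n
  f <- cfg$far_f
  m <- matrix(0, 4, 4)
  m[1, 1] <- ct / cfg$aspect
  m[2, 2] <- ct
  m[3, 3] <- -(f + n) / (f - n)
  m[3, 4] <- -2 * f * n / (f - n)
  m[4, 3] <- -1
  m
}

#' Depth-map container
#'
#' `pixels` holds 8-bit intensities (0 = background; nearer surfaces are
#' brighter), `world_depth` the unquantized camera-space depth in mm used for
#' back-projection, and the camera metadata ties pixels back to world
#' coordinates. Row 1 is the top of the image.
#'
#' @param pixels integer H x W matrix, values 0-255.
#' @param camera a [camera_config()].
#' @param world_depth numeric H x W matrix of camera-space depths (mm),
#'   0 = background. Defaults to the camera distance at every silhouette
#'   pixel, which is adequate for silhouette-only phantoms.
#' @param cam_pos camera position in world coordinates (mm).
#' @return A `depth_map` object.
#' @export
depth_map <- function(pixels, camera = camera_config(), world_depth = NULL,
                      cam_pos = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (is.null(world_depth)) {
    world_depth <- matrix(0, nrow(pixels), ncol(pixels))
    world_depth[pixels > 0] <- camera$cam_distance * 1000
  }
  if (is.null(cam_pos))
    cam_pos <- c(0, camera$cam_height * 1000, camera$cam_distance * 1000)
  if (any(pixels > 0 & !(world_depth > 0)))
    stop("depth_map: every nonzero pixel needs a finite world depth",
         call. = FALSE)
  structure(list(pixels = pixels, world_depth = world_depth, camera = camera,
                 cam_pos = cam_pos, width = ncol(pixels),
                 height = nrow(pixels), row0_is_top = TRUE,
                 empty_frustum = !any(pixels > 0)),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d px, %d silhouette px, camera %.2g m / %.2g m, yaw %g deg\n",
              x$height, x$width, sum(x$pixels > 0),
              x$camera$cam_height, x$camera$cam_distance, x$camera$yaw))
  invisible(x)
}

#' Render a perspective depth map of a mesh
#'
#' CPU z-buffer rasterization: the nearest surface wins each pixel, the
#' intensity maps camera depth linearly from `[near_n, far_f]` to
#' `[255, 1]` (nearer = brighter) and background stays 0. The camera is
#' placed at `cam_height` above the mesh floor and `cam_distance` in front
#' of the subject's horizontal centre, looking horizontally along -Z; a
#' nonzero `yaw` in the camera configuration rotates the subject about its
#' vertical axis first.
#'
#' @param mesh a [trimesh].
#' @param cfg a [camera_config()].
#' @param width,height image resolution in pixels (at least 16).
#' @return A [depth_map()]; if the mesh is entirely outside the frustum the
#'   map is all-zero and its `empty_frustum` flag is set.
#' @export
render_depth_map <- function(mesh, cfg = camera_config(), width = 512,
                             height = 512) {
  validate_trimesh(mesh)
  if (n_faces(mesh) == 0) stop("render_depth_map: empty mesh", call. = FALSE)
  if (width < 16 || height < 16)
    stop("render_depth_map: resolution must be at least 16 x 16", call. = FALSE)
  if (cfg$yaw != 0) mesh <- mesh_rotate_y(mesh, cfg$yaw)
  bb <- mesh_bbox(mesh)
  cam_pos <- c(mean(bb[, 1]), bb[1, 2] + cfg$cam_height * 1000,
               mean(bb[, 3]) + cfg$cam_distance * 1000)
  v <- sweep(mesh$vertices, 2, cam_pos)   # camera frame: look along -Z
  ct <- 1 / tan(cfg$fovy * pi / 360)
  w <- -v[, 3]
  # screen coordinates; vertices behind the camera are culled per-face in C++
  safe_w <- ifelse(w > 1e-9, w, 1e-9)
  ndc_x <- (ct / cfg$aspect) * v[, 1] / safe_w
  ndc_y <- ct * v[, 2] / safe_w
  px <- (ndc_x + 1) / 2 * width
  py <- (1 - ndc_y) / 2 * height
  wd <- rasterize_depth(px, py, v[, 3], mesh$faces, width, height)
  pix <- matrix(0L, height, width)
  nz <- wd > 0
  if (any(nz)) {
    g <- 255 - (wd[nz] - cfg$near_n) / (cfg$far_f - cfg$near_n) * 254
    pix[nz] <- as.integer(pmin(255, pmax(1, round(g))))
  } else {
    warning("render_depth_map: mesh entirely outside the camera frustum")
  }
  depth_map(pix, camera = cfg, world_depth = wd, cam_pos = cam_pos)
}

#' Multi-view snapshot set
#'
#' Rotates the subject in `step_deg` increments about its vertical axis and
#' renders one depth map per view; the default 45-degree step yields the
#' standard 8-view capture (view 1 frontal).
#'
#' @param mesh a [trimesh].
#' @param cfg a [camera_config()].
#' @param step_deg rotation step; must divide 360.
#' @param width,height image resolution.
#' @return List of `360 / step_deg` [depth_map()] objects.
#' @export
multi_view_snapshots <- function(mesh, cfg = camera_config(), step_deg = 45,
                                 width = 512, height = 512) {
  if (step_deg <= 0 || 360 %% step_deg != 0)
    stop("multi_view_snapshots: step_deg must divide 360", call. = FALSE)
  lapply(seq(0, 360 - step_deg, by = step_deg), function(a) {
    cfg_k <- cfg
    cfg_k$yaw <- cfg$yaw + a
    render_depth_map(mesh, cfg_k, width, height)
  })
}

#' Back-project a depth-map pixel to a 3D world point
#'
#' Casts the pixel's ray through the camera using the stored unquantized
#' depth. Re-projecting the returned point lands in the same pixel. The
#' returned point is in the frame of the (possibly yawed) subject as seen by
#' the camera; its Y coordinate is the world height either way.
#'
#' @param dm a [depth_map()].
#' @param row,col 1-based pixel indices; the pixel must be on the silhouette.
#' @return Numeric length-3 world point, mm.
#' @export
back_project <- function(dm, row, col) {
  d <- dm$world_depth[row, col]
  if (!(d > 0))
    stop("back_project: background pixel (", row, ", ", col,
         ") has no depth", call. = FALSE)
  cfg <- dm$camera
  ct <- 1 / tan(cfg$fovy * pi / 360)
  ndc_x <- 2 * (col - 0.5) / dm$width - 1
  ndc_y <- 1 - 2 * (row - 0.5) / dm$height
  xc <- ndc_x * d * cfg$aspect / ct
  yc <- ndc_y * d / ct
  dm$cam_pos + c(xc, yc, -d)
}

# world height (Y, mm) of a landmark pixel; falls back to the nearest
# silhouette pixel within a small window when the exact pixel lacks depth
.pixel_world_height <- function(dm, row, col, win = 2L) {
  if (dm$world_depth[row, col] > 0) return(back_project(dm, row, col)[2])
  rows <- max(1, row - win):min(dm$height, row + win)
  cols <- max(1, col - win):min(dm$width, col + win)
  sub <- dm$world_depth[rows, cols, drop = FALSE]
  idx <- which(sub > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  d2 <- (rows[idx[, 1]] - row)^2 + (cols[idx[, 2]] - col)^2
  k <- which.min(d2)
  back_project(dm, rows[idx[k, 1]], cols[idx[k, 2]])[2]
}

#' Save / load a depth map
#'
#' Writes three sibling files: `<stem>.png` (8-bit grayscale for display),
#' `<stem>.depth.png` (16-bit depth channel scaled over `[near_n, far_f]`)
#' and `<stem>.json` (camera metadata), so a reloaded map supports
#' back-projection with sub-0.1 mm depth fidelity.
#'
#' @param dm a [depth_map()].
#' @param stem output path without extension.
#' @return Invisibly the PNG path.
#' @export
save_depth_map <- function(dm, stem) {
  png::writePNG(dm$pixels / 255, paste0(stem, ".png"))
  cfg <- dm$camera
  dnorm <- (dm$world_depth - cfg$near_n) / (cfg$far_f - cfg$near_n)
  dnorm[dm$world_depth <= 0] <- 0
  dnorm[dnorm < 0] <- 0
  dnorm[dnorm > 1] <- 1
  # 16-bit depth split across two 8-bit channels (high byte in R, low in G)
  q <- round(dnorm * 65535)
  depth_rgb <- array(0, c(nrow(q), ncol(q), 3))
  depth_rgb[, , 1] <- (q %/% 256) / 255
  depth_rgb[, , 2] <- (q %% 256) / 255
  png::writePNG(depth_rgb, paste0(stem, ".depth.png"))
  meta <- c(unclass(cfg), list(cam_pos = dm$cam_pos,
                               width = dm$width, height = dm$height))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".png"))
}

#' @rdname save_depth_map
#' @return `load_depth_map()` returns the reconstructed [depth_map()].
#' @export
load_depth_map <- function(stem) {
  pix <- round(png::readPNG(paste0(stem, ".png")) * 255)
  if (length(dim(pix)) == 3) pix <- pix[, , 1]
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cfg <- camera_config(fovy = meta$fovy, aspect = meta$aspect,
                       near_n = meta$near_n, far_f = meta$far_f,
                       cam_height = meta$cam_height,
                       cam_distance = meta$cam_distance, yaw = meta$yaw)
  depth_path <- paste0(stem, ".depth.png")
  if (file.exists(depth_path)) {
    dn <- png::readPNG(depth_path)
    dn <- (round(dn[, , 1] * 255) * 256 + round(dn[, , 2] * 255)) / 65535
    wd <- cfg$near_n + dn * (cfg$far_f - cfg$near_n)
    wd[pix == 0] <- 0
  } else {
    # invert the display intensity map (coarser quantization)
    wd <- cfg$near_n + (255 - pix) / 254 * (cfg$far_f - cfg$near_n)
    wd[pix == 0] <- 0
  }
  depth_map(pix, camera = cfg, world_depth = wd, cam_pos = meta$cam_pos)
}
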