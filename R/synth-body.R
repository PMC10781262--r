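# Parametric A-pose humanoid generator with analytic ground truth.
# Stands in for full-body scan subjects at desk scale: a lofted elliptical
# torso with controllable chest/waist/hip girths, an ellipsoid head on a
# neck cylinder (creating the top-30% width minimum), abducted cylindrical
# arms and parted cylindrical legs, so the armpit- and crotch-gap landmark
# rules are exercisable and every measurement has a closed-form truth.
# Profiles are polygons (256-gon by default), which makes ground-truth
# perimeters exact polygon sums rather than elliptic integrals.

# perimeter / area of the n-gon inscribed in an axis-aligned ellipse
.pgon_perimeter <- function(a, b, n) {
  th <- 2 * pi * (0:(n - 1)) / n
  pts <- cbind(a * cos(th), b * sin(th))
  nxt <- rbind(pts[-1, ], pts[1, ])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

.pgon_area <- function(a, b, n) 0.5 * n * a * b * sin(2 * pi / n)

.ellipse_ring <- function(a, b, y, n, cx = 0, cz = 0) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(cx + a * cos(th), y, cz + b * sin(th))
}

# loft a stack of same-size rings (bottom to top) into a closed mesh
.loft_rings <- function(rings, cap_bottom = TRUE, cap_top = TRUE) {
  n <- nrow(rings[[1]])
  K <- length(rings)
  verts <- do.call(rbind, rings)
  faces <- vector("list", K - 1)
  j <- seq_len(n)
  jn <- c(2:n, 1L)
  for (k in seq_len(K - 1)) {
    lo <- (k - 1L) * n
    hi <- k * n
    faces[[k]] <- rbind(cbind(lo + j, hi + j, lo + jn),
                        cbind(hi + j, hi + jn, lo + jn))
  }
  faces <- do.call(rbind, faces)
  if (cap_bottom) {
    cb <- colMeans(rings[[1]])
    verts <- rbind(verts, cb)
    ci <- nrow(verts)
    faces <- rbind(faces, cbind(ci, j, jn))       # outward -Y
  }
  if (cap_top) {
    ct <- colMeans(rings[[K]])
    verts <- rbind(verts, ct)
    ci <- nrow(verts)
    top <- (K - 1L) * n
    faces <- rbind(faces, cbind(ci, top + jn, top + j))  # outward +Y
  }
  trimesh(verts, faces)
}

# closed cylinder along an arbitrary axis; `round_p1` closes the p1 end
# with a hemispherical cap (whose horizontal slices stay single intervals,
# unlike a tilted flat cap rim)
.cylinder_axis <- function(p0, p1, radius, n, rings = 2, round_p1 = FALSE) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  d <- d / len
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(d[2] * ref[3] - d[3] * ref[2],
          d[3] * ref[1] - d[1] * ref[3],
          d[1] * ref[2] - d[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  th <- 2 * pi * (0:(n - 1)) / n
  circle <- outer(cos(th), e1) + outer(sin(th), e2)   # n x 3
  stations <- seq(0, len, length.out = max(2, rings))
  rr <- lapply(stations, function(s) {
    sweep(circle * radius, 2, p0 + s * d, "+")
  })
  if (round_p1) {
    phi <- seq(0, pi / 2, length.out = 8)[-c(1, 8)]
    rr <- c(rr, lapply(phi, function(ph) {
      sweep(circle * radius * cos(ph), 2,
            p0 + (len + radius * sin(ph)) * d, "+")
    }))
  }
  .loft_rings(rr, cap_bottom = TRUE, cap_top = TRUE)
}

# UV ellipsoid with semi-axes (ax, ay, az), centred at `center`
.ellipsoid_mesh <- function(ax, ay, az, center = c(0, 0, 0), n = 64,
                            stacks = NULL) {
  if (is.null(stacks)) stacks <- max(8, n %/% 2)
  phi <- seq(-pi / 2, pi / 2, length.out = stacks + 1)[-c(1, stacks + 1)]
  th <- 2 * pi * (0:(n - 1)) / n
  rings <- lapply(phi, function(p) {
    cbind(center[1] + ax * cos(p) * cos(th),
          center[2] + ay * sin(p),
          center[3] + az * cos(p) * sin(th))
  })
  m <- .loft_rings(rings, cap_bottom = FALSE, cap_top = FALSE)
  # pole fans
  vb <- rbind(m$vertices,
              c(center[1], center[2] - ay, center[3]),
              c(center[1], center[2] + ay, center[3]))
  ib <- nrow(vb) - 1L
  it <- nrow(vb)
  j <- seq_len(n)
  jn <- c(2:n, 1L)
  top0 <- (length(rings) - 1L) * n
  f <- rbind(m$faces,
             cbind(ib, j, jn),
             cbind(it, top0 + jn, top0 + j))
  trimesh(vb, f)
}

#' Geometric primitive with analytic ground truth
#'
#' Oracle fixtures for the measurement pipeline: closed meshes whose
#' circumferences and volumes follow from closed forms (inscribed-polygon
#' perimeter and area for the cylinder, exact box measures, the ellipsoid
#' volume 4/3*pi*a*b*c).
#'
#' @param kind `"cylinder"` (dims = radius, height), `"box"`
#'   (dims = dx, dy, dz) or `"ellipsoid"` (dims = semi-axes x, y, z), mm.
#' @param dims numeric dimensions, mm (positive).
#' @param profile_sides polygon resolution of round profiles.
#' @param rings number of rings along a cylinder (densifies the mesh).
#' @return List with `mesh` ([trimesh]) and `truth` (a `ground_truth`:
#'   `circumference_cm` at mid-height, `volume_l`, `height_cm`).
#' @export
make_primitive <- function(kind = c("cylinder", "ellipsoid", "box"), dims,
                           profile_sides = 256, rings = 2) {
  kind <- match.arg(kind)
  if (any(dims <= 0)) stop("make_primitive: dimensions must be positive",
                           call. = FALSE)
  n <- profile_sides
  if (kind == "cylinder") {
    r <- dims[1]
    h <- dims[2]
    rr <- lapply(seq(0, h, length.out = max(2, rings)), function(y)
      .ellipse_ring(r, r, y, n))
    mesh <- .loft_rings(rr)
    truth <- list(circumference_cm = .pgon_perimeter(r, r, n) / 10,
                  volume_l = .pgon_area(r, r, n) * h / 1e6,
                  height_cm = h / 10)
  } else if (kind == "box") {
    dx <- dims[1] / 2
    dy <- dims[2] / 2
    dz <- dims[3] / 2
    v <- rbind(c(-dx, 0, -dz), c(dx, 0, -dz), c(dx, 2 * dy, -dz),
               c(-dx, 2 * dy, -dz), c(-dx, 0, dz), c(dx, 0, dz),
               c(dx, 2 * dy, dz), c(-dx, 2 * dy, dz))
    f <- rbind(c(5, 6, 7), c(5, 7, 8), c(2, 1, 4), c(2, 4, 3),
               c(1, 5, 8), c(1, 8, 4), c(6, 2, 3), c(6, 3, 7),
               c(8, 7, 3), c(8, 3, 4), c(1, 2, 6), c(1, 6, 5))
    mesh <- trimesh(v, f)
    truth <- list(circumference_cm = 2 * (dims[1] + dims[3]) / 10,
                  volume_l = prod(dims) / 1e6,
                  height_cm = dims[2] / 10)
  } else {
    ax <- dims[1]
    ay <- dims[2]
    az <- dims[3]
    mesh <- .ellipsoid_mesh(ax, ay, az, center = c(0, ay, 0), n = n)
    truth <- list(circumference_cm = .pgon_perimeter(ax, az, n) / 10,
                  volume_l = 4 / 3 * pi * ax * ay * az / 1e6,
                  height_cm = 2 * ay / 10)
  }
  list(mesh = mesh, truth = structure(truth, class = "ground_truth"))
}

# vertical placement of body features, as fractions of stature
# the shoulder (full-width) level sits above the top of the abducted arm so
# the neck-to-shoulder taper is not interrupted by the arm cap
.BODY_LEVELS <- c(crotch = 0.47, hip = 0.53, waist = 0.62, chest = 0.72,
                  shoulder = 0.81, neck_base = 0.84, neck_top = 0.90,
                  head_center = 0.94)

#' Parameters of the synthetic A-pose humanoid
#'
#' Defaults describe a 1.70 m adult with chest/waist/hip girths of
#' 100/85/98 cm. The pose is mandatory-A: arm abduction above 10 degrees
#' guarantees the armpit gap and a positive stance gap guarantees the
#' crotch gap that the landmark rules require.
#'
#' @param height stature, mm.
#' @param chest_girth,waist_girth,hip_girth torso control girths, cm
#'   (body-plan invariant: waist smaller than chest and hip).
#' @param torso_aspect depth/width ratio of the torso ellipses.
#' @param head_radius,neck_radius,arm_radius mm; default scale with height.
#' @param arm_length shoulder-to-fingertip length, mm.
#' @param abduction_deg arm abduction from vertical, degrees (> 10).
#' @param stance_halfgap half the gap between the inner leg surfaces, mm.
#' @param profile_sides torso profile polygon resolution.
#' @param limb_sides limb profile polygon resolution.
#' @return A `body_params` object.
#' @export
body_params <- function(height = 1700, chest_girth = 100, waist_girth = 85,
                        hip_girth = 98, torso_aspect = 0.7,
                        head_radius = NULL, neck_radius = NULL,
                        arm_radius = NULL, arm_length = NULL,
                        abduction_deg = 25, stance_halfgap = NULL,
                        profile_sides = 256, limb_sides = 128) {
  s <- height / 1700
  if (is.null(head_radius)) head_radius <- 90 * s
  if (is.null(neck_radius)) neck_radius <- 51 * s
  if (is.null(arm_radius)) arm_radius <- 45 * s
  if (is.null(arm_length)) arm_length <- 0.38 * height
  if (is.null(stance_halfgap)) stance_halfgap <- 0.015 * height
  p <- list(height = height, chest_girth = chest_girth,
            waist_girth = waist_girth, hip_girth = hip_girth,
            torso_aspect = torso_aspect, head_radius = head_radius,
            neck_radius = neck_radius, arm_radius = arm_radius,
            arm_length = arm_length, abduction_deg = abduction_deg,
            stance_halfgap = stance_halfgap, profile_sides = profile_sides,
            limb_sides = limb_sides)
  if (height <= 0) stop("body_params: height must be positive", call. = FALSE)
  if (!(waist_girth < chest_girth && waist_girth < hip_girth))
    stop("body_params: the waist girth must be smaller than both the chest ",
         "and hip girths (default body plan)", call. = FALSE)
  if (abduction_deg <= 10)
    stop("body_params: abduction must exceed 10 degrees so the armpit gap ",
         "is visible", call. = FALSE)
  if (stance_halfgap <= 0)
    stop("body_params: stance gap must be positive so the crotch gap is ",
         "visible", call. = FALSE)
  if (neck_radius >= head_radius)
    stop("body_params: neck must be thinner than the head", call. = FALSE)
  structure(p, class = "body_params")
}

# piecewise cosine interpolation through (x0, y0) control points; flat
# slope at every control, so controls are true local extrema of the profile
.cos_interp <- function(x, xs, ys) {
  out <- numeric(length(x))
  out[x <= xs[1]] <- ys[1]
  out[x >= xs[length(xs)]] <- ys[length(ys)]
  for (k in seq_len(length(xs) - 1)) {
    sel <- x > xs[k] & x < xs[k + 1]
    if (!any(sel)) next
    t <- (x[sel] - xs[k]) / (xs[k + 1] - xs[k])
    out[sel] <- ys[k] + (ys[k + 1] - ys[k]) * (1 - cos(pi * t)) / 2
  }
  exact <- match(x, xs)
  hit <- !is.na(exact)
  out[hit] <- ys[exact[hit]]
  out
}

# torso semi-axis profile functions and derived construction quantities
.humanoid_plan <- function(p) {
  H <- p$height
  n <- p$profile_sides
  lv <- .BODY_LEVELS * H
  unit_per <- .pgon_perimeter(1, p$torso_aspect, n)
  a_of_girth <- function(g_cm) g_cm * 10 / unit_per
  a_hip <- a_of_girth(p$hip_girth)
  a_waist <- a_of_girth(p$waist_girth)
  a_chest <- a_of_girth(p$chest_girth)
  a_sh <- 1.1 * a_chest
  b_sh <- 0.75 * p$torso_aspect * a_chest
  xs_t <- c(lv[["crotch"]], lv[["hip"]], lv[["waist"]], lv[["chest"]],
            lv[["shoulder"]])
  as_t <- c(0.96 * a_hip, a_hip, a_waist, a_chest, a_sh)
  bs_t <- c(0.96 * a_hip * p$torso_aspect, a_hip * p$torso_aspect,
            a_waist * p$torso_aspect, a_chest * p$torso_aspect, b_sh)
  a_prof <- function(y) .cos_interp(y, xs_t, as_t)
  b_prof <- function(y) .cos_interp(y, xs_t, bs_t)
  r_leg <- (0.96 * a_hip - p$stance_halfgap) / 2
  if (r_leg <= 0)
    stop("body_params: stance gap too wide for the hip girth", call. = FALSE)
  leg_x <- p$stance_halfgap + r_leg
  socket_y <- 0.79 * H
  socket_x <- 0.95 * a_sh
  alpha <- p$abduction_deg * pi / 180
  list(H = H, lv = lv, a_prof = a_prof, b_prof = b_prof, a_sh = a_sh,
       b_sh = b_sh, r_leg = r_leg, leg_x = leg_x, socket_y = socket_y,
       socket_x = socket_x, alpha = alpha)
}

#' Generate a synthetic A-pose humanoid with ground truth
#'
#' @param params a [body_params()] object.
#' @return List with `mesh` (a [trimesh], floor at y = 0), `truth`
#'   (a `ground_truth`: per-level circumferences in cm, chest slab volume in
#'   litres, landmark heights in mm) and `params`.
#' @export
make_humanoid <- function(params = body_params()) {
  stopifnot(inherits(params, "body_params"))
  p <- params
  pl <- .humanoid_plan(p)
  H <- pl$H
  n <- p$profile_sides
  nl <- p$limb_sides

  # torso + shoulder taper + neck as one loft
  ys_torso <- sort(unique(c(seq(pl$lv[["crotch"]], pl$lv[["shoulder"]],
                                length.out = 64), pl$lv[1:5])))
  rings <- lapply(ys_torso, function(y)
    .ellipse_ring(pl$a_prof(y), pl$b_prof(y), y, n))
  taper_y <- seq(pl$lv[["shoulder"]], pl$lv[["neck_base"]],
                 length.out = 9)[-1]
  tt <- (taper_y - pl$lv[["shoulder"]]) /
    (pl$lv[["neck_base"]] - pl$lv[["shoulder"]])
  sm <- (1 - cos(pi * tt)) / 2
  rings <- c(rings, lapply(seq_along(taper_y), function(i) {
    a <- pl$a_sh + (p$neck_radius - pl$a_sh) * sm[i]
    b <- pl$b_sh + (p$neck_radius - pl$b_sh) * sm[i]
    .ellipse_ring(a, b, taper_y[i], n)
  }))
  rings <- c(rings, list(.ellipse_ring(p$neck_radius, p$neck_radius,
                                       pl$lv[["neck_top"]], n)))
  torso <- .loft_rings(rings)

  head <- .ellipsoid_mesh(p$head_radius, 0.06 * H, 0.92 * p$head_radius,
                          center = c(0, pl$lv[["head_center"]], 0),
                          n = nl)

  legs <- lapply(c(-1, 1), function(s) {
    rr <- lapply(seq(0, 0.50 * H, length.out = 4), function(y)
      .ellipse_ring(pl$r_leg, pl$r_leg, y, nl, cx = s * pl$leg_x))
    .loft_rings(rr)
  })

  arms <- lapply(c(-1, 1), function(s) {
    d <- c(s * sin(pl$alpha), -cos(pl$alpha), 0)
    socket <- c(s * pl$socket_x, pl$socket_y, 0)
    tip <- socket + p$arm_length * d
    # tip -> socket, then a rounded deltoid cap at the shoulder end
    .cylinder_axis(tip, socket, p$arm_radius, nl, rings = 3, round_p1 = TRUE)
  })

  mesh <- mesh_concat(torso, head, legs[[1]], legs[[2]],
                      arms[[1]], arms[[2]])

  # ---- analytic ground truth -------------------------------------------
  # armpit: height where the arm's inner surface leaves the torso profile
  gap <- function(y) {
    pl$socket_x + (pl$socket_y - y) * tan(pl$alpha) -
      p$arm_radius / cos(pl$alpha) - pl$a_prof(y)
  }
  lo <- pl$lv[["waist"]]
  hi <- min(pl$socket_y, pl$lv[["shoulder"]])
  armpit_y <- if (gap(hi) > 0) hi else stats::uniroot(gap, c(lo, hi))$root
  # neck: height where the head silhouette narrows to the neck radius
  neck_y <- pl$lv[["head_center"]] -
    0.06 * H * sqrt(1 - (p$neck_radius / p$head_radius)^2)
  # chest slab volume between the waist and chest control levels (Simpson)
  nseg <- 400
  yv <- seq(pl$lv[["waist"]], pl$lv[["chest"]], length.out = nseg + 1)
  areas <- .pgon_area(pl$a_prof(yv), pl$b_prof(yv), n)
  wts <- c(1, rep(c(4, 2), length.out = nseg - 1), 1)
  vol_l <- sum(wts * areas) * (yv[2] - yv[1]) / 3 / 1e6

  truth <- structure(list(
    circumference_cm = c(chest = p$chest_girth, waist = p$waist_girth,
                         hip = p$hip_girth,
                         thigh = .pgon_perimeter(pl$r_leg, pl$r_leg, nl) / 10,
                         arm = .pgon_perimeter(p$arm_radius, p$arm_radius,
                                               nl) / 10),
    chest_volume_l = vol_l,
    landmark_heights_mm = c(head_top = H, neck = neck_y, armpit = armpit_y,
                            crotch = pl$lv[["crotch"]], toe = 0),
    height_cm = H / 10), class = "ground_truth")

  list(mesh = mesh, truth = truth, params = p)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Sample a population of synthetic humanoids
#'
#' Deterministic given `seed`; parameters are drawn uniformly (height
#' 1500-1900 mm, chest girth 80-115 cm, waist 60-105 cm, hip 80-115 cm)
#' with the body-plan invariant (waist at least 2 cm below chest and hip,
#' so the waist minimum is well defined) enforced by rejection. The global
#' RNG state is saved and restored.
#'
#' @param n number of subjects (>= 1).
#' @param seed RNG seed.
#' @return List of `n` humanoids as returned by [make_humanoid()].
#' @export
sample_population <- function(n, seed = 1) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      chest <- stats::runif(1, 80, 115)
      waist <- stats::runif(1, 60, 105)
      hip <- stats::runif(1, 80, 115)
      if (waist <= min(chest, hip) - 2) break
    }
    make_humanoid(body_params(height = stats::runif(1, 1500, 1900),
                              chest_girth = chest, waist_girth = waist,
                              hip_girth = hip))
  })
}

#' Write a paired mesh + multi-view dataset
#'
#' Emits the mesh as binary STL together with one depth-map PNG per view
#' (45-degree steps by default, eight views) and a JSON manifest linking
#' them — the pairing used to couple one 3D body dataset with its 2D
#' snapshot set.
#'
#' @param mesh a [trimesh].
#' @param out_dir writable output directory (created if missing).
#' @param cfg a [camera_config()].
#' @param step_deg view step, must divide 360.
#' @param width,height image resolution.
#' @return Invisibly the manifest list (`mesh`, `views` with angles/paths).
#' @export
paired_dataset <- function(mesh, out_dir, cfg = camera_config(),
                           step_deg = 45, width = 512, height = 512) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stl_path <- file.path(out_dir, "mesh.stl")
  write_stl(mesh, stl_path, "binary")
  views <- multi_view_snapshots(mesh, cfg, step_deg, width, height)
  angles <- seq(0, 360 - step_deg, by = step_deg)
  entries <- Map(function(dm, ang) {
    stem <- file.path(out_dir, sprintf("view_%03d", ang))
    save_depth_map(dm, stem)
    list(angle_deg = ang, png = basename(paste0(stem, ".png")))
  }, views, angles)
  manifest <- list(mesh = basename(stl_path), n_views = length(entries),
                   views = unname(entries))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
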