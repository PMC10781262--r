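# Body-value derivation from the 3D mesh: planar cross-sections chained into
# closed loops give circumferences (a convex-hull "tape measure" for torso
# girths, raw perimeters for limbs), slab integration of section areas gives
# volumes, and landmark distances give lengths. Section planes are located
# relative to the detected seed points by searching for the perimeter
# extremum (chest/hip maxima, waist minimum), because published girth
# definitions anchor to landmarks rather than fixed height fractions.

#' Phong-style vertex normals
#'
#' The normal of a vertex is the normalized unweighted average of the unit
#' normals of its adjacent faces; flat regions therefore keep the face
#' normal and curved regions recover the smooth surface direction used for
#' shading. Degenerate (zero-area) faces are skipped with a warning;
#' isolated vertices get a zero vector.
#'
#' @param mesh a [trimesh] with consistently wound faces.
#' @return n x 3 matrix of unit normals (zero rows flag isolated vertices).
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  degen <- rowSums(fn^2) < 0.5
  if (any(degen))
    warning("vertex_normals: skipped ", sum(degen), " degenerate face(s)")
  f <- mesh$faces[!degen, , drop = FALSE]
  fn <- fn[!degen, , drop = FALSE]
  acc <- matrix(0, n_vertices(mesh), 3)
  for (k in 1:3) {
    s <- rowsum(fn, group = f[, k], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  len <- sqrt(rowSums(acc^2))
  ok <- len > 1e-12
  acc[ok, ] <- acc[ok, , drop = FALSE] / len[ok]
  acc[!ok, ] <- 0
  acc
}

#' Horizontal cross-section of a mesh
#'
#' Intersects every face with the plane `y = plane_y`, collects the
#' resulting segments and chains them into closed loops by endpoint matching
#' (tolerance 1e-6 mm). Open chains — leaks from non-watertight regions —
#' are discarded with a warning rather than aborting the measurement.
#'
#' @param mesh a [trimesh].
#' @param plane_y section height, mm.
#' @return A `cross_section`: `plane_y`, `loops` (list of k x 2 matrices of
#'   ordered (x, z) points, closure implied), `perimeter` (mm per loop) and
#'   `area` (mm^2 per loop, shoelace). A plane missing the mesh returns an
#'   empty section.
#' @export
cross_section <- function(mesh, plane_y) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- v[, 2] - plane_y
  d[d == 0] <- 1e-9          # nudge vertices exactly on the plane
  s1 <- d[f[, 1]]
  s2 <- d[f[, 2]]
  s3 <- d[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  empty <- structure(list(plane_y = plane_y, loops = list(),
                          perimeter = numeric(0), area = numeric(0)),
                     class = "cross_section")
  if (!any(crossing)) return(empty)
  fi <- f[crossing, , drop = FALSE]
  da <- cbind(s1, s2, s3)[crossing, , drop = FALSE]
  segs <- matrix(NA_real_, nrow(fi), 4)   # x1 z1 x2 z2
  filled <- integer(nrow(fi))
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (ep in edge_pairs) {
    a <- ep[1]
    b <- ep[2]
    hit <- da[, a] * da[, b] < 0
    if (!any(hit)) next
    t <- da[hit, a] / (da[hit, a] - da[hit, b])
    pa <- v[fi[hit, a], c(1, 3), drop = FALSE]
    pb <- v[fi[hit, b], c(1, 3), drop = FALSE]
    p <- pa + t * (pb - pa)
    rows <- which(hit)
    first <- filled[rows] == 0L
    segs[rows[first], 1:2] <- p[first, , drop = FALSE]
    segs[rows[!first], 3:4] <- p[!first, , drop = FALSE]
    filled[rows] <- filled[rows] + 1L
  }
  segs <- segs[filled == 2L, , drop = FALSE]
  if (nrow(segs) == 0) return(empty)
  .chain_loops(segs, plane_y)
}

# chain unordered 2D segments into closed loops. Fast pass: exact endpoint
# keys on a `tol` grid. The rare chains broken by endpoints straddling a
# rounding-bin boundary (planes grazing a mesh ring) are then stitched by
# nearest-end matching at the chain level. Zero-length segments are
# discarded upfront.
.chain_loops <- function(segs, plane_y, tol = 1e-6) {
  len2 <- (segs[, 1] - segs[, 3])^2 + (segs[, 2] - segs[, 4])^2
  segs <- segs[len2 > tol^2, , drop = FALSE]
  n <- nrow(segs)
  if (n == 0)
    return(structure(list(plane_y = plane_y, loops = list(),
                          perimeter = numeric(0), area = numeric(0)),
                     class = "cross_section"))
  key <- function(x, z) paste(round(x / tol), round(z / tol))
  k1 <- key(segs[, 1], segs[, 2])
  k2 <- key(segs[, 3], segs[, 4])
  ep <- split(rep(seq_len(n), 2), c(k1, k2))
  used <- logical(n)
  match_tol <- 4 * tol
  loops <- list()
  chains <- list()   # open point sequences awaiting stitching
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(segs[start, 1:2], segs[start, 3:4])
    head_key <- k1[start]
    tail_key <- k2[start]
    # extend at the tail
    repeat {
      cand <- ep[[tail_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      if (identical(k1[nxt], tail_key)) {
        pts[[length(pts) + 1L]] <- segs[nxt, 3:4]
        tail_key <- k2[nxt]
      } else {
        pts[[length(pts) + 1L]] <- segs[nxt, 1:2]
        tail_key <- k1[nxt]
      }
    }
    if (identical(tail_key, head_key)) {
      # closed: the final point duplicates the first
      if (length(pts) >= 4)
        loops[[length(loops) + 1L]] <- do.call(rbind, pts[-length(pts)])
      next
    }
    # open: extend at the head too, then queue for stitching
    repeat {
      cand <- ep[[head_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      if (identical(k1[nxt], head_key)) {
        pts <- c(list(segs[nxt, 3:4]), pts)
        head_key <- k2[nxt]
      } else {
        pts <- c(list(segs[nxt, 1:2]), pts)
        head_key <- k1[nxt]
      }
    }
    chains[[length(chains) + 1L]] <- do.call(rbind, pts)
  }
  # stitch broken chains by nearest-end matching
  dropped <- 0L
  while (length(chains) > 0) {
    ch <- chains[[1]]
    chains[[1]] <- NULL
    tail_pt <- ch[nrow(ch), ]
    head_pt <- ch[1, ]
    if (sum((tail_pt - head_pt)^2) <= match_tol^2) {
      if (nrow(ch) >= 4) loops[[length(loops) + 1L]] <- ch[-nrow(ch), ,
                                                           drop = FALSE]
      next
    }
    hit <- 0L
    flip <- FALSE
    best <- match_tol^2
    for (j in seq_along(chains)) {
      d_head <- sum((chains[[j]][1, ] - tail_pt)^2)
      d_tail <- sum((chains[[j]][nrow(chains[[j]]), ] - tail_pt)^2)
      if (d_head <= best) {
        best <- d_head
        hit <- j
        flip <- FALSE
      }
      if (d_tail <= best) {
        best <- d_tail
        hit <- j
        flip <- TRUE
      }
    }
    if (hit == 0L) {
      dropped <- dropped + 1L
      next
    }
    other <- chains[[hit]]
    chains[[hit]] <- NULL
    if (flip) other <- other[nrow(other):1, , drop = FALSE]
    chains[[length(chains) + 1L]] <- rbind(ch, other[-1, , drop = FALSE])
  }
  if (dropped > 0)
    warning("cross_section: discarded ", dropped,
            " open chain(s) (non-watertight region) at y = ", plane_y)
  perim <- vapply(loops, .loop_perimeter, numeric(1))
  area <- vapply(loops, .loop_area, numeric(1))
  structure(list(plane_y = plane_y, loops = loops, perimeter = perim,
                 area = area),
            class = "cross_section")
}

.loop_perimeter <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

.loop_area <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  abs(sum(pts[, 1] * nxt[, 2] - nxt[, 1] * pts[, 2])) / 2
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> y = %.1f mm: %d loop(s)\n",
              x$plane_y, length(x$loops)))
  if (length(x$loops))
    print(data.frame(perimeter_mm = round(x$perimeter, 2),
                     area_mm2 = round(x$area, 1)))
  invisible(x)
}

#' Circumference of a cross-section loop
#'
#' Selects one loop and returns its perimeter in cm. `tape_mode = "convex"`
#' emulates a tape measure spanning concavities (the convex hull's
#' perimeter, used for torso girths); `"raw"` follows the surface (used for
#' limbs). The hull perimeter never exceeds the raw perimeter.
#'
#' @param section a [cross_section()].
#' @param loop_select `"largest_area"` or `"nearest_centroid"` (with
#'   `target`, an (x, z) point in mm).
#' @param tape_mode `"raw"` or `"convex"`.
#' @param target (x, z) reference for `nearest_centroid` selection.
#' @return Circumference in cm.
#' @export
circumference <- function(section,
                          loop_select = c("largest_area", "nearest_centroid"),
                          tape_mode = c("raw", "convex"), target = NULL) {
  loop_select <- match.arg(loop_select)
  tape_mode <- match.arg(tape_mode)
  if (length(section$loops) == 0)
    stop("circumference: empty section at y = ", section$plane_y,
         call. = FALSE)
  idx <- if (loop_select == "largest_area") {
    which.max(section$area)
  } else {
    if (is.null(target))
      stop("circumference: nearest_centroid selection needs a target point",
           call. = FALSE)
    cen <- t(vapply(section$loops, colMeans, numeric(2)))
    which.min((cen[, 1] - target[1])^2 + (cen[, 2] - target[2])^2)
  }
  pts <- section$loops[[idx]]
  if (tape_mode == "convex") pts <- pts[grDevices::chull(pts), , drop = FALSE]
  .loop_perimeter(pts) / 10
}

#' Slab volume between two horizontal planes
#'
#' Trapezoidal integration of the total cross-section area over
#' `n_slices + 1` uniformly spaced planes between `y_low` and `y_high`.
#'
#' @param mesh a [trimesh].
#' @param y_low,y_high slab bounds, mm (`y_low <= y_high`).
#' @param n_slices number of integration intervals (default 64).
#' @param loops `"all"` sums every loop's area per slice; `"largest"`
#'   integrates only the largest loop (e.g. the torso, excluding arm loops).
#' @return Volume in litres (1 L = 1e6 mm^3); 0 with a warning when every
#'   section is empty.
#' @export
slab_volume <- function(mesh, y_low, y_high, n_slices = 64,
                        loops = c("all", "largest")) {
  loops <- match.arg(loops)
  if (y_low > y_high) stop("slab_volume: y_low must be <= y_high", call. = FALSE)
  if (y_low == y_high) return(0)
  ys <- seq(y_low, y_high, length.out = n_slices + 1)
  # keep the end planes infinitesimally inside the slab so sections at flat
  # end caps (e.g. a cylinder sliced over its full height) are not lost
  eps <- (y_high - y_low) * 1e-9
  ys[1] <- ys[1] + eps
  ys[n_slices + 1] <- ys[n_slices + 1] - eps
  areas <- vapply(ys, function(y) {
    cs <- cross_section(mesh, y)
    if (length(cs$area) == 0) return(0)
    if (loops == "all") sum(cs$area) else max(cs$area)
  }, numeric(1))
  if (all(areas == 0)) {
    warning("slab_volume: all sections empty in [", y_low, ", ", y_high, "]")
    return(0)
  }
  h <- (y_high - y_low) / n_slices
  sum((areas[-1] + areas[-length(areas)]) / 2) * h / 1e6
}

# perimeter of the largest loop (convex tape) at a plane, 0 if empty
.torso_girth_at <- function(mesh, y) {
  cs <- cross_section(mesh, y)
  if (length(cs$loops) == 0) return(0)
  circumference(cs, "largest_area", "convex")
}

# coarse grid search then one local refinement pass for a perimeter extremum.
# Tie-break: maxima resolve to the topmost tied plane (a flat-profile torso
# puts the chest at the armpit line), minima to the lowest.
.search_extremum <- function(mesh, lo, hi, maximize, n_coarse = 25,
                             n_fine = 9) {
  pick_of <- function(per, valid) {
    score <- replace(per, !valid, if (maximize) -Inf else Inf)
    best <- if (maximize) max(score) else min(score)
    hits <- which(score == best)
    if (maximize) hits[length(hits)] else hits[1]
  }
  ys <- seq(lo, hi, length.out = n_coarse)
  per <- vapply(ys, function(y) .torso_girth_at(mesh, y), numeric(1))
  valid <- per > 0
  if (!any(valid)) return(NULL)
  pick <- pick_of(per, valid)
  step <- ys[2] - ys[1]
  ys2 <- seq(max(lo, ys[pick] - step), min(hi, ys[pick] + step),
             length.out = n_fine)
  per2 <- vapply(ys2, function(y) .torso_girth_at(mesh, y), numeric(1))
  valid2 <- per2 > 0
  pick2 <- pick_of(per2, valid2)
  list(y = ys2[pick2], girth = per2[pick2],
       interior = pick > 1 && pick < n_coarse)
}

#' Locate the girth measurement planes from seed points
#'
#' Anchors the section planes to the detected landmarks: the waist is the
#' torso perimeter minimum in the upper 60% of the crotch-to-armpit span,
#' the chest the maximum between that lower bound and the armpit line, the
#' hip the maximum between crotch and waist; thighs are sectioned 5% of
#' body height below the crotch and upper arms 25% of the
#' shoulder-to-fingertip span below the armpit.
#'
#' @param mesh a [trimesh].
#' @param seeds a `seed_points` object with world heights.
#' @return Named list of plane heights (mm): `chest`, `waist`, `hip`,
#'   `thigh`, `left_arm`, `right_arm`, plus `warnings` (character).
#' @export
locate_measurement_planes <- function(mesh, seeds) {
  wh <- seeds$world_heights
  if (is.null(wh) || any(is.na(wh[c("left_armpit", "right_armpit", "crotch")])))
    stop("locate_measurement_planes: seeds lack world heights", call. = FALSE)
  H <- mesh_height(mesh)
  armpit_y <- mean(wh[c("left_armpit", "right_armpit")])
  crotch_y <- wh[["crotch"]]
  warns <- character(0)
  lo_w <- crotch_y + 0.4 * (armpit_y - crotch_y)
  if (!(lo_w < armpit_y))
    stop("locate_measurement_planes: empty waist search interval ",
         "(armpit/crotch landmark dependency)", call. = FALSE)
  waist <- .search_extremum(mesh, lo_w, armpit_y - 1e-6, maximize = FALSE)
  if (is.null(waist))
    stop("locate_measurement_planes: no torso sections in the waist interval",
         call. = FALSE)
  # the chest is the perimeter maximum above the waist (searching below it
  # would pick up the hip flank on wide-hipped bodies)
  chest <- .search_extremum(mesh, waist$y, armpit_y, maximize = TRUE)
  if (!chest$interior) {
    warns <- c(warns, "chest: no interior perimeter maximum; using the plane at the interval boundary")
  }
  hip <- .search_extremum(mesh, crotch_y + 1e-6, waist$y, maximize = TRUE)
  if (is.null(hip))
    stop("locate_measurement_planes: no torso sections in the hip interval",
         call. = FALSE)
  thigh_y <- crotch_y - 0.05 * H
  arm_y <- function(side) {
    sh <- seeds$world[paste0(side, "_shoulder"), ]
    ft <- seeds$world[paste0(side, "_fingertip"), ]
    if (any(is.na(sh)) || any(is.na(ft))) return(NA_real_)
    span <- sqrt(sum((sh - ft)^2))
    armpit_y - 0.25 * span
  }
  out <- list(chest = chest$y, waist = waist$y, hip = hip$y, thigh = thigh_y,
              left_arm = arm_y("left"), right_arm = arm_y("right"),
              armpit = armpit_y, crotch = crotch_y, warnings = warns)
  for (w in warns) warning("locate_measurement_planes: ", w)
  out
}

# loop nearest (in x, z) to the interpolated limb axis position at plane y
.limb_girth <- function(mesh, y, p_top, p_bot) {
  cs <- cross_section(mesh, y)
  if (length(cs$loops) == 0) return(NA_real_)
  t <- if (p_top[2] != p_bot[2]) (p_top[2] - y) / (p_top[2] - p_bot[2]) else 0
  t <- min(1, max(0, t))
  axis_pt <- p_top + t * (p_bot - p_top)
  circumference(cs, "nearest_centroid", "raw", target = axis_pt[c(1, 3)])
}

#' Full measurement report
#'
#' Derives stature, the seven girths (chest/waist/hip with the convex tape,
#' limbs raw), the chest slab volume (torso loops between the waist and
#' chest planes) and limb/torso lengths from landmark distances
#' (shoulder-to-fingertip for arms, armpit height to toe for legs, neck to
#' crotch for the torso).
#'
#' @param mesh a [trimesh] (resized to the subject's stature if known).
#' @param seeds a `seed_points` object from [detect_seed_points()].
#' @param n_volume_slices slices for the chest slab integration.
#' @return A `measurement_report`; see [measurement_report()].
#' @export
measure_report <- function(mesh, seeds, n_volume_slices = 64) {
  planes <- locate_measurement_planes(mesh, seeds)
  girth <- function(y) .torso_girth_at(mesh, y)
  circs <- c(chest = girth(planes$chest), waist = girth(planes$waist),
             hip = girth(planes$hip))
  w <- seeds$world
  # legs are near-vertical: the toe (x, z) tracks the leg axis at thigh level
  circs["left_thigh"] <- .limb_girth(mesh, planes$thigh, w["left_toe", ],
                                     w["left_toe", ])
  circs["right_thigh"] <- .limb_girth(mesh, planes$thigh, w["right_toe", ],
                                      w["right_toe", ])
  circs["left_arm"] <- .limb_girth(mesh, planes$left_arm,
                                   w["left_shoulder", ], w["left_fingertip", ])
  circs["right_arm"] <- .limb_girth(mesh, planes$right_arm,
                                    w["right_shoulder", ],
                                    w["right_fingertip", ])
  circs <- circs[c("chest", "waist", "hip", "left_arm", "right_arm",
                   "left_thigh", "right_thigh")]
  vol <- slab_volume(mesh, planes$waist, planes$chest,
                     n_slices = n_volume_slices, loops = "largest")
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  wh <- seeds$world_heights
  lengths <- c(
    arm_left = dist3(w["left_shoulder", ], w["left_fingertip", ]) / 10,
    arm_right = dist3(w["right_shoulder", ], w["right_fingertip", ]) / 10,
    leg_left = (mean(wh[c("left_armpit", "right_armpit")]) -
                  wh[["left_toe"]]) / 10,
    leg_right = (mean(wh[c("left_armpit", "right_armpit")]) -
                   wh[["right_toe"]]) / 10,
    torso = (wh[["neck"]] - wh[["crotch"]]) / 10)
  measurement_report(height = mesh_height(mesh) / 10,
                     circumferences = circs, chest_volume = vol,
                     lengths = lengths, planes = planes)
}

#' Measurement report container
#'
#' @param height stature, cm.
#' @param circumferences named vector, cm: `chest`, `waist`, `hip`,
#'   `left_arm`, `right_arm`, `left_thigh`, `right_thigh` (missing entries
#'   allowed for hand-built reference reports).
#' @param chest_volume chest slab volume, litres.
#' @param lengths named vector, cm.
#' @param planes optional plane metadata from [locate_measurement_planes()].
#' @return A `measurement_report` object.
#' @export
measurement_report <- function(height = NA_real_, circumferences = numeric(0),
                               chest_volume = NA_real_, lengths = numeric(0),
                               planes = NULL) {
  structure(list(height = unname(height), circumferences = circumferences,
                 chest_volume = unname(chest_volume), lengths = lengths,
                 planes = planes),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("<measurement_report> height %.1f cm, chest volume %.2f L\n",
              x$height, x$chest_volume))
  cat("circumferences (cm):\n")
  print(round(x$circumferences, 1))
  if (length(x$lengths)) {
    cat("lengths (cm):\n")
    print(round(x$lengths, 1))
  }
  invisible(x)
}

#' Report as a data frame (measurement, value, unit, method)
#' @param report a `measurement_report`.
#' @return A data.frame suitable for CSV export.
#' @export
report_as_table <- function(report) {
  rows <- list(data.frame(measurement = "height", value = report$height,
                          unit = "cm", method = "mesh vertical extent"))
  for (nm in names(report$circumferences)) {
    method <- if (nm %in% c("chest", "waist", "hip"))
      "convex tape on torso loop" else "raw limb loop perimeter"
    rows[[length(rows) + 1L]] <- data.frame(
      measurement = paste0(nm, "_circumference"),
      value = report$circumferences[[nm]], unit = "cm", method = method)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    measurement = "chest_volume", value = report$chest_volume, unit = "L",
    method = "slab integration waist-to-chest")
  for (nm in names(report$lengths)) {
    rows[[length(rows) + 1L]] <- data.frame(
      measurement = paste0(nm, "_length"), value = report$lengths[[nm]],
      unit = "cm", method = "landmark distance")
  }
  do.call(rbind, rows)
}

#' Body mass index
#' @param weight_kg body mass, kg.
#' @param height_cm stature, cm.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("bmi: weight and height must be positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' Waist-to-height ratio
#' @param waist_cm waist circumference, cm.
#' @param height_cm stature, cm.
#' @return Dimensionless ratio.
#' @export
whtr <- function(waist_cm, height_cm) {
  if (any(waist_cm <= 0) || any(height_cm <= 0))
    stop("whtr: waist and height must be positive", call. = FALSE)
  waist_cm / height_cm
}
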