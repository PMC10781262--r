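# Seed-point detection and body segmentation on frontal depth maps.
# Eleven named keypoints are derived from silhouette topography: head end,
# neck, shoulders, armpits, fingertips, toes and the crotch. The rules fire
# on an A-pose silhouette (arms abducted off the torso, legs apart) so that
# armpit and crotch gaps are visible. "Left"/"right" follow image
# coordinates: col(left) < col(right) in a front view.

SEED_POINT_NAMES <- c("head_top", "neck", "left_shoulder", "right_shoulder",
                      "left_armpit", "right_armpit", "left_fingertip",
                      "right_fingertip", "left_toe", "right_toe", "crotch")

# maximal runs of TRUE in a logical row -> matrix (start, end) cols
.row_intervals <- function(mask_row) {
  r <- rle(mask_row)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# centred moving average that shrinks its window at the edges
.smooth_vec <- function(x, win = 5L) {
  n <- length(x)
  half <- win %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(x[j])
  }
  out
}

#' Per-row silhouette width profile
#'
#' The substrate for the thinnest-part (neck) and gap (armpit, crotch)
#' rules: for every image row, the maximal runs of silhouette pixels and the
#' total width, plus a copy smoothed with a 5-row moving average (raw widths
#' are kept for the interval-count gap tests, which must not be blurred).
#'
#' @param dm a [depth_map()] with a non-empty silhouette.
#' @param smooth_window moving-average window in rows.
#' @return A `width_profile`: list with `width` (per-row total px),
#'   `smoothed`, `intervals` (list of start/end matrices per row), and the
#'   first/last silhouette rows `row_top`, `row_bottom`.
#' @export
width_profile <- function(dm, smooth_window = 5L) {
  sil <- dm$pixels > 0
  if (!any(sil)) stop("width_profile: empty silhouette", call. = FALSE)
  width <- rowSums(sil)
  rows_on <- which(width > 0)
  intervals <- vector("list", nrow(sil))
  for (r in rows_on) intervals[[r]] <- .row_intervals(sil[r, ])
  structure(list(width = width, smoothed = .smooth_vec(width, smooth_window),
                 intervals = intervals,
                 row_top = rows_on[1], row_bottom = rows_on[length(rows_on)]),
            class = "width_profile")
}

# --- individual seed rules (internal, unit-testable) -----------------------

# neck: walk down the smoothed width to the head's widest row (first local
# maximum), then take the row of minimum smoothed width between there and
# the 30%-of-silhouette-height boundary; topmost row on ties.
.find_neck_row <- function(smoothed, row_top, row_bottom) {
  r30 <- row_top + floor(0.30 * (row_bottom - row_top + 1))
  r_headmax <- NA_integer_
  for (r in row_top:(r30 - 1L)) {
    if (smoothed[r + 1L] < smoothed[r]) {
      r_headmax <- r
      break
    }
  }
  if (is.na(r_headmax))
    stop("seed-point detection failed for landmark 'neck': no width maximum ",
         "above the 30% boundary", call. = FALSE)
  seg <- smoothed[r_headmax:r30]
  r_headmax + which.min(seg) - 1L
}

# shoulder: first row below the neck where the second difference of the
# smoothed side contour changes sign (the inflection of the neck-to-shoulder
# curve). side = "left" uses the leftmost silhouette column per row.
.find_shoulder_row <- function(sil, neck_row, row_bottom, side,
                               search_frac = 0.30) {
  rows <- neck_row:row_bottom
  contour <- vapply(rows, function(r) {
    cc <- which(sil[r, ])
    if (length(cc) == 0) return(NA_real_)
    if (side == "left") min(cc) else max(cc)
  }, numeric(1))
  ok <- !is.na(contour)
  contour[!ok] <- stats::approx(which(ok), contour[ok], xout = which(!ok),
                                rule = 2)$y
  sm <- .smooth_vec(contour, 5L)
  d2 <- diff(sm, differences = 2)           # d2[i] at rows[i + 1]
  limit <- min(length(d2), ceiling(search_frac * (row_bottom - neck_row)))
  eps <- 1e-3
  first_sign <- 0
  for (i in seq_len(limit)) {
    s <- if (d2[i] > eps) 1 else if (d2[i] < -eps) -1 else 0
    if (s == 0) next
    if (first_sign == 0) {
      first_sign <- s
    } else if (s != first_sign) {
      return(list(row = rows[i + 1L], col = as.integer(round(contour[i + 1L]))))
    }
  }
  stop("seed-point detection failed for landmark '", side,
       "_shoulder': no curvature inflection below the neck", call. = FALSE)
}

# armpit: first row below the shoulder where a gap opens between the arm and
# the torso on that side; the point sits on the torso-side gap boundary.
# Both the gap and the separated arm interval must span at least `min_gap`
# pixels — single-pixel slivers between near-tangent rounded surfaces are
# rasterization noise, not an armpit.
.find_armpit <- function(profile, shoulder_row, mid_col, side, min_gap = 2L) {
  for (r in (shoulder_row + 1L):profile$row_bottom) {
    iv <- profile$intervals[[r]]
    if (is.null(iv) || nrow(iv) == 0) next
    torso <- which(iv[, "start"] <= mid_col & iv[, "end"] >= mid_col)
    if (length(torso) != 1) next
    if (side == "left") {
      if (torso == 1L) next
      arm <- iv[torso - 1L, ]
      gap_px <- iv[torso, "start"] - arm[["end"]] - 1L
      col <- iv[torso, "start"]
    } else {
      if (torso == nrow(iv)) next
      arm <- iv[torso + 1L, ]
      gap_px <- arm[["start"]] - iv[torso, "end"] - 1L
      col <- iv[torso, "end"]
    }
    arm_px <- arm[["end"]] - arm[["start"]] + 1L
    if (gap_px >= min_gap && arm_px >= min_gap)
      return(list(row = r, col = as.integer(col)))
  }
  stop("seed-point detection failed for landmark '", side,
       "_armpit': arms do not separate from the torso below the shoulder",
       call. = FALSE)
}

# per-row central (midline-connected) column span walked downward from the
# armpit row; intervals overlapping the previous span are central (torso,
# then hips, then legs), anything outside it on a side belongs to that arm
.central_spans <- function(profile, start_row, start_span) {
  spans <- matrix(NA_integer_, length(profile$width), 2)
  spans[start_row, ] <- start_span
  cur <- start_span
  if (start_row < profile$row_bottom) {
    for (r in (start_row + 1L):profile$row_bottom) {
      iv <- profile$intervals[[r]]
      if (is.null(iv) || nrow(iv) == 0) break
      ov <- iv[, "start"] <= cur[2] & iv[, "end"] >= cur[1]
      if (!any(ov)) break
      cur <- c(min(iv[ov, "start"]), max(iv[ov, "end"]))
      spans[r, ] <- cur
    }
  }
  spans
}

# fingertip: range search over the columns outside the central span on that
# side; the bottom-most such silhouette pixel, outermost column on ties.
.find_fingertip <- function(profile, spans, side) {
  best_row <- NA_integer_
  best_col <- NA_integer_
  for (r in which(!is.na(spans[, 1]))) {
    iv <- profile$intervals[[r]]
    if (is.null(iv) || nrow(iv) == 0) next
    outside <- if (side == "left") iv[, "end"] < spans[r, 1]
               else iv[, "start"] > spans[r, 2]
    if (!any(outside)) next
    best_row <- r
    best_col <- if (side == "left") min(iv[outside, "start"])
                else max(iv[outside, "end"])
  }
  if (is.na(best_row))
    stop("seed-point detection failed for landmark '", side,
         "_fingertip': no silhouette outside the torso interval", call. = FALSE)
  list(row = best_row, col = as.integer(best_col))
}

# crotch: scan upward from the toe rows along the leg midline; the first row
# whose silhouette covers the midline is where the two legs merge.
.find_crotch <- function(profile, sil, mid_col, from_row) {
  for (r in from_row:profile$row_top) {
    if (sil[r, mid_col]) return(list(row = r, col = as.integer(mid_col)))
  }
  stop("seed-point detection failed for landmark 'crotch': the leg intervals ",
       "never merge", call. = FALSE)
}

#' Detect the 11 body seed points on a frontal depth map
#'
#' Applies the silhouette rules in order: head end at the topmost silhouette
#' row; neck at the thinnest smoothed width within the top 30% of the body
#' (below the head's widest row); shoulders at the curvature inflection of
#' the side contours below the neck; armpits where a gap first opens beneath
#' the shoulder line between arm and torso; fingertips by range search over
#' the columns outside the torso interval; toes at the bottom of each leg;
#' and the crotch where, scanning upward from the toes along the midline,
#' the two leg intervals merge. Detection is deterministic and works on the
#' frontal view of an A-pose silhouette.
#'
#' @param dm a [depth_map()] whose silhouette is at least 100 px tall.
#' @return A `seed_points` object: `points` (11 x 2 matrix of row/col, named
#'   rows), `world` (11 x 3 world points, mm, where depth is available) and
#'   `world_heights` (named world Y, mm).
#' @export
detect_seed_points <- function(dm) {
  sil <- dm$pixels > 0
  profile <- width_profile(dm)
  if (profile$row_bottom - profile$row_top + 1 < 100)
    stop("detect_seed_points: silhouette must be at least 100 px tall",
         call. = FALSE)

  pts <- matrix(NA_integer_, nrow = 11, ncol = 2,
                dimnames = list(SEED_POINT_NAMES, c("row", "col")))
  # (1) head end
  r_top <- profile$row_top
  head_col <- as.integer(round(mean(which(sil[r_top, ]))))
  pts["head_top", ] <- c(r_top, head_col)
  # (2) neck
  neck_row <- .find_neck_row(profile$smoothed, r_top, profile$row_bottom)
  neck_col <- as.integer(round(mean(which(sil[neck_row, ]))))
  pts["neck", ] <- c(neck_row, neck_col)
  # (3) shoulders
  sh_l <- .find_shoulder_row(sil, neck_row, profile$row_bottom, "left")
  sh_r <- .find_shoulder_row(sil, neck_row, profile$row_bottom, "right")
  pts["left_shoulder", ] <- c(sh_l$row, sh_l$col)
  pts["right_shoulder", ] <- c(sh_r$row, sh_r$col)
  # (4) armpits
  ap_l <- .find_armpit(profile, sh_l$row, neck_col, "left")
  ap_r <- .find_armpit(profile, sh_r$row, neck_col, "right")
  pts["left_armpit", ] <- c(ap_l$row, ap_l$col)
  pts["right_armpit", ] <- c(ap_r$row, ap_r$col)
  # torso column interval at the armpit rows
  iv_l <- profile$intervals[[ap_l$row]]
  torso_l <- iv_l[iv_l[, "start"] <= neck_col & iv_l[, "end"] >= neck_col, ]
  iv_r <- profile$intervals[[ap_r$row]]
  torso_r <- iv_r[iv_r[, "start"] <= neck_col & iv_r[, "end"] >= neck_col, ]
  torso_cols <- c(torso_l[["start"]], torso_r[["end"]])
  # central (midline-connected) span per row below the armpits: torso, hips,
  # then legs; whatever lies outside it on a side is that arm
  span_start <- max(ap_l$row, ap_r$row)
  spans <- .central_spans(profile, span_start, torso_cols)
  # (5) fingertips
  ft_l <- .find_fingertip(profile, spans, "left")
  ft_r <- .find_fingertip(profile, spans, "right")
  pts["left_fingertip", ] <- c(ft_l$row, ft_l$col)
  pts["right_fingertip", ] <- c(ft_r$row, ft_r$col)
  # (6) toes: bottom row of the central region (arms and hands excluded)
  r_bot <- max(which(!is.na(spans[, 1])))
  iv_r_bot <- profile$intervals[[r_bot]]
  central <- iv_r_bot[iv_r_bot[, "start"] <= spans[r_bot, 2] &
                        iv_r_bot[, "end"] >= spans[r_bot, 1], , drop = FALSE]
  if (nrow(central) < 2)
    stop("seed-point detection failed for landmark 'crotch': legs are not ",
         "separated at the bottom row", call. = FALSE)
  left_leg <- central[1, ]
  right_leg <- central[nrow(central), ]
  pts["left_toe", ] <- c(r_bot, as.integer(round(mean(left_leg))))
  pts["right_toe", ] <- c(r_bot, as.integer(round(mean(right_leg))))
  # (7) crotch
  mid_col <- as.integer(round((left_leg[["end"]] + right_leg[["start"]]) / 2))
  cr <- .find_crotch(profile, sil, mid_col, r_bot)
  pts["crotch", ] <- c(cr$row, cr$col)

  seeds <- structure(list(points = pts, image = c(dm$height, dm$width)),
                     class = "seed_points")
  .check_seed_order(seeds)

  world <- matrix(NA_real_, 11, 3, dimnames = list(SEED_POINT_NAMES, NULL))
  for (nm in SEED_POINT_NAMES) {
    r <- pts[nm, "row"]
    cc <- pts[nm, "col"]
    if (dm$world_depth[r, cc] > 0) {
      world[nm, ] <- back_project(dm, r, cc)
    } else {
      h <- .pixel_world_height(dm, r, cc)
      world[nm, 2] <- h
    }
  }
  seeds$world <- world
  seeds$world_heights <- stats::setNames(world[, 2], SEED_POINT_NAMES)
  seeds
}

.check_seed_order <- function(seeds) {
  p <- seeds$points
  ok <- p["head_top", "row"] < p["neck", "row"] &&
    p["neck", "row"] < min(p[c("left_shoulder", "right_shoulder"), "row"]) &&
    all(p[c("left_shoulder", "right_shoulder"), "row"] <=
          p[c("left_armpit", "right_armpit"), "row"]) &&
    max(p[c("left_armpit", "right_armpit"), "row"]) < p["crotch", "row"] &&
    p["crotch", "row"] < min(p[c("left_toe", "right_toe"), "row"]) &&
    p["left_shoulder", "col"] < p["right_shoulder", "col"] &&
    p["left_armpit", "col"] < p["right_armpit", "col"] &&
    p["left_fingertip", "col"] < p["right_fingertip", "col"] &&
    p["left_toe", "col"] < p["right_toe", "col"]
  if (!ok)
    stop("seed points violate the vertical/lateral ordering invariant",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.seed_points <- function(x, ...) {
  cat("<seed_points> 11 landmarks\n")
  df <- data.frame(row = x$points[, "row"], col = x$points[, "col"])
  if (!is.null(x$world_heights))
    df$world_height_mm <- round(x$world_heights, 1)
  print(df)
  invisible(x)
}

#' Write seed points as JSON
#' @param seeds a `seed_points` object.
#' @param path output path; entries are `name: [row, col, world_height_mm]`.
#' @return Invisibly `path`.
#' @export
write_seed_points <- function(seeds, path) {
  out <- lapply(SEED_POINT_NAMES, function(nm) {
    c(seeds$points[nm, "row"], seeds$points[nm, "col"],
      if (!is.null(seeds$world_heights)) seeds$world_heights[[nm]] else NA)
  })
  names(out) <- SEED_POINT_NAMES
  jsonlite::write_json(out, path, digits = NA, na = "null")
  invisible(path)
}

#' Segment the silhouette into labeled body parts
#'
#' Splits the silhouette with the seed points: head above the neck row, neck
#' between neck and shoulder rows, arms below the armpit rows outside the
#' torso column interval, legs below the crotch split at the midline, and
#' the remainder torso. The labels partition the silhouette exactly.
#'
#' @param dm a [depth_map()].
#' @param seeds a `seed_points` object from [detect_seed_points()].
#' @return A `body_segments` object: `labels` is an H x W integer matrix
#'   with levels `background, head, neck, torso, left_arm, right_arm,
#'   left_leg, right_leg` (in `levels`).
#' @export
segment_body <- function(dm, seeds) {
  tryCatch(.check_seed_order(seeds), error = function(e)
    stop("segment_body: inconsistent seeds: ", conditionMessage(e),
         call. = FALSE))
  sil <- dm$pixels > 0
  levels <- c("background", "head", "neck", "torso", "left_arm", "right_arm",
              "left_leg", "right_leg")
  lab <- matrix(0L, nrow(sil), ncol(sil))
  lab[sil] <- 3L  # torso by default
  p <- seeds$points
  rows <- row(sil)
  cols <- col(sil)
  neck_row <- p["neck", "row"]
  sh_row <- min(p[c("left_shoulder", "right_shoulder"), "row"])
  lab[sil & rows < neck_row] <- 1L
  lab[sil & rows >= neck_row & rows < sh_row] <- 2L
  # arm pixels lie outside the midline-connected central span of their row,
  # below the armpit line on that side
  profile <- width_profile(dm)
  tl <- p["left_armpit", "col"]
  tr <- p["right_armpit", "col"]
  span_start <- max(p[c("left_armpit", "right_armpit"), "row"])
  spans <- .central_spans(profile, span_start, c(tl, tr))
  cl <- spans[, 1]
  cr <- spans[, 2]
  cl[seq_len(span_start)] <- tl
  cr[seq_len(span_start)] <- tr
  cl[is.na(cl)] <- tl
  cr[is.na(cr)] <- tr
  lab[sil & lab == 3L & rows >= p["left_armpit", "row"] & cols < cl[rows]] <- 4L
  lab[sil & lab == 3L & rows >= p["right_armpit", "row"] & cols > cr[rows]] <- 5L
  cr_row <- p["crotch", "row"]
  cr_col <- p["crotch", "col"]
  lab[lab == 3L & rows > cr_row & cols <= cr_col] <- 6L
  lab[lab == 3L & rows > cr_row & cols > cr_col] <- 7L
  structure(list(labels = lab, levels = levels), class = "body_segments")
}

#' @export
print.body_segments <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = length(x$levels))
  names(tab) <- x$levels
  cat("<body_segments> pixel counts:\n")
  print(tab)
  invisible(x)
}
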