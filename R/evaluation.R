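# Comparison metrics: ratio-error pairs (A = chest/waist-ratio error,
# B = arm/thigh-ratio error), camera-placement selection over a
# height-by-distance error grid, and per-part error / accuracy aggregation.

.report_girth <- function(report, part) {
  if (inherits(report, "measurement_report")) {
    if (part == "height") return(report$height)
    if (part == "chest_volume") return(report$chest_volume)
    return(report$circumferences[[part]])
  }
  report[[part]]
}

#' Ratio-error pair between a measured and a reference body
#'
#' `A` is the error of the chest-to-waist circumference ratio and `B` the
#' error of the (left) arm-to-thigh circumference ratio. In the default
#' relative mode each is `|r_measured - r_reference| / r_reference`; ratios
#' are scale-free, so uniform scaling of either report leaves both errors
#' unchanged.
#'
#' @param measured,reference `measurement_report`s (or named lists with
#'   `chest`, `waist`, `left_arm`, `left_thigh`).
#' @param mode `"relative"` (default) or `"absolute"` (plain `|dr|`).
#' @return List with nonnegative components `A` and `B`.
#' @export
ratio_error_pair <- function(measured, reference,
                             mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  one <- function(num, den) {
    m <- .report_girth(measured, num) / .report_girth(measured, den)
    r <- .report_girth(reference, num) / .report_girth(reference, den)
    if (!is.finite(r) || r == 0)
      stop("ratio_error_pair: undefined reference ratio ", num, "/", den,
           call. = FALSE)
    if (mode == "relative") abs(m - r) / r else abs(m - r)
  }
  list(A = one("chest", "waist"), B = one("left_arm", "left_thigh"))
}

#' Camera placement error grid
#'
#' A long-format table of ratio-error pairs by camera height, subject
#' distance and generation model; broken cells (placements at which a model
#' failed to produce measurable bodies) carry `broken = TRUE` and are
#' excluded from selection.
#'
#' @param df data.frame with columns `height_m`, `distance_m`, `model`,
#'   `A`, `B` and optionally `broken` (logical, default `FALSE`).
#' @return A `camera_grid` object.
#' @export
camera_grid <- function(df) {
  need <- c("height_m", "distance_m", "model", "A", "B")
  if (!all(need %in% names(df)))
    stop("camera_grid: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$broken)) df$broken <- FALSE
  df$broken <- as.logical(df$broken)
  if (any(df$height_m <= 0) || any(df$distance_m <= 0))
    stop("camera_grid: heights and distances must be positive", call. = FALSE)
  if (!any(!df$broken))
    stop("camera_grid: no usable (non-broken) cells", call. = FALSE)
  if (any(!df$broken & (df$A < 0 | df$B < 0)))
    stop("camera_grid: ratio errors must be nonnegative", call. = FALSE)
  structure(df, class = c("camera_grid", "data.frame"))
}

#' Read a camera grid from CSV
#' @param path CSV with the [camera_grid()] columns.
#' @return A `camera_grid`.
#' @export
read_camera_grid <- function(path) {
  camera_grid(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The reference camera-placement error grid
#'
#' The published height-by-distance grid of (A, B) ratio errors for the two
#' usable generation models (SMPL and PIFuHD) at camera heights 0.5/1/1.5 m
#' and subject distances 1.5-4 m; the PIFuHD 4 m cells are broken (no
#' measurable body was generated there). Shipped as a plain-text CSV in
#' `inst/extdata/camera_error_grid.csv`.
#'
#' @return A `camera_grid`.
#' @export
camera_grid_reference <- function() {
  read_camera_grid(system.file("extdata", "camera_error_grid.csv",
                               package = "anthromesh", mustWork = TRUE))
}

#' Select the camera placement minimizing both ratio errors
#'
#' For each model, the non-broken cell minimizing `A + B` is found; when
#' every model nominates the same (height, distance) cell that placement is
#' returned with `agreement = TRUE`, otherwise the cell minimizing the sum
#' of `A + B` over all models (restricted to cells usable for every model)
#' is returned and flagged. On the reference grid both models select the
#' 1 m height / 3 m distance placement.
#'
#' @param grid a [camera_grid()].
#' @return List with `cam_height`, `cam_distance` (m), `per_model`
#'   (data.frame of each model's minimizer) and `agreement`.
#' @export
select_camera <- function(grid) {
  stopifnot(inherits(grid, "camera_grid"))
  usable <- grid[!grid$broken, , drop = FALSE]
  if (nrow(usable) == 0) stop("select_camera: empty grid", call. = FALSE)
  models <- unique(usable$model)
  per_model <- do.call(rbind, lapply(models, function(m) {
    g <- usable[usable$model == m, , drop = FALSE]
    k <- which.min(g$A + g$B)
    data.frame(model = m, height_m = g$height_m[k],
               distance_m = g$distance_m[k], score = g$A[k] + g$B[k])
  }))
  agree <- nrow(unique(per_model[, c("height_m", "distance_m")])) == 1
  if (agree) {
    return(list(cam_height = per_model$height_m[1],
                cam_distance = per_model$distance_m[1],
                per_model = per_model, agreement = TRUE))
  }
  # disagreement: minimize the total score over cells usable for all models
  key <- paste(usable$height_m, usable$distance_m)
  counts <- table(key)
  full <- names(counts)[counts == length(models)]
  pool <- usable[key %in% full, , drop = FALSE]
  if (nrow(pool) == 0) pool <- usable
  agg <- stats::aggregate(cbind(score = A + B) ~ height_m + distance_m,
                          data = pool, FUN = sum)
  k <- which.min(agg$score)
  list(cam_height = agg$height_m[k], cam_distance = agg$distance_m[k],
       per_model = per_model, agreement = FALSE)
}

#' Per-part error and accuracy summary
#'
#' For each part, the percent error `100 * |actual - generated| / actual`;
#' the summary is their mean and the accuracy `100 - mean`. Parts with a
#' zero actual value are excluded with a warning. Scaling both reports by
#' the same factor leaves every percent error unchanged.
#'
#' @param measured,reference `measurement_report`s or named numeric vectors
#'   (`reference` holds the actual values).
#' @param parts part names to compare; defaults to the parts present in
#'   both inputs when they are named vectors.
#' @return An `error_summary`: `per_part` (named percent errors),
#'   `mean_error` and `accuracy` (percent, summing to 100).
#' @export
error_summary <- function(measured, reference, parts = NULL) {
  if (is.null(parts)) {
    if (is.numeric(measured) && is.numeric(reference))
      parts <- intersect(names(measured), names(reference))
    else stop("error_summary: parts must be given for report inputs",
              call. = FALSE)
  }
  errs <- vapply(parts, function(pn) {
    a <- .report_girth(reference, pn)
    g <- .report_girth(measured, pn)
    if (is.null(a) || is.null(g) || is.na(a) || is.na(g))
      stop("error_summary: part '", pn, "' missing from a report",
           call. = FALSE)
    if (a == 0) return(NA_real_)
    100 * abs(a - g) / a
  }, numeric(1))
  if (anyNA(errs)) {
    warning("error_summary: excluded part(s) with zero actual value: ",
            paste(parts[is.na(errs)], collapse = ", "))
    errs <- errs[!is.na(errs)]
  }
  if (length(errs) == 0)
    stop("error_summary: no comparable parts", call. = FALSE)
  aggregate_accuracy(errs)
}

#' Aggregate per-part error rates into mean error and accuracy
#'
#' The averaging rule applied to a vector of per-part percent errors:
#' `mean_error = mean(errors)`, `accuracy = 100 - mean_error`.
#'
#' @param per_part_errors numeric vector of percent errors (optionally
#'   named by part).
#' @return An `error_summary` object.
#' @export
aggregate_accuracy <- function(per_part_errors) {
  m <- mean(per_part_errors)
  structure(list(per_part = per_part_errors, mean_error = m,
                 accuracy = 100 - m),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("<error_summary>\n")
  if (!is.null(names(x$per_part))) print(round(x$per_part, 2))
  cat(sprintf("mean error %.3f%%  accuracy %.3f%%\n",
              x$mean_error, x$accuracy))
  invisible(x)
}
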