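# Vertex reduction with an information-loss guard, and height calibration.
# Body scans arrive with ~250k vertices; reducing them in 10,000-vertex steps
# down to a 60,000-vertex floor keeps training-scale data tractable while a
# girth-based loss metric guards against losing measurable body information.

#' Decimate a mesh to a target vertex count
#'
#' Iterative shortest-edge collapse with midpoint placement. Each collapse
#' removes exactly one vertex, so the result has exactly `target_vertices`
#' vertices when the input has more, and is returned unchanged otherwise.
#'
#' @param mesh a [trimesh].
#' @param target_vertices positive integer, at least 4.
#' @return A decimated [trimesh].
#' @export
decimate_to <- function(mesh, target_vertices) {
  validate_trimesh(mesh)
  if (!is.numeric(target_vertices) || length(target_vertices) != 1 ||
      target_vertices < 4)
    stop("decimate_to: target_vertices must be a single integer >= 4",
         call. = FALSE)
  target_vertices <- as.integer(target_vertices)
  if (n_vertices(mesh) <= target_vertices) return(mesh)
  res <- collapse_decimate(mesh$vertices, mesh$faces, target_vertices)
  trimesh(res$vertices, res$faces)
}

#' Girth-based information loss between a mesh and its reference
#'
#' The failure mode of aggressive vertex reduction is losing measurable body
#' information, so the loss metric is dimensional, not visual: horizontal
#' probe planes at 10%, 30%, 45%, 55% and 72% of the reference body height
#' are sectioned through both meshes and the largest relative deviation of
#' the total section perimeter is returned. The metric is normalized by the
#' reference perimeter and is therefore not symmetric in its arguments.
#'
#' @param mesh a [trimesh] (typically decimated).
#' @param reference the reference [trimesh] it is compared against.
#' @param probe_fractions probe plane heights as fractions of the reference
#'   vertical extent.
#' @return Fraction in `[0, 1]`-ish scale; 0 when all probe girths agree.
#' @export
information_loss <- function(mesh, reference,
                             probe_fractions = c(0.10, 0.30, 0.45, 0.55, 0.72)) {
  bbr <- range(reference$vertices[, 2])
  ys <- bbr[1] + probe_fractions * diff(bbr)
  losses <- vapply(ys, function(y) {
    pr <- sum(cross_section(reference, y)$perimeter)
    pm <- sum(cross_section(mesh, y)$perimeter)
    if (pr == 0 && pm == 0) return(NA_real_)  # plane misses both: skipped
    if (pr == 0) return(NA_real_)
    abs(pm - pr) / pr
  }, numeric(1))
  if (all(is.na(losses)))
    stop("information_loss: every probe plane missed both meshes",
         call. = FALSE)
  max(losses, na.rm = TRUE)
}

#' Stepwise vertex reduction with a loss guard
#'
#' Repeatedly removes `step` vertices; stops before the first step that
#' would drop below `floor` vertices or whose cumulative information loss
#' (running maximum of the probe-girth deviation against the original mesh;
#' nested decimation can only degrade the retained information) exceeds
#' `max_loss`, whichever comes first.
#'
#' @param mesh a [trimesh].
#' @param step vertices removed per step (default 10,000).
#' @param floor minimum vertex count (default 60,000, below which body
#'   information is judged lost).
#' @param max_loss maximum tolerated information loss fraction.
#' @return A `decimation_trace`: list with `steps` (data.frame of
#'   `vertex_count`, `loss`) and `final_mesh`.
#' @export
reduce_stepwise <- function(mesh, step = 10000, floor = 60000,
                            max_loss = 0.05) {
  if (step <= 0) stop("reduce_stepwise: step must be positive", call. = FALSE)
  if (floor < 4) stop("reduce_stepwise: floor must be >= 4", call. = FALSE)
  reference <- mesh
  current <- mesh
  counts <- integer(0)
  losses <- numeric(0)
  run_max <- 0
  repeat {
    target <- n_vertices(current) - step
    if (target < floor) break
    candidate <- decimate_to(current, target)
    loss <- max(run_max, information_loss(candidate, reference))
    if (loss > max_loss) break
    run_max <- loss
    current <- candidate
    counts <- c(counts, n_vertices(candidate))
    losses <- c(losses, loss)
  }
  structure(list(steps = data.frame(vertex_count = counts, loss = losses),
                 final_mesh = current),
            class = "decimation_trace")
}

#' @export
print.decimation_trace <- function(x, ...) {
  cat(sprintf("<decimation_trace> %d accepted steps, final mesh %d vertices\n",
              nrow(x$steps), n_vertices(x$final_mesh)))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' Resize a mesh to the subject's actual height
#'
#' Uniform similarity scaling about the floor point (the bounding-box centre
#' at minimum Y) so the vertical extent equals `actual_height_cm`. All
#' girths scale by the same factor and volumes by its cube.
#'
#' @param mesh a [trimesh] with positive vertical extent.
#' @param actual_height_cm subject stature in cm.
#' @return The rescaled [trimesh].
#' @export
resize_to_height <- function(mesh, actual_height_cm) {
  if (!is.numeric(actual_height_cm) || length(actual_height_cm) != 1 ||
      actual_height_cm <= 0)
    stop("resize_to_height: height must be a positive number (cm)",
         call. = FALSE)
  h <- mesh_height(mesh)
  if (h <= 0)
    stop("resize_to_height: mesh has no vertical extent", call. = FALSE)
  bb <- mesh_bbox(mesh)
  center <- c(mean(bb[, 1]), bb[1, 2], mean(bb[, 3]))
  mesh_scale_about(mesh, actual_height_cm * 10 / h, center)
}
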