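# End-to-end wiring: load (or synthesize) a mesh, optionally decimate,
# render the frontal depth map at the default error-minimizing camera
# placement, detect seed points, resize to the stated stature and emit the
# measurement report plus intermediate artifacts.

#' Pipeline run configuration
#'
#' @param input path to an STL/OBJ mesh, or `NULL` to run on the default
#'   synthetic humanoid.
#' @param unit unit of the input mesh coordinates.
#' @param height_cm subject stature for resizing calibration, or `NULL` to
#'   keep the mesh scale.
#' @param camera a [camera_config()].
#' @param width,height depth-map resolution, px.
#' @param decimate `NULL`, or a list with `step`, `floor`, `max_loss`
#'   passed to [reduce_stepwise()].
#' @param out_dir output directory for artifacts.
#' @param seed RNG seed (the pipeline itself is deterministic; the seed
#'   feeds the synthetic generator when no input is given).
#' @param verbose log stage progress to stderr.
#' @return A `run_config` object.
#' @export
run_config <- function(input = NULL, unit = "mm", height_cm = NULL,
                       camera = camera_config(), width = 512, height = 512,
                       decimate = NULL, out_dir = tempfile("anthromesh_run"),
                       seed = 0, verbose = TRUE) {
  structure(list(input = input, unit = unit, height_cm = height_cm,
                 camera = camera, width = width, height = height,
                 decimate = decimate, out_dir = out_dir, seed = seed,
                 verbose = verbose),
            class = "run_config")
}

#' Run the measurement pipeline
#'
#' Stages: load (or synthesize) the mesh, optional stepwise decimation,
#' resizing to the stated stature, frontal depth-map rendering, seed-point
#' detection, segmentation and measurement. Artifacts written to
#' `cfg$out_dir`: `depth.png` (+ depth channel and camera JSON),
#' `seeds.json`, `report.json` and `report.csv`. Logging goes to stderr;
#' file outputs are machine-readable. A failing stage raises an error whose
#' message names the stage; artifacts produced so far are retained.
#'
#' @param cfg a [run_config()].
#' @return The `measurement_report`, invisibly.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  log <- function(...) if (isTRUE(cfg$verbose)) message("[anthromesh] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    log(sprintf("%-10s %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  mesh <- stage("load", {
    if (is.null(cfg$input)) {
      make_humanoid(body_params())$mesh
    } else if (!file.exists(cfg$input)) {
      stop("input file not found: ", cfg$input)
    } else if (grepl("\\.obj$", cfg$input, ignore.case = TRUE)) {
      read_obj(cfg$input, unit = cfg$unit)
    } else {
      read_stl(cfg$input, unit = cfg$unit)
    }
  })
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$decimate)) {
    mesh <- stage("decimate", {
      d <- cfg$decimate
      tr <- reduce_stepwise(mesh, step = d$step %||% 10000,
                            floor = d$floor %||% 60000,
                            max_loss = d$max_loss %||% 0.05)
      utils::write.csv(tr$steps, file.path(cfg$out_dir, "decimation.csv"),
                       row.names = FALSE)
      tr$final_mesh
    })
  }
  if (!is.null(cfg$height_cm)) {
    mesh <- stage("resize", resize_to_height(mesh, cfg$height_cm))
  }
  dm <- stage("render", {
    d <- render_depth_map(mesh, cfg$camera, cfg$width, cfg$height)
    save_depth_map(d, file.path(cfg$out_dir, "depth"))
    d
  })
  seeds <- stage("landmarks", {
    s <- detect_seed_points(dm)
    write_seed_points(s, file.path(cfg$out_dir, "seeds.json"))
    s
  })
  stage("segment", {
    seg <- segment_body(dm, seeds)
    counts <- tabulate(seg$labels + 1L, nbins = length(seg$levels))
    jsonlite::write_json(stats::setNames(as.list(counts), seg$levels),
                         file.path(cfg$out_dir, "segments.json"),
                         auto_unbox = TRUE)
    seg
  })
  report <- stage("measure", measure_report(mesh, seeds))
  stage("report", {
    out <- list(height_cm = report$height,
                circumferences_cm = as.list(report$circumferences),
                chest_volume_l = report$chest_volume,
                lengths_cm = as.list(report$lengths))
    jsonlite::write_json(out, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report_as_table(report),
                     file.path(cfg$out_dir, "report.csv"), row.names = FALSE)
  })
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
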