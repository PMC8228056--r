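#' Run the full movement-analysis pipeline
#'
#' Orchestrates the whole evaluation chain for one cage: obtain two-camera
#' detection streams (either simulated or read from CSV), compute
#' frame-pair norms and per-second series per camera, fuse the cameras,
#' apply the sliding-window mean, calibrate or load activity thresholds,
#' classify, and write the duration accounting, the binned activity
#' overview and the residence products, together with a JSON run log.
#'
#' @param config Named list (or YAML path, see [read_run_config()]) with
#'   fields:
#'   \describe{
#'     \item{mode}{`"simulate"` or `"streams"` (exactly one input mode).}
#'     \item{sim}{For simulate mode: arguments for [sim_config()].}
#'     \item{stream_a, stream_b}{For streams mode: per-camera detection
#'       CSV paths (`stream_b` optional).}
#'     \item{window_s, step_s, min_coverage}{Sliding-window parameters
#'       (defaults 30, 1, 0.5).}
#'     \item{thresholds}{Optional list/file with the two threshold values;
#'       in simulate mode, omitted thresholds are calibrated from
#'       ground-truth reference segments.}
#'     \item{segments}{Optional CSV path of calibration segments
#'       (`level`, `summary`).}
#'     \item{bin_s}{Overview bin width (default 1800).}
#'     \item{grid_nx, grid_ny}{Occupancy grid size (defaults 32, 18).}
#'     \item{out_dir}{Output directory (created).}
#'     \item{seed}{Integer seed for every random stage.}
#'   }
#' @return Invisibly, a list with the main in-memory products (`fused`,
#'   `windowed`, `timeline`, `durations`, `overview`, `thresholds`,
#'   `grid`) and `files`, the manifest of written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  mode <- config$mode %||% stop_fw("config must set mode ('simulate' or 'streams')")
  if (!mode %in% c("simulate", "streams")) stop_fw("unknown mode '%s'", mode)
  out_dir <- config$out_dir %||% stop_fw("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  window_s <- config$window_s %||% 30
  step_s <- config$step_s %||% 1
  min_coverage <- config$min_coverage %||% 0.5
  bin_s <- config$bin_s %||% 1800
  seed <- config$seed
  files <- character(0)
  log <- list(package = "foxwatch",
              version = as.character(utils::packageVersion("foxwatch")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              mode = mode, stages = list())
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  truth <- NULL
  if (mode == "simulate") {
    sim_args <- config$sim %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    scfg <- do.call(sim_config, sim_args)
    traj <- simulate_trajectory(scfg)
    cams <- names(scfg$cameras)
    if (length(cams) < 1) stop_fw("simulate mode needs at least one camera")
    stream_a <- render_detections(traj, cams[[1]],
                                  seed = if (is.null(seed)) NULL else seed + 1)
    stream_b <- if (length(cams) >= 2) {
      render_detections(traj, cams[[2]],
                        seed = if (is.null(seed)) NULL else seed + 2)
    }
    truth <- true_activity_labels(traj)
    emit("truth.csv", function(p) utils::write.csv(
      data.frame(frame = traj$frame, time_s = traj$time_s,
                 x = traj$x, y = traj$y, state = traj$state),
      p, row.names = FALSE))
    emit("detections_a.csv", function(p) write_detection_stream(stream_a, p))
    if (!is.null(stream_b)) {
      emit("detections_b.csv", function(p) write_detection_stream(stream_b, p))
    }
    log$stages$simulate <- list(n_frames = nrow(traj), cameras = cams)
  } else {
    if (is.null(config$stream_a)) stop_fw("streams mode needs stream_a")
    stream_a <- read_detection_stream(config$stream_a)
    stream_b <- if (!is.null(config$stream_b)) read_detection_stream(config$stream_b)
  }

  per_second <- function(stream) per_second_series(frame_pair_norms(stream),
                                                   fps = config$sim$fps %||% 5)
  sec_a <- per_second(stream_a)
  emit("per_second_a.csv", function(p) write_motion_series(sec_a, p))
  if (!is.null(stream_b)) {
    sec_b <- per_second(stream_b)
    emit("per_second_b.csv", function(p) write_motion_series(sec_b, p))
    fused <- fuse_series(sec_a, sec_b)
    emit("fused.csv", function(p) utils::write.csv(
      data.frame(time_s = fused$time_s, value = fused$value,
                 value_a = fused$value_a, value_b = fused$value_b,
                 source = fused$source), p, row.names = FALSE, na = ""))
  } else {
    fused <- sec_a
  }
  log$stages$motion <- list(n_seconds = nrow(fused),
                            n_missing = sum(is.na(fused$value)))

  windowed <- sliding_mean(fused, window_s = window_s, step_s = step_s,
                           min_coverage = min_coverage)
  emit("windowed.csv", function(p) write_motion_series(windowed, p))

  thresholds <- resolve_thresholds(config, truth, windowed, window_s)
  emit("thresholds.yaml", function(p) write_thresholds(thresholds, p))

  timeline <- classify_activity(windowed, thresholds)
  emit("timeline.csv", function(p) utils::write.csv(timeline, p, row.names = FALSE))
  durations <- activity_durations(timeline)
  emit("durations.csv", function(p) utils::write.csv(
    data.frame(level = names(durations), seconds = as.numeric(durations)),
    p, row.names = FALSE))
  overview <- activity_overview(timeline, bin_s = bin_s)
  emit("overview.csv", function(p) utils::write.csv(overview, p, row.names = FALSE))
  log$stages$activity <- as.list(durations)

  residence_stream <- if (!is.null(stream_b)) {
    prefer_first_camera(stream_a, stream_b)
  } else {
    stream_a
  }
  trace <- residence_trace(residence_stream)
  emit("residence_trace.csv", function(p) utils::write.csv(trace, p, row.names = FALSE))
  grid <- occupancy_grid(trace, nx = config$grid_nx %||% 32, ny = config$grid_ny %||% 18)
  emit("occupancy.csv", function(p) write_occupancy_grid(grid, p))
  log$stages$residence <- list(n_points = grid$n_points)

  log$config <- config
  log$config_digest <- fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                null = "null", digits = NA))
  log$files <- basename(files)
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, log_path)

  invisible(list(fused = fused, windowed = windowed, timeline = timeline,
                 durations = durations, overview = overview,
                 thresholds = thresholds, grid = grid, files = files))
}

# thresholds: explicit values > segment file > ground-truth calibration
resolve_thresholds <- function(config, truth, windowed, window_s) {
  th <- config$thresholds
  if (!is.null(th)) {
    if (is.character(th)) return(read_thresholds(th))
    return(activity_thresholds(th$theta_inactive_active, th$theta_active_high))
  }
  if (!is.null(config$segments)) {
    return(calibrate_thresholds(utils::read.csv(config$segments)))
  }
  if (!is.null(truth)) {
    segs <- reference_segments(truth, windowed, window_s = window_s)
    return(calibrate_thresholds(segs))
  }
  stop_fw("no thresholds: provide 'thresholds', 'segments', or run in simulate mode")
}

# union of two cameras' detections: camera A's box when present, else B's
prefer_first_camera <- function(stream_a, stream_b) {
  merged <- stream_a
  if (nrow(stream_b) != nrow(stream_a) ||
      any(stream_b$frame_index != stream_a$frame_index)) {
    stop_fw("camera streams cover different frames")
  }
  take_b <- is.na(merged$cx) & !is.na(stream_b$cx)
  for (col in c("cx", "cy", "w", "h", "confidence")) {
    merged[[col]][take_b] <- stream_b[[col]][take_b]
  }
  merged
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file whose keys match the `config` argument of
#'   [run_pipeline()].
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
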