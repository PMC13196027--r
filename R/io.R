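# Frame input, result writers and the end-to-end analysis runner.

FRAME_EXT <- "\\.(png|tif|tiff)$"
VIDEO_EXT <- "\\.(mp4|avi|mov|mkv)$"

to_grayscale <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      return(0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3])
    return(a[, , 1])
  }
  stop_domain("unsupported image array shape")
}

#' Read a frame sequence from disk
#'
#' Reads a directory of numbered PNG/TIFF frames in lexicographic
#' order; color frames are converted to grayscale by BT.709 luminance.
#' Container videos (mp4/avi/...) must be pre-extracted to frames
#' (e.g. `ffmpeg -i video.mp4 frames/%06d.png`): this reader handles
#' image directories only.
#'
#' @param path directory containing the frames.
#' @param calibration a [calibration_state()]; its frame dimensions are
#'   checked against the images.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, calibration) {
  if (file.exists(path) && !dir.exists(path)) {
    if (grepl(VIDEO_EXT, path, ignore.case = TRUE))
      stop_domain(paste0(
        "container video input is not supported; extract frames to a ",
        "directory first (e.g. ffmpeg -i video.mp4 frames/%06d.png)"))
    stop_domain(sprintf("'%s' is not a frame directory", path))
  }
  if (!dir.exists(path)) stop_domain(sprintf("no such directory: '%s'", path))
  files <- sort(list.files(path, pattern = FRAME_EXT, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0)
    stop_domain(sprintf("no PNG/TIFF frames found in '%s'", path))
  frames <- vector("list", length(files))
  d <- NULL
  for (i in seq_along(files)) {
    img <- tryCatch({
      if (grepl("\\.png$", files[i], ignore.case = TRUE))
        png::readPNG(files[i])
      else tiff::readTIFF(files[i])
    }, error = function(e) stop_domain(
      sprintf("cannot read frame '%s': %s", files[i], conditionMessage(e))))
    m <- to_grayscale(img)
    if (is.null(d)) d <- dim(m)
    else if (!all(dim(m) == d))
      stop_domain(sprintf("frame '%s' has inconsistent shape", files[i]))
    frames[[i]] <- m
  }
  if (!missing(calibration) &&
      (d[1] != calibration$frame_height_px ||
       d[2] != calibration$frame_width_px))
    stop_domain(sprintf(
      "frames are %d x %d px but calibration says %d x %d",
      d[2], d[1], calibration$frame_width_px, calibration$frame_height_px))
  if (missing(calibration))
    stop_domain("`calibration` is required for directory input")
  frame_sequence(frames, calibration)
}

#' Analysis configuration
#'
#' Bundles every parameter of a run with defaults; the effective
#' configuration is echoed to disk alongside the results so any run can
#' be reproduced from its output directory alone.
#'
#' @param input a frame directory path or a [frame_sequence()].
#' @param mode `"topdown"` (population optical flow) or `"bottomup"`
#'   (single-cell tracking).
#' @param calibration a [calibration_state()] (required for directory
#'   input).
#' @param out_dir output directory.
#' @param seg a [seg_params()] (bottomup).
#' @param topdown a [topdown_params()] (topdown).
#' @param link a [link_params()], or `NULL` to derive the gate as 3x
#'   the expected per-frame displacement.
#' @param expected_speed_um_s expected swimming speed used only to
#'   derive the default gate.
#' @param area_low_frac,area_high_frac pooled area-percentile filter
#'   fractions.
#' @param classifier `"speed"` or `"trajectory"` (bottomup report).
#' @param speed_threshold_um_s threshold of the speed classifier.
#' @param drift_policy drift handling of the topdown pipeline.
#' @param schedule optional [stimulus_schedule()] or path to a schedule
#'   JSON; enables photoshock analysis on the topdown speed series.
#' @param n_bins orientation histogram bins.
#' @param seed integer seed echoed with the config (analysis itself is
#'   deterministic).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(input, mode = c("topdown", "bottomup"),
                            calibration = NULL, out_dir,
                            seg = seg_params(), topdown = topdown_params(),
                            link = NULL, expected_speed_um_s = 100,
                            area_low_frac = 0.10, area_high_frac = 0.10,
                            classifier = c("speed", "trajectory"),
                            speed_threshold_um_s = 5,
                            drift_policy = c("consensus", "dark", "none"),
                            schedule = NULL, n_bins = 16, seed = 1L) {
  mode <- match.arg(mode)
  classifier <- match.arg(classifier)
  drift_policy <- match.arg(drift_policy)
  structure(list(input = input, mode = mode, calibration = calibration,
                 out_dir = out_dir, seg = seg, topdown = topdown,
                 link = link, expected_speed_um_s = expected_speed_um_s,
                 area_low_frac = area_low_frac,
                 area_high_frac = area_high_frac, classifier = classifier,
                 speed_threshold_um_s = speed_threshold_um_s,
                 drift_policy = drift_policy, schedule = schedule,
                 n_bins = n_bins, seed = as.integer(seed)),
            class = "analysis_config")
}

config_echo <- function(config, calibration) {
  cfg <- unclass(config)
  cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory frames>"
  cfg$calibration <- unclass(calibration)
  cfg$seg <- unclass(cfg$seg)
  td <- unclass(cfg$topdown); td$flow <- unclass(td$flow)
  cfg$topdown <- td
  cfg$link <- if (is.null(cfg$link)) NULL else unclass(cfg$link)
  cfg$schedule <- if (is.character(cfg$schedule)) cfg$schedule
                  else if (is.null(cfg$schedule)) NULL else "<in-memory schedule>"
  cfg
}

#' Run a full analysis and write the result bundle
#'
#' Reads the input frames, runs the selected pipeline and writes, to
#' `out_dir`: the echoed effective configuration (`config.json`), a
#' per-stage log (`analysis.log`), and either the speed-series CSV
#' (`speed_series.csv`, plus `photoshock.csv` when a stimulus schedule
#' is given) for the topdown mode, or the trajectory table
#' (`trajectories.csv`, `tracks.jsonl`), the motility report
#' (`motility_report.csv`, `motility_report.json`) and the orientation
#' histogram of motile tracks (`orientation.csv`) for the bottomup
#' mode. Identical input, configuration and seed produce byte-identical
#' outputs.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with the in-memory results and the paths
#'   written.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  frames <- if (inherits(config$input, "frame_sequence")) config$input
            else read_frames(config$input, config$calibration)
  cal <- attr(frames, "calibration")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("frames: %d (%d x %d px, %g fps, %g um/px)",
                   length(frames), cal$frame_width_px, cal$frame_height_px,
                   cal$frame_rate, cal$um_per_px),
           sprintf("mode: %s", config$mode))
  jsonlite::write_json(config_echo(config, cal),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths <- c(config = file.path(config$out_dir, "config.json"))
  results <- list()
  schedule <- config$schedule
  if (is.character(schedule)) schedule <- read_schedule_json(schedule)
  if (config$mode == "topdown") {
    drift <- NULL
    if (config$drift_policy == "dark")
      drift <- estimate_drift_dark(frames, config$topdown)
    speeds <- frame_pair_speeds(frames, config$topdown,
                                drift_policy = config$drift_policy,
                                drift = drift)
    p <- file.path(config$out_dir, "speed_series.csv")
    write.csv(speeds, p, row.names = FALSE)
    paths["speed_series"] <- p
    results$speed_series <- speeds
    log <- c(log, sprintf("frame pairs: %d; pairs with regions: %d",
                          nrow(speeds), sum(!is.na(speeds$mean_speed_um_s))),
             sprintf("mean speed: %.2f um/s",
                     mean(speeds$mean_speed_um_s, na.rm = TRUE)))
    if (!is.null(schedule)) {
      ps <- photoshock_response(speeds, schedule)
      p <- file.path(config$out_dir, "photoshock.csv")
      write.csv(ps, p, row.names = FALSE)
      paths["photoshock"] <- p
      results$photoshock <- ps
      log <- c(log, sprintf("pulses analysed: %d; responses: %d",
                            nrow(ps), sum(ps$responded)))
    }
  } else {
    dets <- lapply(seq_along(frames), function(i) {
      mask <- segment_frame(frames[[i]], config$seg)
      detect_cells(mask, frames[[i]], frame_index = i)
    })
    dets <- do.call(rbind, dets)
    n_raw <- nrow(dets)
    dets <- filter_by_area_percentile(dets, config$area_low_frac,
                                      config$area_high_frac)
    log <- c(log, sprintf("detections: %d raw, %d after area filter",
                          n_raw, nrow(dets)))
    lk <- config$link
    if (is.null(lk)) {
      disp <- config$expected_speed_um_s / (cal$um_per_px * cal$frame_rate)
      lk <- link_params(gate_px = 3 * disp)
    }
    tracks <- link_detections(dets, lk)
    tbl <- track_table(tracks, cal)
    log <- c(log, sprintf("tracks confirmed: %d", length(tracks)))
    p <- file.path(config$out_dir, "trajectories.csv")
    write.csv(tbl, p, row.names = FALSE)
    paths["trajectories"] <- p
    write_tracks_jsonl(tracks, file.path(config$out_dir, "tracks.jsonl"))
    paths["tracks_jsonl"] <- file.path(config$out_dir, "tracks.jsonl")
    report <- if (config$classifier == "speed")
      classify_by_speed(tbl, config$speed_threshold_um_s)
    else classify_by_trajectory_angle(tbl)
    p <- file.path(config$out_dir, "motility_report.csv")
    per <- report$per_track
    write.csv(per, p, row.names = FALSE)
    cat(sprintf("summary,motile_fraction,%.6f\n", report$motile_fraction),
        file = p, append = TRUE)
    paths["motility_report"] <- p
    jsonlite::write_json(
      list(classification_mode = report$classification_mode,
           absolute = report$absolute,
           motile_fraction = report$motile_fraction,
           parameters = report$parameters),
      file.path(config$out_dir, "motility_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["motility_report_json"] <-
      file.path(config$out_dir, "motility_report.json")
    motile_ids <- per$track_id[per$label == "motile"]
    oh <- orientation_histogram(
      per$mean_heading_deg[per$track_id %in% motile_ids], config$n_bins)
    p <- file.path(config$out_dir, "orientation.csv")
    write.csv(data.frame(bin_start_deg = head(oh$bin_edges_deg, -1),
                         bin_end_deg = tail(oh$bin_edges_deg, -1),
                         count = oh$counts,
                         relative_frequency = oh$relative_frequency),
              p, row.names = FALSE)
    paths["orientation"] <- p
    results$tracks <- tracks
    results$track_table <- tbl
    results$report <- report
    results$orientation <- oh
    log <- c(log, sprintf("motile fraction: %.3f (%s)",
                          report$motile_fraction,
                          report$classification_mode))
  }
  writeLines(log, file.path(config$out_dir, "analysis.log"))
  paths["log"] <- file.path(config$out_dir, "analysis.log")
  invisible(c(results, list(paths = paths)))
}

#' Generate a synthetic fixture on disk
#'
#' Simulates and renders a scene and writes it with [write_fixture()].
#'
#' @param config a [scene_config()] or the path to a `scene.json` file
#'   (the format echoed by [write_fixture()]).
#' @param out_dir fixture directory.
#' @return the output directory, invisibly.
#' @export
simulate_scene_fixture <- function(config, out_dir) {
  if (is.character(config)) config <- read_scene_config(config)
  truth <- simulate_tracks(config)
  frames <- render_frames(truth, config)
  write_fixture(frames, truth, out_dir)
}

#' Read a scene configuration from JSON
#'
#' @param path path to a `scene.json` file.
#' @return a [scene_config()].
#' @export
read_scene_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("populations", "calibration", "n_frames", "drift_um_per_frame",
             "background_level", "noise_sd", "seed", "speed_scale")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop_domain(sprintf("unknown scene config key(s): %s",
                        paste(unknown, collapse = ", ")))
  cal <- calibration_state(cfg$calibration$um_per_px,
                           cfg$calibration$frame_rate,
                           cfg$calibration$frame_width_px,
                           cfg$calibration$frame_height_px)
  pops <- cfg$populations
  if (is.data.frame(pops)) pops <- split(pops, seq_len(nrow(pops)))
  pops <- lapply(pops, function(p)
    particle_population(kind = p$kind, count = p$count,
                        speed_um_s = p$speed_um_s,
                        speed_sd_um_s = p$speed_sd_um_s %||% 0,
                        heading_mode = p$heading_mode %||% "isotropic",
                        heading_deg = p$heading_deg %||% 0,
                        kappa = p$kappa %||% 4,
                        turn_sd_deg = p$turn_sd_deg %||% 0,
                        radius_um = p$radius_um %||% 4,
                        intensity = p$intensity %||% 0.8))
  scene_config(pops, cal, cfg$n_frames,
               drift_um_per_frame = cfg$drift_um_per_frame %||% c(0, 0),
               background_level = cfg$background_level %||% 0.1,
               noise_sd = cfg$noise_sd %||% 0.02,
               seed = cfg$seed %||% 1L,
               speed_scale = cfg$speed_scale)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
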