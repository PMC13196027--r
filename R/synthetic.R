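# Ground-truthed synthetic scenes.
#
# The generator emulates the population structure the analysis pipelines
# assume: bright roughly-circular cells on a darker noisy background,
# with three motion classes — ballistic swimmers with heading
# persistence, sedimenters moving uniformly straight down, and adherent
# (stationary) cells — plus an optional uniform bulk drift.

#' Describe one particle population of a synthetic scene
#'
#' @param kind one of `"swimmer"`, `"sedimenter"`, `"adherent"`.
#' @param count number of particles (>= 0).
#' @param speed_um_s mean own speed in um/s (forced to 0 for adherent
#'   cells).
#' @param speed_sd_um_s between-particle speed spread (>= 0).
#' @param heading_mode `"isotropic"`, `"fixed"` or `"biased"`. Ignored
#'   for sedimenters, which always head straight down (180 deg).
#' @param heading_deg reference heading for `"fixed"`/`"biased"` modes.
#' @param kappa concentration of the `"biased"` mode; headings are drawn
#'   from a wrapped normal with angular sd `(180/pi)/sqrt(kappa)` deg.
#' @param turn_sd_deg per-frame Gaussian heading diffusion of swimmers
#'   (>= 0; forced to 0 for sedimenters and adherent cells).
#' @param radius_um cell radius in um (> 0).
#' @param intensity mean brightness of the rendered cell in `[0, 1]`.
#' @return an object of class `particle_population`.
#' @export
particle_population <- function(kind = c("swimmer", "sedimenter", "adherent"),
                                count, speed_um_s = 0, speed_sd_um_s = 0,
                                heading_mode = c("isotropic", "fixed", "biased"),
                                heading_deg = 0, kappa = 4,
                                turn_sd_deg = 0, radius_um = 4,
                                intensity = 0.8) {
  kind <- match.arg(kind)
  heading_mode <- match.arg(heading_mode)
  if (count < 0 || count != round(count))
    stop_domain("`count` must be a non-negative integer")
  check_positive(radius_um = radius_um,
                 speed_um_s = speed_um_s, speed_sd_um_s = speed_sd_um_s,
                 turn_sd_deg = turn_sd_deg,
                 .allow_zero = c("speed_um_s", "speed_sd_um_s", "turn_sd_deg"))
  if (intensity < 0 || intensity > 1)
    stop_domain("`intensity` must be in [0, 1]")
  if (kind == "adherent") {
    speed_um_s <- 0; speed_sd_um_s <- 0; turn_sd_deg <- 0
  }
  if (kind == "sedimenter") {
    heading_mode <- "fixed"; heading_deg <- 180; turn_sd_deg <- 0
  }
  structure(
    list(kind = kind, count = as.integer(count), speed_um_s = speed_um_s,
         speed_sd_um_s = speed_sd_um_s, heading_mode = heading_mode,
         heading_deg = heading_deg, kappa = kappa,
         turn_sd_deg = turn_sd_deg, radius_um = radius_um,
         intensity = intensity),
    class = "particle_population")
}

#' Configure a synthetic scene
#'
#' @param populations a list of [particle_population()] objects.
#' @param calibration a [calibration_state()] giving frame geometry,
#'   um/px and frame rate.
#' @param n_frames number of frames (>= 2).
#' @param drift_um_per_frame uniform bulk drift added to every particle,
#'   as an (x, y) vector in um per frame (image y grows downward).
#' @param background_level background brightness in `[0, 1]`.
#' @param noise_sd Gaussian pixel noise sd (>= 0).
#' @param seed integer RNG seed; the same seed reproduces the scene
#'   bit-for-bit.
#' @param speed_scale optional numeric vector of length `n_frames`
#'   multiplying swimmer speeds frame-by-frame; a piecewise profile can
#'   impose stimulus-coupled pauses (e.g. a photoshock stop) without
#'   modelling the stimulus response itself.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(populations, calibration, n_frames,
                         drift_um_per_frame = c(0, 0),
                         background_level = 0.1, noise_sd = 0.02,
                         seed = 1L, speed_scale = NULL) {
  stopifnot(inherits(calibration, "calibration_state"))
  if (inherits(populations, "particle_population"))
    populations <- list(populations)
  if (!all(vapply(populations, inherits, TRUE, "particle_population")))
    stop_domain("`populations` must be particle_population objects")
  if (n_frames < 2) stop_domain("`n_frames` must be >= 2")
  if (length(drift_um_per_frame) != 2)
    stop_domain("`drift_um_per_frame` must have 2 components")
  if (background_level < 0 || background_level > 1)
    stop_domain("`background_level` must be in [0, 1]")
  if (noise_sd < 0) stop_domain("`noise_sd` must be >= 0")
  if (is.null(speed_scale)) speed_scale <- rep(1, n_frames)
  if (length(speed_scale) != n_frames || any(speed_scale < 0))
    stop_domain("`speed_scale` must be non-negative, length n_frames")
  structure(
    list(populations = populations, calibration = calibration,
         n_frames = as.integer(n_frames),
         drift_um_per_frame = as.numeric(drift_um_per_frame),
         background_level = background_level, noise_sd = noise_sd,
         seed = as.integer(seed), speed_scale = as.numeric(speed_scale)),
    class = "scene_config")
}

#' Simulate ground-truth particle trajectories
#'
#' Swimmers move ballistically at a per-particle constant own speed with
#' per-frame Gaussian heading perturbation; sedimenters move straight
#' down at constant speed; adherent cells are static. The configured
#' drift is added to every particle. Positions wrap toroidally at the
#' field-of-view borders and wrap events are flagged so trajectory-based
#' checks can exclude them.
#'
#' @param config a [scene_config()].
#' @return a `data.frame` of class `ground_truth` with columns
#'   `particle_id`, `kind`, `frame`, `x_um`, `y_um`, `speed_um_s`
#'   (instantaneous own speed, excluding drift), `heading_deg` and
#'   `wrapped`; the drift vector and config are attached as attributes.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  fov <- fov_um(config$calibration)
  w <- fov[["width_um"]]; h <- fov[["height_um"]]
  nf <- config$n_frames
  kinds <- unlist(lapply(config$populations, function(p) rep(p$kind, p$count)))
  n <- length(kinds)
  empty <- data.frame(particle_id = integer(), kind = character(),
                      frame = integer(), x_um = numeric(), y_um = numeric(),
                      speed_um_s = numeric(), heading_deg = numeric(),
                      wrapped = logical())
  if (n == 0) {
    return(structure(empty, class = c("ground_truth", "data.frame"),
                     drift_um_per_frame = config$drift_um_per_frame,
                     config = config))
  }
  set.seed(config$seed)
  speed <- numeric(n); turn_sd <- numeric(n); theta <- numeric(n)
  i0 <- 0L
  for (p in config$populations) {
    if (p$count == 0) next
    idx <- i0 + seq_len(p$count); i0 <- i0 + p$count
    s <- rnorm(p$count, p$speed_um_s, p$speed_sd_um_s)
    speed[idx] <- pmax(s, 0)
    turn_sd[idx] <- p$turn_sd_deg
    theta[idx] <- switch(p$heading_mode,
      isotropic = runif(p$count, 0, 360),
      fixed = rep(p$heading_deg, p$count),
      biased = (p$heading_deg +
                rnorm(p$count, 0, (180 / pi) / sqrt(p$kappa))) %% 360)
  }
  # hard-core initial placement: cells are solid bodies and must not
  # interpenetrate at t = 0 (overlapping renders would merge into one
  # segmentation blob for as long as the overlap lasts). Sequential
  # rejection sampling; gives up after 200 draws per cell so that very
  # dense configurations still initialize.
  radius <- unlist(lapply(config$populations,
                          function(p) rep(p$radius_um, p$count)))
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      xi <- runif(1, 0, w); yi <- runif(1, 0, h)
      if (i == 1) break
      j <- seq_len(i - 1)
      dx <- pmin(abs(x[j] - xi), w - abs(x[j] - xi))  # toroidal metric
      dy <- pmin(abs(y[j] - yi), h - abs(y[j] - yi))
      if (all(dx^2 + dy^2 >= (radius[j] + radius[i])^2)) break
    }
    x[i] <- xi; y[i] <- yi
  }
  per_frame_s <- 1 / config$calibration$frame_rate
  drift <- config$drift_um_per_frame
  res_x <- matrix(0, n, nf); res_y <- matrix(0, n, nf)
  res_theta <- matrix(0, n, nf); res_speed <- matrix(0, n, nf)
  res_wrap <- matrix(FALSE, n, nf)
  for (f in seq_len(nf)) {
    res_x[, f] <- x; res_y[, f] <- y
    res_theta[, f] <- theta
    res_speed[, f] <- speed * config$speed_scale[f]
    if (f == nf) break
    step_um <- res_speed[, f] * per_frame_s
    rad <- theta * pi / 180
    nx <- x + step_um * sin(rad) + drift[1]
    ny <- y - step_um * cos(rad) + drift[2]
    wrapped <- nx < 0 | nx >= w | ny < 0 | ny >= h
    x <- nx %% w; y <- ny %% h
    res_wrap[, f + 1] <- wrapped
    dtheta <- rnorm(n, 0, 1) * turn_sd
    theta <- (theta + dtheta) %% 360
  }
  out <- data.frame(
    particle_id = rep(seq_len(n), each = nf),
    kind = rep(kinds, each = nf),
    frame = rep(seq_len(nf), times = n),
    x_um = as.vector(t(res_x)), y_um = as.vector(t(res_y)),
    speed_um_s = as.vector(t(res_speed)),
    heading_deg = as.vector(t(res_theta)),
    wrapped = as.vector(t(res_wrap)))
  structure(out, class = c("ground_truth", "data.frame"),
            drift_um_per_frame = drift, config = config)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Render a ground truth into a frame sequence
#'
#' Each particle is drawn as an anti-aliased bright disk of its
#' configured radius on the background level; Gaussian pixel noise is
#' added, frames are clipped to `[0, 1]` and quantized to 8-bit levels.
#' Disks crossing a border are drawn wrapped, consistent with the
#' toroidal motion model.
#'
#' @param truth a `ground_truth` from [simulate_tracks()].
#' @param config the same [scene_config()] used for the simulation.
#' @return a [frame_sequence()].
#' @export
render_frames <- function(truth, config) {
  stopifnot(inherits(config, "scene_config"))
  cal <- config$calibration
  nr <- cal$frame_height_px; nc <- cal$frame_width_px
  radii_px <- vapply(config$populations,
                     function(p) p$radius_um / cal$um_per_px, 0)
  if (any(radii_px[vapply(config$populations, function(p) p$count > 0,
                          TRUE)] < 1))
    warning("particle radius below 1 px at this calibration; ",
            "sub-pixel cells segment unreliably")
  kind_int <- rep(seq_along(config$populations),
                  vapply(config$populations, function(p) p$count, 0L))
  intens <- vapply(config$populations, function(p) p$intensity, 0)
  set.seed(config$seed + 7919L)
  frames <- vector("list", config$n_frames)
  xc <- seq_len(nc) - 0.5  # pixel-centre x coordinates
  yc <- seq_len(nr) - 0.5
  for (f in seq_len(config$n_frames)) {
    img <- matrix(config$background_level, nr, nc)
    rows <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(rows) > 0) {
      for (k in seq_len(nrow(rows))) {
        pid <- rows$particle_id[k]
        rpx <- radii_px[kind_int[pid]]
        amp <- intens[kind_int[pid]] - config$background_level
        px <- rows$x_um[k] / cal$um_per_px
        py <- rows$y_um[k] / cal$um_per_px
        for (ox in c(-nc, 0, nc)) for (oy in c(-nr, 0, nr)) {
          cx <- px + ox; cy <- py + oy
          c0 <- max(1L, floor(cx - rpx - 1)); c1 <- min(nc, ceiling(cx + rpx + 1))
          r0 <- max(1L, floor(cy - rpx - 1)); r1 <- min(nr, ceiling(cy + rpx + 1))
          if (c0 > c1 || r0 > r1) next
          dx2 <- (xc[c0:c1] - cx)^2
          dy2 <- (yc[r0:r1] - cy)^2
          dist <- sqrt(outer(dy2, dx2, `+`))
          cov <- clamp01(rpx + 0.5 - dist)
          img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * cov
        }
      }
    }
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    frames[[f]] <- round(clamp01(img) * 255) / 255
  }
  frame_sequence(frames, cal)
}

#' Ordered grayscale frame sequence
#'
#' The common currency of both analysis pipelines: a list of numeric
#' matrices in `[0, 1]` (rows = image y, columns = image x) sharing one
#' [calibration_state()].
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param calibration a [calibration_state()].
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, calibration) {
  stopifnot(inherits(calibration, "calibration_state"), is.list(frames))
  if (length(frames) > 0) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == d), TRUE)
    if (!all(ok))
      stop_domain(sprintf("frame %d has inconsistent shape", which(!ok)[1]))
  }
  structure(frames, class = "frame_sequence", calibration = calibration)
}

#' @export
print.frame_sequence <- function(x, ...) {
  cal <- attr(x, "calibration")
  d <- if (length(x) > 0) dim(x[[1]]) else c(0, 0)
  cat(sprintf("<frame_sequence> %d frames of %d x %d px at %g fps, %g um/px\n",
              length(x), d[2], d[1], cal$frame_rate, cal$um_per_px))
  invisible(x)
}

#' @export
`[.frame_sequence` <- function(x, i) {
  frame_sequence(unclass(x)[i], attr(x, "calibration"))
}

#' Write a synthetic fixture to disk
#'
#' Layout: `frames/000001.png` ... (8-bit grayscale PNG), `truth.csv`
#' (columns `particle_id`, `kind`, `frame`, `x_um`, `y_um`,
#' `speed_um_s`) and `scene.json` echoing the full configuration
#' including the seed.
#'
#' @param frames a [frame_sequence()].
#' @param truth the matching `ground_truth`.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(frames, truth, directory) {
  config <- attr(truth, "config")
  dir.create(file.path(directory, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(directory))
    stop_domain(sprintf("cannot create fixture directory '%s'", directory))
  for (f in seq_along(frames)) {
    path <- file.path(directory, "frames", sprintf("%06d.png", f))
    png::writePNG(frames[[f]], path)
  }
  cols <- c("particle_id", "kind", "frame", "x_um", "y_um", "speed_um_s")
  write.csv(as.data.frame(truth)[, cols], file.path(directory, "truth.csv"),
            row.names = FALSE)
  cfg <- config
  cfg$calibration <- unclass(cfg$calibration)
  cfg$populations <- lapply(cfg$populations, unclass)
  jsonlite::write_json(unclass(cfg), file.path(directory, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return a list with elements `frames` (a [frame_sequence()]),
#'   `truth` (`data.frame`) and `config` (the echoed scene
#'   configuration, as a plain list).
#' @export
read_fixture <- function(directory) {
  cfg <- jsonlite::read_json(file.path(directory, "scene.json"),
                             simplifyVector = TRUE)
  cal <- calibration_state(cfg$calibration$um_per_px,
                           cfg$calibration$frame_rate,
                           cfg$calibration$frame_width_px,
                           cfg$calibration$frame_height_px)
  frames <- read_frames(file.path(directory, "frames"), cal)
  truth <- read.csv(file.path(directory, "truth.csv"))
  list(frames = frames, truth = truth, config = cfg)
}
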