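# Top-down, population-scale motility from dense optical flow.
#
# Pipeline per consecutive frame pair: dense flow -> magnitude
# thresholding -> motion-region extraction (edges + area filter) ->
# drift correction -> mean region speed in um/s.

#' Dense optical flow parameters
#'
#' @param window_px side of the local integration window in pixels.
#' @param pyramid_levels number of pyramid levels (coarse-to-fine).
#' @param iterations warp-refinement iterations per level.
#' @param presmooth number of binomial pre-smoothing passes applied to
#'   both frames before flow estimation (noise suppression).
#' @param min_eig smaller-eigenvalue threshold of the windowed
#'   structure tensor below which a pixel is treated as textureless and
#'   keeps zero flow; calibrated for images scaled to `[0, 1]`: about
#'   5x the windowed gradient noise floor at pixel noise sd 0.02 and
#'   far below the signal of a resolved cell edge.
#' @return a list of class `flow_params`.
#' @export
flow_params <- function(window_px = 15, pyramid_levels = 3, iterations = 3,
                        presmooth = 1, min_eig = 0.03) {
  check_positive(window_px = window_px, pyramid_levels = pyramid_levels,
                 iterations = iterations, presmooth = presmooth,
                 min_eig = min_eig, .allow_zero = c("presmooth", "min_eig"))
  structure(list(window_px = as.integer(window_px),
                 pyramid_levels = as.integer(pyramid_levels),
                 iterations = as.integer(iterations),
                 presmooth = as.integer(presmooth), min_eig = min_eig),
            class = "flow_params")
}

new_flow_field <- function(dx, dy, frames = c(NA_integer_, NA_integer_)) {
  magnitude <- sqrt(dx^2 + dy^2)
  angle <- heading_deg(dx, dy)
  angle[magnitude == 0] <- NA_real_
  structure(list(dx = dx, dy = dy, magnitude = magnitude,
                 angle_deg = angle, frames = frames),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d px, frames (%s, %s), max |v| %.3g px\n",
              ncol(x$dx), nrow(x$dx), x$frames[1], x$frames[2],
              max(x$magnitude)))
  invisible(x)
}

#' Dense displacement field between two frames
#'
#' Estimates a per-pixel displacement field with a pyramidal, iterative
#' Lucas-Kanade scheme (uniform integration window, coarse-to-fine warp
#' refinement). Deterministic for fixed parameters.
#'
#' @param frame_a,frame_b grayscale matrices in `[0, 1]` with identical
#'   dimensions (rows = image y, columns = image x).
#' @param params a [flow_params()].
#' @param frames optional source frame indices `(i, i+1)` recorded in
#'   the result.
#' @return a `flow_field` with per-pixel `dx`, `dy`, derived `magnitude`
#'   (px/frame) and `angle_deg` rasters.
#' @export
dense_flow <- function(frame_a, frame_b, params = flow_params(),
                       frames = c(NA_integer_, NA_integer_)) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b))
    stop_domain("frames must be matrices")
  if (!all(dim(frame_a) == dim(frame_b)))
    stop_domain("frames must share dimensions")
  res <- lk_flow_cpp(frame_a, frame_b, params$window_px,
                     params$pyramid_levels, params$iterations,
                     params$presmooth, params$min_eig)
  new_flow_field(res$dx, res$dy, frames)
}

#' Remove low-magnitude flow vectors
#'
#' Vectors with magnitude below the threshold are set to (0, 0); all
#' others pass unchanged. Idempotent.
#'
#' @param field a `flow_field`.
#' @param min_magnitude_px magnitude threshold in px/frame (>= 0).
#' @return the thresholded `flow_field`.
#' @export
threshold_flow <- function(field, min_magnitude_px) {
  stopifnot(inherits(field, "flow_field"))
  if (min_magnitude_px < 0) stop_domain("`min_magnitude_px` must be >= 0")
  drop <- field$magnitude < min_magnitude_px
  dx <- field$dx; dy <- field$dy
  dx[drop] <- 0; dy[drop] <- 0
  new_flow_field(dx, dy, field$frames)
}

#' Canny edge detection
#'
#' Binomial smoothing, Sobel gradients, non-maximum suppression along
#' the quantized gradient direction and two-threshold hysteresis (weak
#' edges are kept only when 8-connected to a strong pixel).
#'
#' @param frame grayscale matrix in `[0, 1]`.
#' @param sigma Gaussian smoothing sd in pixels (approximated by
#'   repeated binomial passes).
#' @param low,high hysteresis thresholds on the Sobel gradient
#'   magnitude; the defaults separate resolved cell edges (about 1 in
#'   these units) from the pixel-noise floor (about 0.05).
#' @return a logical matrix of edge pixels.
#' @export
canny_edges <- function(frame, sigma = 1, low = 0.10, high = 0.25) {
  passes <- max(0L, as.integer(round(2 * sigma^2)))
  canny_cpp(frame, passes, low, high)
}

new_motion_region <- function(pixels, area_px, dx_mean, dy_mean) {
  mag <- sqrt(dx_mean^2 + dy_mean^2)
  structure(list(pixels = pixels, area_px = area_px,
                 mean_vector = c(dx = dx_mean, dy = dy_mean),
                 mean_magnitude_px = mag,
                 mean_angle_deg = if (mag > 0) heading_deg(dx_mean, dy_mean)
                                  else NA_real_),
            class = "motion_region")
}

#' Extract per-cell motion regions from a thresholded flow field
#'
#' Cell footprints are isolated from the frame itself: Canny edge
#' contours are closed morphologically, hole-filled and labelled, and
#' components with an area outside the given bounds are discarded
#' (excluding small debris and large aggregates). A footprint becomes a
#' moving region when at least `min_moving_frac` of its pixels carry a
#' supra-threshold flow vector; its mean vector is the arithmetic mean
#' of those member-pixel vectors and its mean magnitude is the norm of
#' the mean vector (the cell is treated as a rigid translating body).
#' Footprints whose flow was removed by thresholding are stationary
#' cells: they stay in the region list with a zero mean vector, so a
#' population that stops swimming (photoshock) reads as speed ~0
#' rather than as an empty frame.
#'
#' @param field a thresholded `flow_field` (see [threshold_flow()]).
#' @param frame the grayscale frame the flow originates from.
#' @param area_bounds_px numeric `(min_px, max_px)` with `min < max`.
#' @param min_moving_frac minimum fraction of footprint pixels with
#'   surviving flow.
#' @return a list of `motion_region` objects (possibly empty).
#' @export
extract_motion_regions <- function(field, frame, area_bounds_px,
                                   min_moving_frac = 0.2) {
  stopifnot(inherits(field, "flow_field"))
  if (length(area_bounds_px) != 2 || area_bounds_px[1] >= area_bounds_px[2])
    stop_domain("`area_bounds_px` must be (min, max) with min < max")
  moving <- field$magnitude > 0
  edges <- canny_edges(frame)
  if (!any(edges)) return(list())
  closed <- close_diamond(edges)
  filled <- EBImage::fillHull(closed) > 0
  lab <- EBImage::bwlabel(filled)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  idx <- which(lab > 0)
  comps <- split(idx, lab[idx])
  out <- list()
  for (pix in comps) {
    area <- length(pix)
    if (area < area_bounds_px[1] || area > area_bounds_px[2]) next
    members <- pix[moving[pix]]
    reg <- if (length(members) >= min_moving_frac * area)
      new_motion_region(members, area, mean(field$dx[members]),
                        mean(field$dy[members]))
    else new_motion_region(pix, area, 0, 0)
    out[[length(out) + 1]] <- reg
  }
  out
}

#' Drift estimate constructor
#'
#' @param vector drift vector `(dx, dy)` in px/frame.
#' @param support number of contributing vectors.
#' @param mode one of `"consensus"`, `"dark_calibrated"`, `"none"`.
#' @param members optional indices of the contributing input vectors.
#' @return an object of class `drift_estimate`; `mode = "none"` forces
#'   a zero vector and zero support.
#' @export
drift_estimate <- function(vector = c(0, 0), support = 0L,
                           mode = c("none", "consensus", "dark_calibrated"),
                           members = integer()) {
  mode <- match.arg(mode)
  if (mode == "none") { vector <- c(0, 0); support <- 0L; members <- integer() }
  structure(list(vector = setNames(as.numeric(vector), c("dx", "dy")),
                 support = as.integer(support), mode = mode,
                 members = members),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("<drift_estimate> mode %s, vector (%.3g, %.3g) px, support %d\n",
              x$mode, x$vector[1], x$vector[2], x$support))
  invisible(x)
}

#' Consensus drift estimation from region vectors
#'
#' Bulk drift (sedimentation or fluid motion) moves the non-motile
#' majority coherently. The estimator finds the largest group of
#' vectors mutually within `angle_tol_deg` of the group's circular-mean
#' direction and within a relative magnitude band of the group median,
#' and returns the group's arithmetic mean as the drift vector. The
#' estimate is refused (`mode = "none"`) when the group is too small to
#' be trusted, or so large that collective directed swimming (strong
#' phototaxis) cannot be ruled out — in that case a dark pre-exposure
#' calibration ([estimate_drift_dark()]) must be used instead.
#'
#' @param vectors an n x 2 matrix of region mean vectors (px/frame), or
#'   a list of `motion_region`s.
#' @param angle_tol_deg angular tolerance in degrees (typically 5-10).
#' @param mag_tol_frac relative magnitude tolerance around the group
#'   median.
#' @param min_support_frac minimum fraction of all vectors the winning
#'   group must hold.
#' @param min_support_n minimum absolute number of coherent vectors; a
#'   "majority" of fewer cells is indistinguishable from chance
#'   alignment of swimmers.
#' @param max_support_frac fraction above which the estimate is refused
#'   as indistinguishable from collective motion.
#' @return a [drift_estimate()] with the contributing vector indices in
#'   `$members`.
#' @export
estimate_drift_consensus <- function(vectors, angle_tol_deg = 7.5,
                                     mag_tol_frac = 0.2,
                                     min_support_frac = 0.2,
                                     min_support_n = 5L,
                                     max_support_frac = 0.9) {
  if (is.list(vectors) && length(vectors) > 0 &&
      inherits(vectors[[1]], "motion_region"))
    vectors <- do.call(rbind, lapply(vectors, function(r) r$mean_vector))
  if (is.null(vectors) || length(vectors) == 0)
    return(drift_estimate(mode = "none"))
  vectors <- matrix(as.numeric(vectors), ncol = 2)
  n <- nrow(vectors)
  mag <- sqrt(rowSums(vectors^2))
  ang <- heading_deg(vectors[, 1], vectors[, 2])
  usable <- which(mag > 0)
  if (length(usable) == 0) return(drift_estimate(mode = "none"))
  best <- integer()
  for (seed in usable) {
    grp <- usable[ang_diff(ang[usable], ang[seed]) <= angle_tol_deg]
    for (it in 1:20) {
      mu <- circ_mean_deg(ang[grp])
      med <- median(mag[grp])
      new_grp <- usable[ang_diff(ang[usable], mu) <= angle_tol_deg &
                          abs(mag[usable] - med) <= mag_tol_frac * med]
      if (length(new_grp) == length(grp) && all(new_grp == grp)) break
      if (length(new_grp) == 0) break
      grp <- new_grp
    }
    if (length(grp) > length(best)) best <- grp
  }
  frac <- length(best) / n
  if (frac < min_support_frac || length(best) < min_support_n ||
      frac > max_support_frac)
    return(drift_estimate(mode = "none"))
  drift_estimate(colMeans(vectors[best, , drop = FALSE]),
                 support = length(best), mode = "consensus", members = best)
}

#' Drift calibration from a dark pre-exposure segment
#'
#' Runs the full top-down pass over a dark segment (no directional
#' stimulus, hence no collective swimming direction) and averages all
#' region vectors without a consensus restriction. The result can be
#' stored and applied throughout an experiment in which strong
#' phototaxis defeats per-pair consensus estimation.
#'
#' @param dark_frames a [frame_sequence()] of at least 2 frames.
#' @param params a [topdown_params()].
#' @return a [drift_estimate()] with `mode = "dark_calibrated"`, or
#'   `mode = "none"` (zero vector) with a warning when no motion
#'   regions are detected.
#' @export
estimate_drift_dark <- function(dark_frames, params = topdown_params()) {
  stopifnot(inherits(dark_frames, "frame_sequence"))
  if (length(dark_frames) < 2)
    stop_domain("dark segment needs at least 2 frames")
  cal <- attr(dark_frames, "calibration")
  bounds <- resolve_area_bounds(params, cal)
  vecs <- list()
  for (i in seq_len(length(dark_frames) - 1)) {
    fld <- dense_flow(dark_frames[[i]], dark_frames[[i + 1]], params$flow,
                      frames = c(i, i + 1))
    fld <- threshold_flow(fld, params$min_magnitude_px)
    regs <- extract_motion_regions(fld, dark_frames[[i]], bounds,
                                   min_moving_frac = params$min_moving_frac)
    for (r in regs) vecs[[length(vecs) + 1]] <- r$mean_vector
  }
  if (length(vecs) == 0) {
    warning("no motion regions detected in dark segment; drift set to (0,0)")
    return(drift_estimate(mode = "none"))
  }
  m <- do.call(rbind, vecs)
  drift_estimate(colMeans(m), support = nrow(m), mode = "dark_calibrated")
}

#' Subtract an estimated drift from motion regions
#'
#' The drift vector is subtracted from every region's mean vector and
#' the derived angle and magnitude are recomputed. With `mode = "none"`
#' this is the identity; correcting by `d` then by `-d` restores the
#' original vectors exactly.
#'
#' @param regions list of `motion_region`s.
#' @param drift a [drift_estimate()].
#' @return the corrected list of regions.
#' @export
apply_drift_correction <- function(regions, drift) {
  stopifnot(inherits(drift, "drift_estimate"))
  if (drift$mode == "none") return(regions)
  lapply(regions, function(r)
    new_motion_region(r$pixels, r$area_px,
                      r$mean_vector[["dx"]] - drift$vector[["dx"]],
                      r$mean_vector[["dy"]] - drift$vector[["dy"]]))
}

resolve_area_bounds <- function(params, calibration) {
  if (!is.null(params$area_bounds_px)) return(params$area_bounds_px)
  r_px <- params$cell_radius_um / calibration$um_per_px
  area <- pi * r_px^2
  c(0.25 * area, 4 * area)
}

#' Top-down pipeline parameters
#'
#' @param flow a [flow_params()].
#' @param min_magnitude_px flow-noise threshold in px/frame.
#' @param cell_radius_um expected cell radius, used to derive default
#'   region area bounds of (0.25x, 4x) the expected cell area.
#' @param area_bounds_px explicit area bounds overriding the derived
#'   default.
#' @param angle_tol_deg,mag_tol_frac,min_support_frac,min_support_n,max_support_frac
#'   consensus drift parameters (see [estimate_drift_consensus()]).
#' @param min_moving_frac minimum moving-pixel fraction for a footprint
#'   to count as a motion region (see [extract_motion_regions()]).
#' @param include_drift_group include the drift-consensus regions
#'   (presumed non-motile) in the speed average after correction.
#' @return a list of class `topdown_params`.
#' @export
topdown_params <- function(flow = flow_params(), min_magnitude_px = 0.5,
                           cell_radius_um = 4, area_bounds_px = NULL,
                           angle_tol_deg = 7.5, mag_tol_frac = 0.2,
                           min_support_frac = 0.2, min_support_n = 5L,
                           max_support_frac = 0.9,
                           min_moving_frac = 0.2, include_drift_group = FALSE) {
  structure(list(flow = flow, min_magnitude_px = min_magnitude_px,
                 cell_radius_um = cell_radius_um,
                 area_bounds_px = area_bounds_px,
                 angle_tol_deg = angle_tol_deg, mag_tol_frac = mag_tol_frac,
                 min_support_frac = min_support_frac,
                 min_support_n = min_support_n,
                 max_support_frac = max_support_frac,
                 min_moving_frac = min_moving_frac,
                 include_drift_group = include_drift_group),
            class = "topdown_params")
}

#' Per-frame-pair mean swimming speed series
#'
#' For each consecutive frame pair: dense flow, magnitude thresholding,
#' motion-region extraction, drift correction, then the mean of the
#' corrected region speeds converted to um/s. Frame pairs are processed
#' independently. Pairs with no contributing region yield `NA`, not
#' zero.
#'
#' @param frames a [frame_sequence()] of at least 2 frames with a valid
#'   calibration.
#' @param params a [topdown_params()].
#' @param drift_policy `"consensus"` (estimated per pair),
#'   `"dark"` (a fixed, pre-calibrated estimate passed via `drift`) or
#'   `"none"`.
#' @param drift a [drift_estimate()] used when
#'   `drift_policy = "dark"`.
#' @return a `data.frame` with columns `frame_index`, `time_s`,
#'   `mean_speed_um_s`, `n_regions`, `drift_dx_px`, `drift_dy_px`.
#' @export
frame_pair_speeds <- function(frames, params = topdown_params(),
                              drift_policy = c("consensus", "dark", "none"),
                              drift = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  drift_policy <- match.arg(drift_policy)
  if (length(frames) < 2) stop_domain("need at least 2 frames")
  if (drift_policy == "dark" &&
      (is.null(drift) || !inherits(drift, "drift_estimate")))
    stop_domain("`drift` must be a drift_estimate when drift_policy = 'dark'")
  cal <- attr(frames, "calibration")
  bounds <- resolve_area_bounds(params, cal)
  n_pairs <- length(frames) - 1
  out <- data.frame(frame_index = seq_len(n_pairs),
                    time_s = (seq_len(n_pairs) - 1) / cal$frame_rate,
                    mean_speed_um_s = NA_real_, n_regions = 0L,
                    drift_dx_px = 0, drift_dy_px = 0)
  for (i in seq_len(n_pairs)) {
    fld <- dense_flow(frames[[i]], frames[[i + 1]], params$flow,
                      frames = c(i, i + 1))
    fld <- threshold_flow(fld, params$min_magnitude_px)
    regs <- extract_motion_regions(fld, frames[[i]], bounds,
                                   min_moving_frac = params$min_moving_frac)
    if (length(regs) == 0) next
    d <- switch(drift_policy,
                consensus = estimate_drift_consensus(
                  regs, params$angle_tol_deg, params$mag_tol_frac,
                  params$min_support_frac, params$min_support_n,
                  params$max_support_frac),
                dark = drift,
                none = drift_estimate(mode = "none"))
    corrected <- apply_drift_correction(regs, d)
    keep <- seq_along(corrected)
    if (d$mode == "consensus" && !params$include_drift_group)
      keep <- setdiff(keep, d$members)
    if (length(keep) == 0) next
    mags <- vapply(corrected[keep], function(r) r$mean_magnitude_px, 0)
    out$mean_speed_um_s[i] <- px_per_frame_to_um_per_s(mean(mags), cal)
    out$n_regions[i] <- length(keep)
    out$drift_dx_px[i] <- d$vector[["dx"]]
    out$drift_dy_px[i] <- d$vector[["dy"]]
  }
  out
}
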