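# Biological readouts: speed statistics, motile/non-motile
# classification, orientation distributions and photoshock response.

per_track_stats <- function(track_tbl, min_points = 2) {
  ids <- unique(track_tbl$track_id)
  rows <- lapply(ids, function(id) {
    p <- track_tbl[track_tbl$track_id == id, , drop = FALSE]
    if (nrow(p) < min_points) return(NULL)
    steps <- p$step_speed_um_s[!is.na(p$step_speed_um_s)]
    heads <- p$heading_deg[!is.na(p$heading_deg)]
    data.frame(track_id = id, n_points = nrow(p),
               mean_speed_um_s = mean(steps),
               mean_heading_deg = circ_mean_deg(heads))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(track_id = integer(), n_points = integer(),
                      mean_speed_um_s = numeric(),
                      mean_heading_deg = numeric()))
  do.call(rbind, rows)
}

# Motile fraction weighting: a fast swimmer crosses the field of view
# (or a wrap boundary of the synthetic scene) more often than a slow
# sedimenter, so it fragments into more tracks; a per-track count is
# then biased toward the motile class. Weighting each track by its
# observed duration (point count) makes every cell contribute its time
# on screen once, recovering the per-cell fraction.
new_motility_report <- function(per_track, mode, absolute, parameters,
                                weight = c("duration", "count")) {
  weight <- match.arg(weight)
  frac <- if (nrow(per_track) == 0) NA_real_
  else if (weight == "count") mean(per_track$label == "motile")
  else sum(per_track$n_points[per_track$label == "motile"]) /
    sum(per_track$n_points)
  parameters$weight <- weight
  structure(list(per_track = per_track, motile_fraction = frac,
                 classification_mode = mode, absolute = absolute,
                 parameters = parameters),
            class = "motility_report")
}

#' @export
print.motility_report <- function(x, ...) {
  cat(sprintf(
    "<motility_report> %s: %d tracks, motile fraction %.3f (%s)\n",
    x$classification_mode, nrow(x$per_track), x$motile_fraction,
    if (x$absolute) "absolute" else "comparative"))
  invisible(x)
}

#' Speed-based motile/non-motile classification
#'
#' Suited to the vertical (droplet) observation mode, where
#' non-swimmers are adhered to the chamber wall and show near-zero
#' speed: a track is motile iff its mean step speed exceeds the
#' threshold. The resulting fraction is comparative (adhered cells on
#' the wall are only part of the non-motile pool), not an absolute
#' motility percentage.
#'
#' @param track_tbl a [track_table()].
#' @param speed_threshold_um_s speed threshold in um/s.
#' @param min_points minimum points for a track to be labelled.
#' @param weight `"duration"` weights each track by its observed point
#'   count when computing the fraction (correcting the fragmentation
#'   bias of fast tracks splitting at field-of-view crossings);
#'   `"count"` counts each track once.
#' @return a `motility_report` with per-track labels and the motile
#'   fraction.
#' @export
classify_by_speed <- function(track_tbl, speed_threshold_um_s = 5,
                              min_points = 2,
                              weight = c("duration", "count")) {
  pt <- per_track_stats(track_tbl, min_points)
  if (nrow(pt) == 0) warning("no tracks to classify")
  pt$label <- ifelse(pt$mean_speed_um_s > speed_threshold_um_s,
                     "motile", "non_motile")
  new_motility_report(pt, "speed_based", absolute = FALSE,
                      list(speed_threshold_um_s = speed_threshold_um_s,
                           min_points = min_points), weight = weight)
}

# histogram-free mode estimate: peak of a Gaussian kernel density
mode_estimate <- function(x) {
  if (length(x) == 1) return(x)
  d <- density(x)
  d$x[which.max(d$y)]
}

#' Trajectory-angle motile/non-motile classification
#'
#' Suited to the horizontal (cuvette) observation mode, where
#' non-motile cells sediment through the field of view at a uniform
#' speed in a single downward direction while swimmers show a broad
#' diversity of headings. The modal sedimentation speed is estimated
#' from tracks heading within `down_tol_deg` of straight down; a track
#' is non-motile iff its mean heading is within `down_tol_deg` of down
#' and its mean speed lies within `sed_speed_tol_frac` of that modal
#' speed. The resulting motile fraction is absolute.
#'
#' @param track_tbl a [track_table()].
#' @param down_tol_deg angular tolerance around straight down (180
#'   deg).
#' @param sed_speed_tol_frac relative speed tolerance around the modal
#'   sedimentation speed.
#' @param min_points minimum points for a track to be labelled.
#' @param weight fraction weighting, see [classify_by_speed()].
#' @return a `motility_report`; if no downward tracks exist the
#'   sedimentation speed is undefined and classification falls back to
#'   the angle criterion alone, with a warning.
#' @export
classify_by_trajectory_angle <- function(track_tbl, down_tol_deg = 15,
                                         sed_speed_tol_frac = 0.25,
                                         min_points = 2,
                                         weight = c("duration", "count")) {
  pt <- per_track_stats(track_tbl, min_points)
  if (nrow(pt) == 0) {
    warning("no tracks to classify")
    pt$label <- character()
    return(new_motility_report(pt, "trajectory_based", TRUE,
                               list(down_tol_deg = down_tol_deg,
                                    sed_speed_tol_frac = sed_speed_tol_frac),
                               weight = weight))
  }
  down <- ang_diff(pt$mean_heading_deg, 180) <= down_tol_deg
  sed_speed <- NA_real_
  if (!any(down)) {
    warning("no downward tracks; sedimentation speed undefined, ",
            "falling back to angle-only classification")
    nonmotile <- down
  } else {
    # centre of the sedimentation-speed band: start at the density mode
    # of downward-track speeds, then refine as the duration-weighted
    # mean of the tracks currently inside the band. The mode alone is
    # noisy at a few dozen tracks and a centre off by a few percent
    # clips the tail of the sedimenter speed distribution.
    sed_speed <- mode_estimate(pt$mean_speed_um_s[down])
    for (it in 1:3) {
      inband <- down &
        abs(pt$mean_speed_um_s - sed_speed) <= sed_speed_tol_frac * sed_speed
      if (!any(inband)) break
      sed_speed <- sum(pt$mean_speed_um_s[inband] * pt$n_points[inband]) /
        sum(pt$n_points[inband])
    }
    nonmotile <- down &
      abs(pt$mean_speed_um_s - sed_speed) <= sed_speed_tol_frac * sed_speed
  }
  pt$label <- ifelse(nonmotile, "non_motile", "motile")
  new_motility_report(pt, "trajectory_based", absolute = TRUE,
                      list(down_tol_deg = down_tol_deg,
                           sed_speed_tol_frac = sed_speed_tol_frac,
                           sediment_speed_um_s = sed_speed),
                      weight = weight)
}

#' Polar orientation histogram with circular statistics
#'
#' Bins headings (typically per-track mean headings of the motile
#' population; filter non-motile entries first) into uniform sectors
#' over `[0, 360)` and reports the circular mean and the resultant
#' length `R` of the mean unit vector (1 = perfectly aligned, 0 =
#' isotropic).
#'
#' @param x numeric headings in degrees, or a [track_table()] (one
#'   heading per track: the circular mean of its step headings).
#' @param n_bins number of sectors (>= 4).
#' @return an object of class `orientation_histogram` with fields
#'   `bin_edges_deg`, `counts`, `relative_frequency`, `n_total`,
#'   `circular_mean_deg`, `resultant_length`.
#' @export
orientation_histogram <- function(x, n_bins = 16) {
  if (n_bins < 4) stop_domain("`n_bins` must be >= 4")
  if (is.data.frame(x)) x <- per_track_stats(x)$mean_heading_deg
  x <- x[!is.na(x)] %% 360
  edges <- seq(0, 360, length.out = n_bins + 1)
  counts <- if (length(x) == 0) integer(n_bins)
            else tabulate(findInterval(x, edges, rightmost.closed = FALSE,
                                       left.open = FALSE), nbins = n_bins)
  structure(list(
    bin_edges_deg = edges, counts = counts,
    relative_frequency = if (length(x) > 0) counts / length(x)
                         else rep(NA_real_, n_bins),
    n_total = length(x),
    circular_mean_deg = circ_mean_deg(x),
    resultant_length = circ_resultant(x)),
    class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf(
    "<orientation_histogram> n = %d in %d bins; circular mean %.1f deg, R = %.3f\n",
    x$n_total, length(x$counts), x$circular_mean_deg, x$resultant_length))
  invisible(x)
}

#' Polar plot of an orientation histogram
#'
#' Bar length is the relative frequency of swimming directions; 0 deg
#' (the light-source side) points up and angles grow clockwise.
#'
#' @param x an `orientation_histogram`.
#' @param ... ignored.
#' @export
plot.orientation_histogram <- function(x, ...) {
  graphics::plot.new()
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  rel <- x$relative_frequency
  rmax <- max(rel, na.rm = TRUE)
  if (!is.finite(rmax) || rmax == 0) rmax <- 1
  nb <- length(x$counts)
  for (i in seq_len(nb)) {
    a0 <- x$bin_edges_deg[i] * pi / 180
    a1 <- x$bin_edges_deg[i + 1] * pi / 180
    r <- rel[i] / rmax
    if (is.na(r) || r == 0) next
    aa <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, r * sin(aa)), c(0, r * cos(aa)),
                      col = "steelblue", border = "white")
  }
  aa <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(sin(aa), cos(aa), col = "grey50")
  graphics::text(0, 1.08, "0°"); graphics::text(1.08, 0, "90°")
  graphics::text(0, -1.08, "180°"); graphics::text(-1.08, 0, "270°")
  invisible(x)
}

#' Photoshock response detection from a speed time series
#'
#' A photoshock is a transient interruption of swimming triggered by a
#' sudden light increase. For each pulse: the baseline is the mean
#' speed over `pre_window_s` before onset; the population responded iff
#' the speed falls below `drop_frac * baseline` within
#' `react_window_s` after onset; the response duration runs from onset
#' until the speed first recovers to `recover_frac * baseline`
#' sustained for `hold_frames` consecutive samples. All thresholds are
#' relative, so the result is invariant to rescaling the series.
#'
#' @param speed_series `data.frame` with `time_s` and
#'   `mean_speed_um_s` (e.g. from [frame_pair_speeds()]).
#' @param stimulus a [stimulus_schedule()], or a numeric vector of
#'   pulse onset times in seconds.
#' @param pre_window_s,drop_frac,recover_frac,hold_frames,react_window_s
#'   analysis-window parameters.
#' @return `data.frame` with one row per pulse: `pulse_onset_s`,
#'   `baseline_speed_um_s`, `min_speed_um_s`, `responded`,
#'   `response_duration_s`.
#' @export
photoshock_response <- function(speed_series, stimulus, pre_window_s = 5,
                                drop_frac = 0.5, recover_frac = 0.7,
                                hold_frames = 5, react_window_s = 1) {
  onsets <- if (inherits(stimulus, "stimulus_schedule"))
    pulse_onsets(stimulus) else sort(as.numeric(stimulus))
  if (length(onsets) == 0) stop_domain("no pulses in stimulus")
  if (length(onsets) > 1 &&
      any(diff(onsets) < pre_window_s + react_window_s))
    stop_domain("pulses too close: analysis windows overlap")
  t <- speed_series$time_s
  v <- speed_series$mean_speed_um_s
  out <- lapply(seq_along(onsets), function(k) {
    on <- onsets[k]
    upper <- if (k < length(onsets)) onsets[k + 1] else max(t) + 1
    pre <- v[t >= on - pre_window_s & t < on]
    baseline <- mean(pre, na.rm = TRUE)
    react <- v[t > on & t <= on + react_window_s]
    responded <- any(react < drop_frac * baseline, na.rm = TRUE)
    post_idx <- which(t >= on & t < upper)
    min_speed <- suppressWarnings(min(v[post_idx], na.rm = TRUE))
    duration <- 0
    if (responded) {
      ok <- v[post_idx] >= recover_frac * baseline
      ok[is.na(ok)] <- FALSE
      run <- 0; rec <- NA_integer_
      for (i in seq_along(ok)) {
        run <- if (ok[i]) run + 1 else 0
        if (run >= hold_frames) { rec <- i - hold_frames + 1; break }
      }
      duration <- if (is.na(rec)) upper - on
                  else max(0, t[post_idx[rec]] - on)
    }
    data.frame(pulse_onset_s = on, baseline_speed_um_s = baseline,
               min_speed_um_s = min_speed, responded = responded,
               response_duration_s = duration)
  })
  do.call(rbind, out)
}

#' Mean and standard deviation over replicate recordings
#'
#' Summarizes replicate means (one value per recording) as an
#' arithmetic mean and a sample standard deviation; with a single
#' replicate the sd is undefined and reported as `NA`.
#'
#' @param x numeric vector of replicate mean speeds (um/s), or a list
#'   of speed-series data frames whose `mean_speed_um_s` columns are
#'   averaged per replicate first.
#' @return named numeric vector `c(mean, sd)`.
#' @export
speed_summary <- function(x) {
  if (is.list(x) && !is.numeric(x))
    x <- vapply(x, function(s) mean(s$mean_speed_um_s, na.rm = TRUE), 0)
  if (length(x) == 0) stop_domain("need at least one replicate")
  c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
}
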