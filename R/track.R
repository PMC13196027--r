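# Bottom-up, single-cell segmentation and identity-preserving tracking.
#
# Order of operations mirrors the analysis this package implements:
# adaptive threshold -> contour closing and labelling -> subpixel
# intensity-weighted centroids -> pooled percentile area filter ->
# frame-by-frame linking with constant-velocity prediction and global
# minimal-cost assignment under a gating radius.

#' Segmentation parameters
#'
#' @param block_size odd side (px) of the local-mean adaptive threshold
#'   window; should exceed the cell diameter.
#' @param offset brightness offset above the local mean for foreground.
#' @param polarity `"bright"` for bright cells on dark background,
#'   `"dark"` for the inverse (the frame is inverted before
#'   thresholding, so the mask is identical under polarity flip).
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(block_size = 31, offset = 0.08,
                       polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (block_size < 3 || block_size %% 2 == 0)
    stop_domain("`block_size` must be an odd integer >= 3")
  structure(list(block_size = as.integer(block_size), offset = offset,
                 polarity = polarity),
            class = "seg_params")
}

#' Adaptive-threshold segmentation of one frame
#'
#' Local-mean adaptive thresholding: a pixel is foreground when it
#' exceeds the mean of its `block_size` neighbourhood by `offset`.
#'
#' @param frame grayscale matrix in `[0, 1]`.
#' @param params a [seg_params()].
#' @return a logical foreground mask.
#' @export
segment_frame <- function(frame, params = seg_params()) {
  if (!is.matrix(frame)) stop_domain("`frame` must be a matrix")
  x <- if (params$polarity == "dark") 1 - frame else frame
  hw <- (params$block_size - 1) / 2
  EBImage::thresh(x, w = hw, h = hw, offset = params$offset) > 0
}

#' Detect cells in a segmented frame
#'
#' Closes and hole-fills the mask contours, labels connected
#' components, and reports per-component area and intensity-weighted
#' subpixel centroid (pixel centres at half-integer coordinates,
#' origin at the top-left frame corner).
#'
#' @param mask logical mask from [segment_frame()].
#' @param frame the original grayscale frame (centroid weights).
#' @param frame_index frame number recorded with each detection.
#' @return a `data.frame` with columns `frame_index`, `x_px`, `y_px`,
#'   `area_px` (possibly zero rows).
#' @export
detect_cells <- function(mask, frame, frame_index = NA_integer_) {
  stopifnot(is.matrix(mask), all(dim(mask) == dim(frame)))
  empty <- data.frame(frame_index = integer(), x_px = numeric(),
                      y_px = numeric(), area_px = numeric())
  if (!any(mask)) return(empty)
  closed <- close_diamond(mask)
  filled <- EBImage::fillHull(closed) > 0
  lab <- EBImage::bwlabel(filled)
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  idx <- which(lab > 0)
  comp <- lab[idx]
  rr <- ((idx - 1) %% nrow(mask)) + 1
  cc <- ((idx - 1) %/% nrow(mask)) + 1
  w <- frame[idx]
  wsum <- tapply(w, comp, sum)
  xs <- tapply(w * (cc - 0.5), comp, sum) / wsum
  ys <- tapply(w * (rr - 0.5), comp, sum) / wsum
  areas <- tabulate(comp, nbins = nlab)
  data.frame(frame_index = frame_index, x_px = as.numeric(xs),
             y_px = as.numeric(ys), area_px = as.numeric(areas))
}

#' Pooled percentile area filter
#'
#' Pools all detection areas over the whole video, computes the
#' `low_frac` and `1 - high_frac` empirical quantiles (linear
#' interpolation between order statistics) and retains detections with
#' `q_low < area <= q_high`, excluding debris and aggregates. With
#' fewer than 10 detections the filter is disabled with a warning.
#'
#' @param detections a `data.frame` of detections (see
#'   [detect_cells()]).
#' @param low_frac,high_frac fractions excluded at each end;
#'   `low_frac + high_frac < 1`.
#' @return the filtered `data.frame`.
#' @export
filter_by_area_percentile <- function(detections, low_frac = 0.10,
                                      high_frac = 0.10) {
  if (low_frac < 0 || high_frac < 0 || low_frac + high_frac >= 1)
    stop_domain("need 0 <= low_frac + high_frac < 1")
  if (low_frac == 0 && high_frac == 0) return(detections)
  n <- nrow(detections)
  if (n < 10) {
    warning("fewer than 10 detections; area-percentile filter disabled")
    return(detections)
  }
  q <- quantile(detections$area_px, c(low_frac, 1 - high_frac),
                type = 7, names = FALSE)
  keep <- detections$area_px > q[1] & detections$area_px <= q[2]
  # degenerate area distribution: both quantiles coincide and the open
  # lower bound would empty the set; keep the modal area instead
  if (!any(keep) && q[1] == q[2]) keep <- detections$area_px == q[1]
  detections[keep, , drop = FALSE]
}

#' Linking parameters
#'
#' @param gate_px gating radius in pixels; a sensible default is 3x the
#'   expected per-frame displacement.
#' @param init_hits consecutive matches required before a tentative
#'   track is confirmed (and reported).
#' @param max_skip missed frames tolerated before a track is dropped
#'   (bridging brief occlusions).
#' @return a list of class `link_params`.
#' @export
link_params <- function(gate_px, init_hits = 2, max_skip = 3) {
  check_positive(gate_px = gate_px, init_hits = init_hits)
  if (max_skip < 0) stop_domain("`max_skip` must be >= 0")
  structure(list(gate_px = gate_px, init_hits = as.integer(init_hits),
                 max_skip = as.integer(max_skip)),
            class = "link_params")
}

# Gated one-to-one assignment minimizing total Euclidean cost.
# Returns an integer vector: for each row (track), the matched column
# (detection) or NA. Standard augmented-matrix construction: each row
# and column owns a "skip" slot priced at the gate radius, so a pair is
# matched iff its cost beats leaving both unmatched.
gated_assignment <- function(cost, gate) {
  nt <- nrow(cost); nd <- ncol(cost)
  if (nt == 0 || nd == 0) return(rep(NA_integer_, nt))
  big <- 1e8
  s <- nt + nd
  m <- matrix(0, s, s)
  m[seq_len(nt), seq_len(nd)] <- ifelse(cost <= gate, cost, big)
  m[seq_len(nt), nd + seq_len(nt)] <- big
  m[cbind(seq_len(nt), nd + seq_len(nt))] <- gate
  m[nt + seq_len(nd), seq_len(nd)] <- big
  m[cbind(nt + seq_len(nd), seq_len(nd))] <- gate
  sol <- hungarian_cpp(m)
  out <- rep(NA_integer_, nt)
  for (i in seq_len(nt)) {
    j <- sol[i]
    if (j <= nd && cost[i, j] <= gate) out[i] <- j
  }
  out
}

#' Link detections into identity-preserving tracks
#'
#' Each live track predicts its next position under a constant-velocity
#' model; predictions and detections are matched frame by frame with a
#' globally optimal one-to-one assignment under the gating radius.
#' Unmatched detections seed tentative tracks (reported once they
#' collect `init_hits` points); tracks are dropped after `max_skip`
#' consecutive missed frames. Detections within a frame are processed
#' in a canonical (x, then y) order, so the result does not depend on
#' their input order.
#'
#' @param detections `data.frame` with `frame_index`, `x_px`, `y_px`
#'   and optionally `area_px`.
#' @param params a [link_params()].
#' @return a list of confirmed tracks (class `track_set`); each track
#'   is a list with `track_id` and a `points` data.frame ordered by
#'   frame.
#' @export
link_detections <- function(detections, params) {
  stopifnot(inherits(params, "link_params"))
  if (is.null(detections$area_px)) detections$area_px <- NA_real_
  done <- list()
  active <- list()
  next_id <- 1L
  if (nrow(detections) > 0) {
    frames_seq <- seq(min(detections$frame_index),
                      max(detections$frame_index))
    for (f in frames_seq) {
      dets <- detections[detections$frame_index == f, , drop = FALSE]
      dets <- dets[order(dets$x_px, dets$y_px), , drop = FALSE]
      nd <- nrow(dets); nt <- length(active)
      assigned <- rep(NA_integer_, nt)
      if (nt > 0 && nd > 0) {
        pred <- t(vapply(active, function(tr) {
          gap <- f - tr$last_frame
          c(tr$x + tr$vx * gap, tr$y + tr$vy * gap)
        }, numeric(2)))
        cost <- sqrt(outer(pred[, 1], dets$x_px, `-`)^2 +
                       outer(pred[, 2], dets$y_px, `-`)^2)
        assigned <- gated_assignment(cost, params$gate_px)
      }
      survivors <- list()
      for (i in seq_len(nt)) {
        tr <- active[[i]]
        j <- assigned[i]
        if (!is.na(j)) {
          gap <- f - tr$last_frame
          tr$vx <- (dets$x_px[j] - tr$x) / gap
          tr$vy <- (dets$y_px[j] - tr$y) / gap
          tr$x <- dets$x_px[j]; tr$y <- dets$y_px[j]
          tr$last_frame <- f; tr$missed <- 0L
          tr$points[[length(tr$points) + 1]] <-
            c(f, dets$x_px[j], dets$y_px[j], dets$area_px[j])
          survivors[[length(survivors) + 1]] <- tr
        } else {
          tr$missed <- tr$missed + 1L
          if (tr$missed > params$max_skip) {
            if (length(tr$points) >= params$init_hits)
              done[[length(done) + 1]] <- tr
          } else survivors[[length(survivors) + 1]] <- tr
        }
      }
      taken <- assigned[!is.na(assigned)]
      for (j in setdiff(seq_len(nd), taken)) {
        survivors[[length(survivors) + 1]] <- list(
          track_id = next_id, x = dets$x_px[j], y = dets$y_px[j],
          vx = 0, vy = 0, last_frame = f, missed = 0L,
          points = list(c(f, dets$x_px[j], dets$y_px[j], dets$area_px[j])))
        next_id <- next_id + 1L
      }
      active <- survivors
    }
  }
  for (tr in active)
    if (length(tr$points) >= params$init_hits)
      done[[length(done) + 1]] <- tr
  done <- done[order(vapply(done, function(tr) tr$track_id, 0L))]
  out <- lapply(done, function(tr) {
    m <- do.call(rbind, tr$points)
    list(track_id = tr$track_id,
         points = data.frame(frame = as.integer(m[, 1]), x_px = m[, 2],
                             y_px = m[, 3], area_px = m[, 4]))
  })
  structure(out, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d points\n", length(x),
              sum(vapply(x, function(tr) nrow(tr$points), 0L))))
  invisible(x)
}

#' Long-format trajectory table
#'
#' One row per track point with physical units and per-step kinematics.
#' Step speed and heading at a point describe the step arriving from
#' the previous point of the same track (`NA` on the first point);
#' gaps bridged by the tracker divide displacement by the frame gap.
#'
#' @param tracks a `track_set` from [link_detections()].
#' @param calibration a [calibration_state()].
#' @return `data.frame` with columns `track_id`, `frame`, `t_s`,
#'   `x_px`, `y_px`, `x_um`, `y_um`, `step_speed_um_s`, `heading_deg`.
#' @export
track_table <- function(tracks, calibration) {
  stopifnot(inherits(calibration, "calibration_state"))
  rows <- lapply(tracks, function(tr) {
    p <- tr$points
    n <- nrow(p)
    speed <- rep(NA_real_, n); head <- rep(NA_real_, n)
    if (n >= 2) {
      gap <- diff(p$frame)
      dx <- diff(p$x_px); dy <- diff(p$y_px)
      disp_px <- sqrt(dx^2 + dy^2) / gap
      speed[-1] <- disp_px * calibration$um_per_px * calibration$frame_rate
      head[-1] <- heading_deg(dx, dy)
    }
    data.frame(track_id = tr$track_id, frame = p$frame,
               t_s = (p$frame - 1) / calibration$frame_rate,
               x_px = p$x_px, y_px = p$y_px,
               x_um = p$x_px * calibration$um_per_px,
               y_um = p$y_px * calibration$um_per_px,
               step_speed_um_s = speed, heading_deg = head)
  })
  if (length(rows) == 0)
    return(data.frame(track_id = integer(), frame = integer(),
                      t_s = numeric(), x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      step_speed_um_s = numeric(), heading_deg = numeric()))
  do.call(rbind, rows)
}

#' Write and read tracks as JSON-lines
#'
#' One track per line, with point arrays; round-trips losslessly with
#' [read_tracks_jsonl()].
#'
#' @param tracks a `track_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_jsonl <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    writeLines(jsonlite::toJSON(
      list(track_id = tr$track_id, frame = tr$points$frame,
           x_px = tr$points$x_px, y_px = tr$points$y_px,
           area_px = tr$points$area_px),
      auto_unbox = FALSE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_tracks_jsonl
#' @export
read_tracks_jsonl <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    list(track_id = as.integer(x$track_id),
         points = data.frame(frame = as.integer(x$frame), x_px = x$x_px,
                             y_px = x$y_px, area_px = x$area_px))
  })
  structure(out, class = "track_set")
}
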