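# Shared builders for synthetic test scenes and hand-made track tables.

test_cal <- function(width = 256, height = 256, um_per_px = 0.86,
                     fps = 30) {
  calibration_state(um_per_px, fps, width, height)
}

swimmer_pop <- function(count, speed = 100, mode = "isotropic",
                        heading = 0, turn_sd = 3, radius = 4) {
  particle_population("swimmer", count = count, speed_um_s = speed,
                      heading_mode = mode, heading_deg = heading,
                      turn_sd_deg = turn_sd, radius_um = radius,
                      intensity = 0.8)
}

# a rendered scene plus its ground truth
test_scene <- function(pops, n_frames, cal = test_cal(), seed = 1,
                       drift = c(0, 0), noise_sd = 0.02,
                       speed_scale = NULL) {
  cfg <- scene_config(pops, cal, n_frames, drift_um_per_frame = drift,
                      noise_sd = noise_sd, seed = seed,
                      speed_scale = speed_scale)
  truth <- simulate_tracks(cfg)
  list(config = cfg, truth = truth,
       frames = render_frames(truth, cfg))
}

# default region area bounds for a given cell radius and calibration
test_area_bounds <- function(radius_um = 4, cal = test_cal()) {
  a <- pi * (radius_um / cal$um_per_px)^2
  c(0.25 * a, 4 * a)
}

# run the bottom-up pipeline on a frame sequence
run_bottomup <- function(frames, gate_px, filter = TRUE) {
  dets <- do.call(rbind, lapply(seq_along(frames), function(i)
    detect_cells(segment_frame(frames[[i]]), frames[[i]], i)))
  if (filter) dets <- filter_by_area_percentile(dets)
  tracks <- link_detections(dets, link_params(gate_px = gate_px))
  track_table(tracks, attr(frames, "calibration"))
}

# hand-made track table: one track from px coordinates
manual_track_tbl <- function(track_id, x_px, y_px, cal = test_cal()) {
  tr <- structure(list(list(
    track_id = track_id,
    points = data.frame(frame = seq_along(x_px), x_px = x_px, y_px = y_px,
                        area_px = 50))), class = "track_set")
  track_table(tr, cal)
}

# track table with one straight constant-speed track per row of `spec`
# (columns: speed_um_s, heading_deg, n optional)
manual_population_tbl <- function(spec, cal = test_cal()) {
  tbls <- lapply(seq_len(nrow(spec)), function(i) {
    n <- if ("n" %in% names(spec)) spec$n[i] else 10
    step_px <- spec$speed_um_s[i] / (cal$um_per_px * cal$frame_rate)
    v <- heading_vector(spec$heading_deg[i])
    manual_track_tbl(i, 100 + step_px * v$dx * (0:(n - 1)),
                     100 + step_px * v$dy * (0:(n - 1)), cal)
  })
  do.call(rbind, tbls)
}

# exhaustive minimal-cost one-to-one matching (reference oracle);
# returns per-row matched column or NA, allowing unmatched at `gate`
brute_force_assignment <- function(cost, gate) {
  nt <- nrow(cost); nd <- ncol(cost)
  best <- NULL; best_cost <- Inf
  options <- c(NA_integer_, seq_len(nd))
  rec <- function(i, used, acc, assign) {
    if (acc >= best_cost) return()
    if (i > nt) {
      # unmatched rows and columns each pay the gate
      total <- acc + gate * sum(is.na(assign)) +
        gate * (nd - sum(!is.na(assign)))
      if (total < best_cost) { best_cost <<- total; best <<- assign }
      return()
    }
    for (j in options) {
      if (!is.na(j) && (j %in% used || cost[i, j] > gate)) next
      rec(i + 1, c(used, j), acc + if (is.na(j)) 0 else cost[i, j],
          c(assign, j))
    }
  }
  rec(1L, integer(), 0, integer())
  # recompute with gate charges folded in (rec above already charges
  # unmatched pairs at return time)
  best
}

# independent reference tracker: same documented rules as
# link_detections (constant-velocity prediction, gated minimal-cost
# matching, init_hits confirmation, max_skip termination) but built on
# the exhaustive brute-force matcher; usable for <= 5 live tracks
ref_link <- function(detections, params) {
  active <- list(); done <- list(); next_id <- 1L
  for (f in seq(min(detections$frame_index), max(detections$frame_index))) {
    dets <- detections[detections$frame_index == f, , drop = FALSE]
    dets <- dets[order(dets$x_px, dets$y_px), , drop = FALSE]
    nt <- length(active); nd <- nrow(dets)
    assigned <- rep(NA_integer_, nt)
    if (nt > 0 && nd > 0) {
      pred <- t(vapply(active, function(tr) {
        gap <- f - tr$last_frame
        c(tr$x + tr$vx * gap, tr$y + tr$vy * gap)
      }, numeric(2)))
      cost <- sqrt(outer(pred[, 1], dets$x_px, `-`)^2 +
                     outer(pred[, 2], dets$y_px, `-`)^2)
      assigned <- brute_force_assignment(cost, params$gate_px)
    }
    keep <- list()
    for (i in seq_len(nt)) {
      tr <- active[[i]]; j <- assigned[i]
      if (!is.na(j)) {
        gap <- f - tr$last_frame
        tr$vx <- (dets$x_px[j] - tr$x) / gap
        tr$vy <- (dets$y_px[j] - tr$y) / gap
        tr$x <- dets$x_px[j]; tr$y <- dets$y_px[j]
        tr$last_frame <- f; tr$missed <- 0L
        tr$pts <- rbind(tr$pts, c(f, dets$x_px[j], dets$y_px[j]))
        keep[[length(keep) + 1]] <- tr
      } else {
        tr$missed <- tr$missed + 1L
        if (tr$missed > params$max_skip) {
          if (nrow(tr$pts) >= params$init_hits)
            done[[length(done) + 1]] <- tr
        } else keep[[length(keep) + 1]] <- tr
      }
    }
    for (j in setdiff(seq_len(nd), assigned[!is.na(assigned)])) {
      keep[[length(keep) + 1]] <- list(
        track_id = next_id, x = dets$x_px[j], y = dets$y_px[j], vx = 0,
        vy = 0, last_frame = f, missed = 0L,
        pts = matrix(c(f, dets$x_px[j], dets$y_px[j]), 1))
      next_id <- next_id + 1L
    }
    active <- keep
  }
  for (tr in active)
    if (nrow(tr$pts) >= params$init_hits) done[[length(done) + 1]] <- tr
  done <- done[order(vapply(done, function(tr) tr$track_id, 0L))]
  lapply(done, function(tr) {
    data.frame(frame = tr$pts[, 1], x_px = tr$pts[, 2], y_px = tr$pts[, 3])
  })
}

# well-separated random-walk tracking instance: k particles on a coarse
# grid with per-frame jitter far below half the grid spacing
tracking_instance <- function(seed, n_frames = 15, spacing = 60) {
  set.seed(seed)
  k <- sample(1:5, 1)
  slots <- expand.grid(x = spacing * (1:4), y = spacing * (1:4))
  slots <- slots[sample(nrow(slots), k), ]
  steps_x <- matrix(rnorm(k * n_frames, 0, 2), k)
  steps_y <- matrix(rnorm(k * n_frames, 0, 2), k)
  rows <- lapply(seq_len(k), function(i) {
    data.frame(frame_index = 1:n_frames, particle = i,
               x_px = slots$x[i] + cumsum(steps_x[i, ]),
               y_px = slots$y[i] + cumsum(steps_y[i, ]), area_px = 40)
  })
  do.call(rbind, rows)
}
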