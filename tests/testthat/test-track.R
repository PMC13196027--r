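test_that("adaptive segmentation isolates rendered cells", {
  # uniform frame: empty mask
  expect_false(any(segment_frame(matrix(0.3, 64, 64))))
  # rendered disk: mask overlaps the true disk with IoU > 0.6
  cal <- test_cal(128, 128)
  adh <- particle_population("adherent", count = 1, radius_um = 5,
                             intensity = 0.8)
  sc <- test_scene(list(adh), 2, cal = cal, seed = 31, noise_sd = 0.01)
  mask <- segment_frame(sc$frames[[1]])
  tt <- sc$truth[sc$truth$frame == 1, ]
  xs <- outer(rep(1, 128), seq_len(128) - 0.5)
  ys <- outer(seq_len(128) - 0.5, rep(1, 128))
  disk <- (xs - tt$x_um / 0.86)^2 + (ys - tt$y_um / 0.86)^2 <=
    (5 / 0.86)^2
  iou <- sum(mask & disk) / sum(mask | disk)
  expect_gt(iou, 0.6)
  # polarity flag makes dark-on-bright equivalent to bright-on-dark
  inv <- segment_frame(1 - sc$frames[[1]],
                       seg_params(polarity = "dark"))
  expect_identical(mask, inv)
})

test_that("detection counts cells and locates centroids to sub-pixel", {
  expect_equal(nrow(detect_cells(matrix(FALSE, 32, 32),
                                 matrix(0.1, 32, 32))), 0)
  sc <- test_scene(list(swimmer_pop(5, turn_sd = 0)), 2, seed = 32,
                   noise_sd = 0.01)
  mask <- segment_frame(sc$frames[[1]])
  dets <- detect_cells(mask, sc$frames[[1]], frame_index = 1)
  expect_equal(nrow(dets), 5)
  tt <- sc$truth[sc$truth$frame == 1, ]
  for (k in seq_len(5)) {
    d <- sqrt((dets$x_px - tt$x_um[k] / 0.86)^2 +
                (dets$y_px - tt$y_um[k] / 0.86)^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("area-percentile filter matches the order-statistics oracle", {
  det <- data.frame(frame_index = 1, x_px = 1, y_px = 1, area_px = 1:10)
  kept <- filter_by_area_percentile(det, 0.10, 0.10)
  expect_equal(kept$area_px, 2:9)
  # identity and degenerate cases
  expect_identical(filter_by_area_percentile(det, 0, 0), det)
  same <- transform(det, area_px = 7)
  expect_equal(nrow(filter_by_area_percentile(same)), 10)
  expect_warning(filter_by_area_percentile(det[1:5, ]), "disabled")
  # random instances against a brute-force quantile rule
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(12:60, 1)
    areas <- round(runif(n, 1, 300))
    lo <- runif(1, 0, 0.3); hi <- runif(1, 0, 0.3)
    d <- data.frame(frame_index = 1, x_px = 0, y_px = 0, area_px = areas)
    kept <- filter_by_area_percentile(d, lo, hi)
    q <- quantile(areas, c(lo, 1 - hi), type = 7, names = FALSE)
    ref <- areas[areas > q[1] & areas <= q[2]]
    if (length(ref) == 0 && q[1] == q[2]) ref <- areas[areas == q[1]]
    expect_identical(kept$area_px, ref)
    expect_lte(nrow(kept), (1 - lo - hi) * n + 2)
  }
})

test_that("linking follows identity, occlusion and confirmation rules", {
  # one detection per frame: a single track holding every point
  d <- data.frame(frame_index = 1:6, x_px = seq(10, 35, 5), y_px = 8,
                  area_px = 40)
  tr <- link_detections(d, link_params(gate_px = 10))
  expect_equal(length(tr), 1)
  expect_equal(nrow(tr[[1]]$points), 6)
  # a gap longer than max_skip splits the identity
  d2 <- d[-(3:6), ]
  d2b <- transform(d[5:6, ], frame_index = frame_index + 3)  # frames 8, 9
  tr2 <- link_detections(rbind(d2, d2b), link_params(gate_px = 10,
                                                     max_skip = 3))
  expect_equal(length(tr2), 2)
  expect_false(tr2[[1]]$track_id == tr2[[2]]$track_id)
  # two well-separated particles: two tracks, no identity swap
  pa <- data.frame(frame_index = rep(1:8, 2),
                   x_px = c(10 + (1:8), 100 - (1:8)),
                   y_px = rep(c(20, 90), each = 8), area_px = 40)
  tr3 <- link_detections(pa, link_params(gate_px = 6))
  expect_equal(length(tr3), 2)
  ys <- vapply(tr3, function(t) unique(t$points$y_px), 0)
  expect_setequal(ys, c(20, 90))
  for (t in tr3) expect_equal(length(unique(t$points$y_px)), 1)
})

test_that("gated assignment equals exhaustive minimal-cost matching", {
  set.seed(34)
  for (rep in 1:40) {
    nt <- sample(1:5, 1); nd <- sample(1:5, 1)
    cost <- matrix(runif(nt * nd, 0, 10), nt, nd)
    gate <- runif(1, 2, 8)
    got <- motilitr:::gated_assignment(cost, gate)
    ref <- brute_force_assignment(cost, gate)
    cost_of <- function(a) sum(cost[cbind(which(!is.na(a)),
                                          a[!is.na(a)])]) +
      gate * sum(is.na(a)) + gate * (nd - sum(!is.na(a)))
    expect_equal(cost_of(got), cost_of(ref), tolerance = 1e-9)
  }
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(35)
  d <- data.frame(frame_index = rep(1:5, each = 3),
                  x_px = as.vector(sapply(1:5, function(f)
                    c(10, 60, 110) + 2 * f)),
                  y_px = rep(c(15, 50, 85), 5), area_px = 40)
  tr_a <- link_detections(d, link_params(gate_px = 8))
  d_shuffled <- d[sample(nrow(d)), ]
  tr_b <- link_detections(d_shuffled, link_params(gate_px = 8))
  expect_equal(length(tr_a), length(tr_b))
  pts <- function(tr) lapply(tr, function(t) t$points[order(t$points$frame), ])
  expect_equal(pts(tr_a), pts(tr_b))
})

test_that("trajectory tables carry physical kinematics", {
  cal <- calibration_state(1, 30, 200, 200)
  tbl <- manual_track_tbl(1, c(0, 3), c(0, 4), cal)
  expect_equal(nrow(tbl), 2)
  expect_true(is.na(tbl$step_speed_um_s[1]))
  expect_equal(tbl$step_speed_um_s[2], 150)       # 5 px * 30 fps * 1 um/px
  expect_equal(tbl$heading_deg[2], heading_deg(3, 4))
  empty <- track_table(structure(list(), class = "track_set"), cal)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("track_id", "t_s", "x_um", "heading_deg") %in%
                    names(empty)))
})

test_that("tracks round-trip through JSON-lines", {
  d <- data.frame(frame_index = rep(1:4, 2),
                  x_px = c(10:13 + 0.25, 50:53), y_px = rep(c(5, 40), each = 4),
                  area_px = c(30, 31, 30, 29, 60, 61, 62, 60))
  tr <- link_detections(d, link_params(gate_px = 5))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tracks_jsonl(tr, path)
  back <- read_tracks_jsonl(path)
  expect_equal(length(back), length(tr))
  for (i in seq_along(tr))
    expect_equal(back[[i]]$points, tr[[i]]$points)
})
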