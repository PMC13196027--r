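test_that("simulation is deterministic in the seed and sensitive to it", {
  sc1 <- test_scene(list(swimmer_pop(5)), 10, seed = 7)
  sc2 <- test_scene(list(swimmer_pop(5)), 10, seed = 7)
  sc3 <- test_scene(list(swimmer_pop(5)), 10, seed = 8)
  expect_identical(sc1$truth, sc2$truth)
  expect_identical(unclass(sc1$frames), unclass(sc2$frames))
  expect_false(isTRUE(all.equal(sc1$truth$x_um, sc3$truth$x_um)))
})

test_that("population motion models follow their definitions", {
  # empty scene
  empty <- simulate_tracks(scene_config(list(), test_cal(), 5))
  expect_equal(nrow(empty), 0)
  # adherent: static, zero speed
  adh <- particle_population("adherent", count = 1, radius_um = 4)
  tr <- simulate_tracks(scene_config(list(adh), test_cal(), 8, seed = 2))
  expect_equal(length(unique(tr$x_um)), 1)
  expect_equal(length(unique(tr$y_um)), 1)
  expect_true(all(tr$speed_um_s == 0))
  # fixed-heading swimmer at 100 um/s, 30 fps: 10/3 um straight up per frame
  sw <- swimmer_pop(1, speed = 100, mode = "fixed", heading = 0, turn_sd = 0)
  tr <- simulate_tracks(scene_config(list(sw), test_cal(), 5, seed = 3))
  expect_equal(diff(tr$y_um[!tr$wrapped]), rep(-10 / 3, 4))
  expect_equal(diff(tr$x_um[!tr$wrapped]), rep(0, 4))
  # sedimenters head straight down with no heading diffusion
  sed <- particle_population("sedimenter", count = 3, speed_um_s = 25)
  expect_equal(sed$heading_deg, 180)
  expect_equal(sed$turn_sd_deg, 0)
  tr <- simulate_tracks(scene_config(list(sed), test_cal(), 6, seed = 4))
  ok <- !tr$wrapped & c(diff(tr$frame) == 1, FALSE)
  expect_true(all(abs(diff(tr$y_um)[diff(tr$frame) == 1] -
                        25 / 30)[!tr$wrapped[-1][diff(tr$frame) == 1]] < 1e-9))
})

test_that("adding a drift shifts every per-frame displacement by exactly d", {
  pops <- list(swimmer_pop(4, turn_sd = 5))
  base <- simulate_tracks(scene_config(pops, test_cal(), 6, seed = 9))
  d <- c(1.3, -0.4)
  drifted <- simulate_tracks(scene_config(pops, test_cal(), 6, seed = 9,
                                          drift_um_per_frame = d))
  for (pid in unique(base$particle_id)) {
    b <- base[base$particle_id == pid, ]
    w <- drifted[drifted$particle_id == pid, ]
    sel <- !b$wrapped[-1] & !w$wrapped[-1]
    expect_equal(diff(w$x_um)[sel] - diff(b$x_um)[sel],
                 rep(d[1], sum(sel)), tolerance = 1e-9)
    expect_equal(diff(w$y_um)[sel] - diff(b$y_um)[sel],
                 rep(d[2], sum(sel)), tolerance = 1e-9)
  }
})

test_that("ground-truth speeds converge to the configured mean", {
  n <- 60
  pop <- particle_population("swimmer", count = n, speed_um_s = 100,
                             speed_sd_um_s = 12, radius_um = 4)
  tr <- simulate_tracks(scene_config(list(pop), test_cal(512, 512), 3,
                                     seed = 10))
  per_particle <- tapply(tr$speed_um_s, tr$particle_id, mean)
  expect_lt(abs(mean(per_particle) - 100), 3 * 12 / sqrt(n))
})

test_that("rendering is faithful: centroids, determinism, degenerate cases", {
  # a rendered disk's intensity-weighted centroid lies within 0.5 px of truth
  sc <- test_scene(list(swimmer_pop(1, turn_sd = 0)), 2, seed = 12,
                   noise_sd = 0.005)
  cal <- sc$config$calibration
  f <- sc$frames[[1]]
  w <- f - min(f)
  w[f < 0.4] <- 0  # mask the noisy background; the disk sits near 0.8
  xs <- outer(rep(1, nrow(f)), seq_len(ncol(f)) - 0.5)
  ys <- outer(seq_len(nrow(f)) - 0.5, rep(1, ncol(f)))
  cx <- sum(w * xs) / sum(w)
  cy <- sum(w * ys) / sum(w)
  tt <- sc$truth[sc$truth$frame == 1, ]
  expect_lt(abs(cx - tt$x_um / cal$um_per_px), 0.5)
  expect_lt(abs(cy - tt$y_um / cal$um_per_px), 0.5)
  # noiseless static scene renders identical frames
  adh <- particle_population("adherent", count = 1, radius_um = 5)
  sc0 <- test_scene(list(adh), 3, seed = 13, noise_sd = 0)
  expect_identical(sc0$frames[[1]], sc0$frames[[3]])
  # empty truth: background plus noise only
  cfg <- scene_config(list(), test_cal(64, 64), 2, noise_sd = 0,
                      background_level = 0.25)
  fr <- render_frames(simulate_tracks(cfg), cfg)
  expect_equal(unique(as.vector(fr[[1]])), round(0.25 * 255) / 255)
  # sub-pixel cells warn
  tiny <- particle_population("adherent", count = 1, radius_um = 0.5)
  cfg2 <- scene_config(list(tiny), test_cal(), 2)
  expect_warning(render_frames(simulate_tracks(cfg2), cfg2), "radius")
})

test_that("fixtures round-trip losslessly", {
  dir <- withr::local_tempdir()
  sc <- test_scene(list(swimmer_pop(3)), 4, seed = 14)
  write_fixture(sc$frames, sc$truth, dir)
  expect_equal(length(list.files(file.path(dir, "frames"))), 4)
  back <- read_fixture(dir)
  expect_equal(length(back$frames), 4)
  for (i in 1:4)
    expect_equal(back$frames[[i]], sc$frames[[i]], tolerance = 1e-9)
  expect_equal(nrow(back$truth), 3 * 4)
  expect_equal(back$config$seed, 14)
  # re-running the analysis on the re-read frames is bit-identical
  b1 <- frame_pair_speeds(sc$frames, drift_policy = "none")
  b2 <- frame_pair_speeds(back$frames, drift_policy = "none")
  expect_identical(b1, b2)
})
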