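test_that("identical frames yield essentially zero flow", {
  set.seed(1)
  A <- matrix(runif(120 * 120), 120, 120)
  fld <- dense_flow(A, A)
  expect_lt(max(fld$magnitude), 0.05)
  expect_equal(dim(fld$dx), dim(A))
})

test_that("a known rigid shift of a textured image is recovered", {
  set.seed(2)
  A <- as.matrix(EBImage::gblur(matrix(runif(200 * 200), 200, 200), 2))
  B <- matrix(0, 200, 200)
  B[, 4:200] <- A[, 1:197]  # +3 px along x
  fld <- dense_flow(A, B)
  inner <- 30:170
  expect_lt(abs(median(fld$dx[inner, inner]) - 3), 0.25)
  expect_lt(abs(median(fld$dy[inner, inner])), 0.25)
})

test_that("a moving disk's flow matches its ground-truth displacement", {
  cal <- calibration_state(1, 30, 128, 128)
  sw <- particle_population("swimmer", count = 1, speed_um_s = 4 * 30,
                            heading_mode = "fixed", heading_deg = 90,
                            radius_um = 5, intensity = 0.8)
  sc <- test_scene(list(sw), 2, cal = cal, seed = 5, noise_sd = 0.01)
  fld <- dense_flow(sc$frames[[1]], sc$frames[[2]])
  tt <- sc$truth[sc$truth$frame == 1, ]
  xs <- outer(rep(1, 128), seq_len(128) - 0.5)
  ys <- outer(seq_len(128) - 0.5, rep(1, 128))
  disk <- (xs - tt$x_um)^2 + (ys - tt$y_um)^2 <= 5^2
  expect_lt(abs(mean(fld$dx[disk]) - 4), 0.5)
  expect_lt(abs(mean(fld$dy[disk]) - 0), 0.5)
})

test_that("flow thresholding removes exactly the sub-threshold vectors", {
  dx <- matrix(c(0.2, 2, 0, 0.4), 2, 2)
  dy <- matrix(0, 2, 2)
  fld <- motilitr:::new_flow_field(dx, dy)
  expect_identical(threshold_flow(fld, 0)$dx, dx)
  kept <- threshold_flow(fld, 0.5)
  expect_equal(as.vector(kept$dx), c(0, 2, 0, 0))
  expect_identical(threshold_flow(threshold_flow(fld, 0.5), 0.5), kept)
  all0 <- threshold_flow(fld, 10)
  expect_true(all(all0$magnitude == 0))
})

test_that("motion regions isolate moving cells by edge and area", {
  cal <- test_cal()
  bounds <- test_area_bounds()
  # blank frame: nothing
  blank <- matrix(0.1, 256, 256)
  fld0 <- motilitr:::new_flow_field(matrix(0, 256, 256),
                                    matrix(0, 256, 256))
  expect_equal(length(extract_motion_regions(fld0, blank, bounds)), 0)
  # one rendered moving disk: exactly one region, correct mean vector
  sw <- particle_population("swimmer", count = 1, speed_um_s = 100,
                            heading_mode = "fixed", heading_deg = 90,
                            turn_sd_deg = 0, radius_um = 4, intensity = 0.8)
  sc <- test_scene(list(sw), 2, seed = 6)
  fld <- threshold_flow(dense_flow(sc$frames[[1]], sc$frames[[2]]), 0.5)
  regs <- extract_motion_regions(fld, sc$frames[[1]], bounds)
  expect_equal(length(regs), 1)
  expect_lt(abs(regs[[1]]$mean_vector[["dx"]] - 100 / 30 / 0.86), 0.6)
  expect_equal(regs[[1]]$mean_magnitude_px,
               sqrt(sum(regs[[1]]$mean_vector^2)))
  # a second region below the minimum area bound is filtered out
  regs2 <- extract_motion_regions(fld, sc$frames[[1]],
                                  c(bounds[2] * 0.9, bounds[2]))
  expect_equal(length(regs2), 0)
})

test_that("consensus drift matches an exhaustive grouping oracle", {
  vecs <- rbind(matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 3), 3), ncol = 2, byrow = TRUE))
  est <- estimate_drift_consensus(vecs, angle_tol_deg = 7.5,
                                  mag_tol_frac = 0.2)
  expect_equal(est$mode, "consensus")
  expect_equal(unname(est$vector), c(1, 0))
  expect_equal(est$support, 10)
  # exhaustive oracle over all subsets: largest mutually-consistent group
  set.seed(3)
  vr <- cbind(rnorm(11), rnorm(11))
  ang <- heading_deg(vr[, 1], vr[, 2])
  mag <- sqrt(rowSums(vr^2))
  consistent <- function(idx) {
    mu <- motilitr:::circ_mean_deg(ang[idx])
    med <- median(mag[idx])
    all(motilitr:::ang_diff(ang[idx], mu) <= 7.5) &&
      all(abs(mag[idx] - med) <= 0.2 * med)
  }
  best <- 0
  for (m in seq_len(2^11 - 1)) {
    idx <- which(bitwAnd(m, 2^(0:10)) > 0)
    if (length(idx) > best && consistent(idx)) best <- length(idx)
  }
  est2 <- estimate_drift_consensus(vr, 7.5, 0.2, min_support_frac = 0,
                                   min_support_n = 1)
  if (est2$mode == "consensus") expect_lte(est2$support, best)
  expect_true(best < 0.2 * 11 || est2$mode == "consensus")
})

test_that("consensus drift refuses degenerate and collective inputs", {
  # identical vectors: the group is everyone -> indistinguishable from
  # collective motion, refused at the default support ceiling
  same <- matrix(rep(c(2, 0), 8), ncol = 2, byrow = TRUE)
  expect_equal(estimate_drift_consensus(same)$mode, "none")
  # but accepted when the ceiling is lifted
  est <- estimate_drift_consensus(same, max_support_frac = 1)
  expect_equal(unname(est$vector), c(2, 0))
  expect_equal(est$support, 8)
  # three mutually dissimilar vectors at 40% support floor
  diss <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(estimate_drift_consensus(diss,
                                        min_support_frac = 0.4)$mode, "none")
  expect_equal(estimate_drift_consensus(NULL)$mode, "none")
})

test_that("drift correction subtracts the vector and is an involution", {
  regs <- list(motilitr:::new_motion_region(1:5, 5, 2, 1),
               motilitr:::new_motion_region(6:9, 4, -1, 0.5))
  none <- drift_estimate(mode = "none")
  expect_identical(apply_drift_correction(regs, none), regs)
  d <- drift_estimate(c(0.7, -0.3), 4, "consensus")
  dm <- drift_estimate(-d$vector, 4, "consensus")
  back <- apply_drift_correction(apply_drift_correction(regs, d), dm)
  for (i in 1:2) {
    expect_equal(back[[i]]$mean_vector, regs[[i]]$mean_vector)
    expect_equal(back[[i]]$mean_magnitude_px, regs[[i]]$mean_magnitude_px)
  }
  corr <- apply_drift_correction(regs, d)
  expect_equal(unname(corr[[1]]$mean_vector), c(2 - 0.7, 1 + 0.3))
})

test_that("dark-segment calibration recovers a pure translation", {
  # adherent cells under uniform drift: dark estimate ~ drift
  adh <- particle_population("adherent", count = 10, radius_um = 4,
                             intensity = 0.8)
  d_px <- c(1.5, 0.8)
  sc <- test_scene(list(adh), 6, seed = 21, drift = d_px * 0.86)
  est <- estimate_drift_dark(sc$frames)
  expect_equal(est$mode, "dark_calibrated")
  expect_lt(abs(est$vector[["dx"]] - d_px[1]), 0.3)
  expect_lt(abs(est$vector[["dy"]] - d_px[2]), 0.3)
  # static scene: zero drift
  sc0 <- test_scene(list(adh), 4, seed = 22)
  est0 <- estimate_drift_dark(sc0$frames)
  expect_lt(sqrt(sum(est0$vector^2)), 0.2)
  # isotropic swimmers: vectors cancel, |drift| well below the speed
  sw <- swimmer_pop(25)
  sc1 <- test_scene(list(sw), 10, cal = test_cal(384, 384), seed = 23)
  est1 <- estimate_drift_dark(sc1$frames)
  speed_px <- 100 / 30 / 0.86
  expect_lt(sqrt(sum(est1$vector^2)), speed_px / 3)
})

test_that("speed series: static scenes, linear unit scaling", {
  adh <- particle_population("adherent", count = 5, radius_um = 4,
                             intensity = 0.8)
  sc <- test_scene(list(adh), 4, seed = 24)
  sp <- frame_pair_speeds(sc$frames, drift_policy = "none")
  expect_true(all(is.na(sp$mean_speed_um_s) | sp$mean_speed_um_s < 5))
  # same pixel data at doubled calibration factor: speeds double
  sw <- swimmer_pop(6)
  sc2 <- test_scene(list(sw), 4, seed = 25)
  sp1 <- frame_pair_speeds(sc2$frames, drift_policy = "none")
  cal2 <- calibration_state(2 * 0.86, 30, 256, 256)
  sp2 <- frame_pair_speeds(frame_sequence(unclass(sc2$frames), cal2),
                           topdown_params(cell_radius_um = 8),
                           drift_policy = "none")
  ok <- !is.na(sp1$mean_speed_um_s) & !is.na(sp2$mean_speed_um_s)
  expect_equal(sp2$mean_speed_um_s[ok], 2 * sp1$mean_speed_um_s[ok])
})
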