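# motilitr

Quantitative motility and photoresponse analysis of free-swimming
microorganisms from grayscale video.

Motile microalgae and other microswimmers (5–100 µm, 50–250 µm/s)
reveal their physiological state through how they swim: mean speed,
the fraction of cells that swim at all, collective orientation toward
or away from a light source (phototaxis), and the transient swimming
stop triggered by a sudden strong light pulse (photoshock). `motilitr`
turns calibrated image sequences of such organisms into these
readouts. It is written for labs running low-cost, light-controlled
video microscopes, and for anyone who needs a fully testable,
scriptable motility pipeline in R.

## What it computes

Two complementary analysis routes share one calibration layer
(µm/pixel, frames/s):

- **Top-down (population scale).** Dense optical flow between
  consecutive frames (pyramidal Lucas–Kanade), noise thresholding,
  motion-region extraction by Canny edges + area filtering, and drift
  correction by consensus: the largest group of region vectors with a
  common direction (within a tolerance, typically 5–10°) and
  magnitude is taken as bulk drift — sedimentation or fluid motion —
  and subtracted. Per frame pair *t*, the mean region displacement
  \|v̄\| converts to speed as \|v̄\|·(µm/px)·fps. Robust, per-pair
  independent, ideal for instantaneous speed dynamics.
- **Bottom-up (single cell).** Adaptive-threshold segmentation,
  subpixel intensity-weighted centroids, pooled percentile area
  filtering (drop the 10 % smallest and largest objects), and
  identity-preserving linking: constant-velocity prediction plus
  globally optimal gated assignment (Hungarian algorithm), confirming
  tracks after 2 hits and surviving 3 missed frames.

On top of the trajectories and speed series:
`classify_by_speed()` / `classify_by_trajectory_angle()` (motile
fraction; the latter separates swimmers from cells sedimenting
uniformly straight down and is an absolute fraction),
`orientation_histogram()` (polar histogram, circular mean, resultant
length R), `photoshock_response()` (baseline, drop and recovery
timing around light pulses), and `speed_summary()` (replicate mean ±
sd). Supporting modules: closed-form optics (Rayleigh limit
r = 0.61 λ/NA, rolling-shutter errors E = v/(L·f), FOV and
magnification arithmetic), the JSON wire protocol of a five-channel
LED stimulus driver with pulse-and-restore semantics, and a
ground-truthed synthetic scene generator (ballistic swimmers,
sedimenters, adherent cells, bulk drift) that exercises every stage
end to end.

## Worked example

Simulate a scene of 8 swimmers at 100 µm/s, render it, and run both
pipelines:

```r
library(motilitr)

cal <- calibration_state(um_per_px = 0.86, frame_rate = 30,
                         frame_width_px = 256, frame_height_px = 256)
pop <- particle_population("swimmer", count = 8, speed_um_s = 100,
                           heading_mode = "isotropic", turn_sd_deg = 3,
                           radius_um = 4, intensity = 0.8)
cfg <- scene_config(list(pop), cal, n_frames = 20, seed = 3)
frames <- render_frames(simulate_tracks(cfg), cfg)
frames
#> <frame_sequence> 20 frames of 256 x 256 px at 30 fps, 0.86 um/px

speeds <- frame_pair_speeds(frames)     # top-down route
head(speeds, 3)
#>   frame_index     time_s mean_speed_um_s n_regions drift_dx_px drift_dy_px
#> 1           1 0.00000000        96.85079         7           0           0
#> 2           2 0.03333333        99.67844         7           0           0
#> 3           3 0.06666667        98.03570         8           0           0
mean(speeds$mean_speed_um_s, na.rm = TRUE)
#> [1] 100.0031
```

Each row is one frame pair: the mean speed of the detected motion
regions in µm/s, how many cell-sized regions contributed, and the
drift vector that was subtracted (zero here — with only 8 cells the
consensus estimator correctly refuses to call a "drift"). The
recovered 100.0 µm/s matches the configured ground truth.

```r
dets <- do.call(rbind, lapply(seq_along(frames), function(i)
  detect_cells(segment_frame(frames[[i]]), frames[[i]], i)))
dets <- filter_by_area_percentile(dets)
tracks <- link_detections(dets, link_params(gate_px = 12))
tbl <- track_table(tracks, cal)
classify_by_speed(tbl)
#> <motility_report> speed_based: 11 tracks, motile fraction 1.000 (comparative)
mean(tbl$step_speed_um_s, na.rm = TRUE)
#> [1] 97.45525
```

The bottom-up route reconstructs individual trajectories (11 tracks:
8 cells plus splits where a cell crosses the wrap boundary), agrees on
the speed within a few percent, and labels every track motile. The
optics and stimulus-protocol helpers are plain function calls:

```r
rayleigh_resolution(0.85, 0.12)      # resolution limit at 850 nm, NA 0.12
#> [1] 4.320833                       # ~4.3 um
build_command(b = 1000, pulse_ms = 100)  # LED driver wire format
#> {"pulse":100,"b":1000}
```

A command-line wrapper with subcommands `simulate`, `analyze`,
`photoshock`, `orient`, `ledcmd` and `version` is installed under
`exec/motilitr`.

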