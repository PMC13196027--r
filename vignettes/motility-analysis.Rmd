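---
title: "Quantifying microswimmer motility from video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microswimmer motility from video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motilitr)
```

`motilitr` quantifies the swimming behaviour of free-swimming
microorganisms — microalgae such as *Chlamydomonas reinhardtii* or
*Euglena gracilis*, and other microswimmers in the 5–100 µm range —
from grayscale video recorded on a calibrated microscope. It covers
two complementary analysis routes, the supporting optics arithmetic,
the wire protocol of a programmable five-channel LED stimulus driver,
and a ground-truthed synthetic scene generator that makes every stage
of the pipeline testable without hardware. This vignette describes the
models, the tunable parameters, and the design decisions behind them.

## Conventions

All lengths are micrometres, times are seconds and angles are degrees;
unit conversions happen only in the calibration layer
(`calibration_state()`, `px_per_frame_to_um_per_s()`). Headings use a
polar-plot convention: 0° points to the top of the frame (where a
directional light source sits in phototaxis assays) and angles grow
clockwise on screen. Because the image y axis points down, a heading
of 180° is sedimentation straight down.

## The two analysis routes

**Top-down (population scale).** Dense optical flow is computed
between consecutive frames and summarized per cell:

1. `dense_flow()` estimates a per-pixel displacement field with a
   pyramidal, iterative Lucas–Kanade scheme: per pixel, the windowed
   normal equations of the brightness-constancy constraint are solved
   and the second frame is re-warped, coarse to fine. Defaults:
   15 px window, 3 pyramid levels, 3 iterations per level, one
   binomial pre-smoothing pass. A pixel whose windowed structure
   tensor has a smaller eigenvalue below `min_eig` (default 0.03 on
   images scaled to [0, 1]) carries no displacement evidence — flat or
   noise-only background — and keeps zero flow. The gate sits about
   5× above the gradient-noise floor at pixel noise sd 0.02 and about
   100× below the signal of a resolved cell edge, so it is insensitive
   to moderate mis-specification. We chose Lucas–Kanade over a
   polynomial-expansion scheme because its per-pixel normal equations
   are directly checkable against rigid-shift oracles, and at these
   cell sizes (diameter below the window) both schemes integrate the
   same evidence.
2. `threshold_flow()` zeroes vectors below `min_magnitude_px`
   (default 0.5 px/frame, above the flow noise floor measured on
   identical-frame pairs).
3. `extract_motion_regions()` isolates cell footprints from the frame
   itself — Canny edges, contour closing, hole filling, connected
   components — and discards components outside the area bounds
   (default 0.25–4× the expected cell area πr² from the caller's
   `cell_radius_um`), removing debris and aggregates. A footprint's
   mean vector is the arithmetic mean of its supra-threshold pixel
   vectors; its magnitude is the **norm of the mean vector**, treating
   the cell as a rigid translating body (averaging norms would rectify
   noise). Footprints whose flow was entirely thresholded away remain
   in the list with a zero vector: a population that stops swimming
   reads as speed ≈ 0, not as an empty frame. Truly empty frames still
   yield a missing value.
4. Drift correction (below), then the mean region speed is converted
   to µm/s. Each frame pair is independent, which is what makes this
   route robust and parallelizable — at the price of not tracking
   identities.

**Bottom-up (single cell).** `segment_frame()` applies a local-mean
adaptive threshold (default 31 px block, offset 0.08 ≈ 4 noise sd —
an offset near the noise sd floods the mask with false positives);
`detect_cells()` closes and fills the mask, labels components and
takes intensity-weighted subpixel centroids;
`filter_by_area_percentile()` pools all areas over the video and drops
the smallest and largest 10 % (linear-interpolation quantiles, with
membership `(q_low, q_high]`; when the distribution is degenerate and
both quantiles coincide, everything at the modal area is kept).
`link_detections()` builds identities: each live track predicts its
next position under a constant-velocity model, predictions and
detections are matched by a globally optimal one-to-one assignment
(an O(n³) Hungarian solver written for this package) under a gating
radius, tentative tracks are confirmed after `init_hits = 2` points,
and tracks survive `max_skip = 3` missed frames to bridge brief
occlusions. A sensible gate is 3× the expected per-frame
displacement. The tracker is implemented natively, rather than
delegated, so its behaviour is fully specified: ties in the
assignment resolve deterministically to the lowest indices, and
detections are processed in a canonical within-frame order so results
do not depend on input order.

## Drift correction

Sedimentation or bulk fluid motion adds a common displacement to every
cell. `estimate_drift_consensus()` finds the largest group of region
vectors mutually within `angle_tol_deg` of the group's circular-mean
direction (default 7.5°, the midpoint of the typical 5–10° working
range) and within ±20 % of the group's median magnitude — the paper
trail behind that magnitude band is thin, so it is an explicit,
configurable completion of the rule — and returns the group mean as
the drift. Two refusal guards are deliberate:

- if the group holds less than `min_support_frac = 0.2` of all
  vectors, or fewer than `min_support_n = 5` vectors in absolute
  terms, there is no credible non-motile majority — in a sparse scene
  a couple of swimmers aligned by chance would otherwise pass the
  fractional floor and their speed would be subtracted as "drift";
- if it holds more than `max_support_frac = 0.9`, coherent collective
  swimming (strong phototaxis) cannot be distinguished from drift, and
  subtracting it would cancel the signal. In that regime the drift
  must come from a dark pre-exposure segment
  (`estimate_drift_dark()`), during which no directed swimming is
  assumed and all region vectors are averaged without a consensus
  restriction.

`apply_drift_correction()` subtracts the drift vector from every
region; correcting by *d* and then by *−d* is exactly the identity.
After a consensus correction the drift-group regions (presumed
non-motile) are excluded from the speed average by default
(`include_drift_group` restores them) — whether they should re-enter
after correction is genuinely ambiguous, and excluding cells that
defined "not moving" is the conservative choice.

## Biological readouts

**Motile fraction.** Two classifiers mirror the two observation
geometries. In a droplet chamber viewed from above, non-swimmers are
adhered and `classify_by_speed()` labels a track motile above a speed
threshold (default 5 µm/s, well above centroid-noise speed at all
supported calibrations at 30 fps); the resulting fraction is
comparative only. In a cuvette viewed horizontally, non-motile cells
sediment at a uniform speed straight down, so
`classify_by_trajectory_angle()` estimates the modal sedimentation
speed from downward tracks (kernel-density mode) and labels a track
non-motile iff its mean heading is within ±15° of down *and* its mean
speed within ±25 % of that mode; this fraction is absolute. The
tolerances are defaults of this package — the criterion itself does
not fix them — and both are exposed.

By default the fraction weights each track by its number of points
rather than counting tracks once. The reason is an observation bias:
a fast swimmer crosses the field of view (or, in the synthetic scene,
a wrap boundary) more often than a slow sedimenter and therefore
fragments into more tracks. On a 50/50 synthetic scene the per-track
count reads ≈ 0.62 while duration weighting recovers 0.50; `weight =
"count"` restores the unweighted definition.

**Orientation.** `orientation_histogram()` bins per-track mean
headings into 16 sectors of 22.5° (a typical polar-plot granularity;
`n_bins` is exposed) and reports the circular mean together with the
resultant length R of the mean unit vector: R = 1 for perfectly
aligned headings, R → 0 for isotropy. Callers filter non-motile
tracks first, as a phototaxis readout should. The statistic is
equivariant under global rotation and, for n = 1000 isotropic
headings, stays below 0.08 with 99 % probability (the Rayleigh
statistic).

**Photoshock.** A sudden strong light pulse triggers a transient
swimming stop. `photoshock_response()` works on the top-down speed
series because frame-pair speeds react instantly: per pulse, the
baseline is the mean speed over 5 s before onset, a response is a drop
below 0.5× baseline within 1 s of onset, and the response duration
runs from onset until the speed first recovers to 0.7× baseline
sustained for 5 consecutive samples. These window defaults fit assays
with ~10 s pulse spacing and ~5 s responses; all are parameters, all
thresholds are relative, so the result is invariant to rescaling the
series. Overlapping analysis windows of consecutive pulses are an
error rather than a silent misreading.

**Speed tables.** `speed_summary()` reports mean and sample sd over
replicate recordings (one mean per recording), the usual form of
published speed tables; a single replicate has no sd and reports `NA`.

## Optics arithmetic

`rayleigh_resolution()` (r = 0.61 λ/NA), `fov_um()`,
`magnification()` and the rolling-shutter error pair
(`rolling_shutter_relative_error()` E = v/(L·f),
`rolling_shutter_shift()` ΔL = v·L_cell/(L·f)) are closed forms used
to reason about a build before measuring anything: e.g. at λ =
0.85 µm and an effective NA of 0.12 the resolution limit is ≈ 4.3 µm
— oversampled for subcellular detail but ample for centroid tracking —
and a worst-case 250 µm/s cell under a 245 µm scan FOV at 30 fps
suffers only a 3.4 % velocity error and a 0.34 µm shape shift, so
rolling-shutter sensors remain usable. The published FOV of the
high-magnification state (440 × 240 µm) disagrees slightly with
0.34 µm/px × 1280 × 720 (435 × 245 µm); the package treats the
calibration factor times the pixel count as authoritative.

## The synthetic scene generator

`simulate_tracks()` + `render_frames()` produce ground-truthed videos
with the population structure the analyses assume: ballistic swimmers
with per-frame Gaussian heading diffusion, sedimenters moving straight
down at uniform speed, adherent (static) cells, optional uniform bulk
drift, anti-aliased disk rendering, Gaussian pixel noise (default sd
0.02) and 8-bit quantization. Initial positions are sampled with a
hard-core constraint — centres at least the sum of radii apart — since
real cells exclude volume; two cells initialized on top of each other
would otherwise render as one segmentation blob for as long as their
motion keeps them together (for co-moving sedimenters, the entire
recording). Overlaps can still develop during motion, because
collision dynamics are out of scope. Positions wrap toroidally — keeping the
density constant, as cells entering and leaving a real field of view
do — and wrap events are flagged in the ground truth so
trajectory-level comparisons can exclude them. Stimulus-coupled
behaviour is imposed, not modelled: a per-frame `speed_scale` profile
can stop the swimmers for 5 s after each pulse, which is how the
photoshock pipeline is exercised end to end. Exposure is treated as
instantaneous (no motion blur or rolling-shutter distortion — the
closed forms above show the distortion is sub-resolution at the speeds
of interest), and cells do not interact hydrodynamically or collide.
Passing tests on these scenes therefore demonstrates correct
*measurement* of idealized motion, not robustness to crowding,
focus drift or illumination gradients in real footage.

Default scene conditions used by the validation suite: 0.86 µm/px at
30 fps (the mid-magnification working point), cells of radius 4 µm and
brightness 0.8 on a 0.1 background, swimmers at 100 µm/s (the order of
a healthy *C. reinhardtii* culture), sedimenters at 25 µm/s,
512 × 512 px scenes of 40 cells for speed/drift recovery and 300
frames (10 s); the photoshock scene uses 256 × 256 px and 900 frames
(30 s, pulses at 10 s and 20 s). These sizes keep a full validation
run to a few minutes while leaving every estimate's sampling error far
below the tolerance being tested.

## Numerical choices and edge cases

- Flow updates are clamped to 1.5 px per iteration (the linearization
  is local); large displacements are handled by the pyramid, not the
  clamp.
- Region mean magnitude is the norm of the mean vector, not the mean
  of norms (rectification bias).
- Quantiles are type-7 (linear interpolation); area-filter membership
  is `(q_low, q_high]` with a degenerate-distribution guard.
- Assignment cost ties break toward lower indices; the augmented
  matrix prices "leave unmatched" at exactly the gate radius, so a
  pair is linked iff it beats dropping both.
- Pairs with no detected cell footprint yield `NA` speeds, never 0.
- The LED command serializer emits keys in the fixed order `pulse, r,
  g, b, w, ir` with no whitespace, reproducing the documented examples
  byte for byte; the parser is strict (unknown keys, duplicates and
  non-integers are errors) because a driver's tolerance for malformed
  input is unspecified. Overlapping pulses are rejected; a constant
  command arriving during a pulse updates the state that will be
  restored. The duty-cycle scale 0–1000 maps to physical photon flux
  (µE m⁻² s⁻¹) only through a per-device calibration the caller
  supplies.

## Known limitations

- Dense cultures: overlapping cells merge into single detections and
  identities fragment or swap; the tracker makes no attempt at
  splitting merged blobs. Keep cultures dilute.
- Container videos (mp4/avi) must be extracted to frame directories
  before analysis (`ffmpeg -i video.mp4 frames/%06d.png`); the reader
  handles PNG/TIFF directories only.
- Lens-distortion correction is out of scope; record with a central
  sensor crop.
- The consensus drift estimator assumes a coherent non-motile
  minority-to-majority; between its two refusal guards (20 %–90 %
  support) lies the regime it is designed for.
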