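---
title: "Spray-mode analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spray-mode analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spraymode)
```

`spraymode` characterizes the droplet stream of an electrospray delivery
device from side-view high-speed video. This vignette records the models the
package implements, the parameters that matter, and the design decisions
taken where the method leaves genuine freedom — in enough detail that a
maintainer can judge each choice.

## The measurement model

A recording is a stack of grayscale frames with a known field of view,
image size and frame rate; droplets travel along one image axis from the
capillary tip (at `tip_position_px`) toward the target at the working
distance `d_wd`. The pixel size is taken as the mean of the width- and
height-derived values and the two must agree within 2% — a spray-mode
analysis silently calibrated with anisotropic pixels would corrupt every
volume by the square of the anisotropy, so the configuration is rejected
instead.

Per frame, droplet images are segmented from a temporal-median background
at an adaptive threshold of `threshold_k` (default 4) times the robust
noise SD (MAD) of the difference image, labelled under 8-connectivity
(diagonal contact matters for fast movers), and discarded below
`pixel_cutoff` (default 10) pixels. Each surviving blob is measured by its
intensity-weighted sub-pixel centroid, pixel area, extent along the
propagation axis, and a focus proxy (mean boundary gradient).

**Half-maximum area refinement.** Area, extents and centroid are measured
on the pixels at or above half of the blob's peak background-subtracted
intensity rather than on the raw `k`·SD mask. The raw mask's area depends
on where the threshold sits on the blurred edge profile of the droplet:
with a bright droplet (SNR ~20) a 4-SD threshold sits far down the skirt
and inflates the radius by most of a pixel, which — because the volume
model scales as area squared — biased small-droplet volumes by over 30% in
synthetic trials. Measuring at half maximum (the FWHM convention) makes
the area estimate independent of the threshold height for any symmetric
edge profile. `refine = "none"` restores the raw-mask measurement.

## Volumetry

The droplet volume is estimated assuming rotational symmetry around the
direction of propagation: the measured axial diameter gives the semi-axis
`a`, the projected area `A` gives the lateral semi-axis `b = A/(π·a)`, and
`V = 4/3·π·a·b²`. The model reproduces both detection-limit reference
shapes exactly — a 10-pixel image at 5.6 µm/pixel is a 4.2 pl sphere
(r = 10 µm) or a 2.1 pl prolate ellipsoid (20 µm × 5 µm):

```{r}
detection_limit_volume(10, 5.6, "sphere")
detection_limit_volume(10, 5.6, "ellipsoid", c(20, 5))
```

Note that at fixed area the volume *decreases* with axial extent
(`V ∝ A²/a`): an elongated image of the same projected area implies a
slimmer body of revolution. Volumes at or below the 4.2 pl floor are not
evaluated (pixelation noise dominates there), and neither are velocities
above 20 m/s (less than two usable observations inside the field).

Volume is evaluated at the droplet's **first appearance**, where droplets
are closest to the focal plane. Two guards apply before trusting that
observation: its fill ratio (area over the ellipse spanned by its axial and
lateral extents) must be at least 0.75, and its area must lie within
[0.6, 1.67] of the trajectory's median area. Near the emission point a
droplet image occasionally merges with a neighbour's, and (rarely) a
trajectory's first observation belongs to a different droplet than the rest
of the track; both corrupt `V ∝ A²/a` badly, and in either case the
earliest consistent observation is used instead.

## Trajectory linking

Frame-to-frame linking is greedy nearest-neighbour within a gating radius
of `max_velocity/frame_rate` (2 mm at the defaults — 20 m/s at 10 kHz),
with backward axial motion beyond 1 px forbidden and ties broken by
distance, then area difference. Two refinements proved necessary at
realistic emission densities:

* **Constant-velocity prediction.** For tracks with at least two
  observations the neighbour distance is measured from the extrapolated
  next position (standard particle-tracking-velocimetry practice), and the
  match must fall within `accel_tol` (default 0.35) of the gate around that
  prediction. Pure position-nearest linking systematically captured newly
  emitted droplets near the tip — a new droplet appears *closer* to a
  track head than the head's own continuation one step ahead — fragmenting
  trajectories and corrupting impact velocities by up to two orders of
  magnitude.
* **Exit termination.** A track whose predicted centre leaves the image is
  over; allowing it to capture another droplet's blob manufactured
  chimeric records.

**Splitting.** When at least two candidate blobs fall inside one parent's
gate and their summed area is at most `(1 + area_tol)` times the parent's
(area conservation as the observable proxy for volume conservation —
splitting a sphere into two equal halves increases total projected area by
only 26%), and every child is distinctly smaller than the parent (≤ 0.9×
its area — a continuation blob next to a small bystander is not a split),
the parent ends and the children begin with their `parent_id` set.

**Qualification.** A droplet is evaluated only if its first appearance
lies ahead of the ROI (25% of `d_wd` beyond the tip) and its last beyond
it (87.5%). Split children inherit their ultimate parent's entry position.
This traversal rule has a measurable sampling consequence the analyst
should know: a droplet at 14 m/s advances 1.4 mm between frames, so its
first observation falls beyond the ROI start in roughly a third of
flights. The fast minor group of a spray is therefore under-sampled
relative to its emitted share — visible in synthetic recoveries as a minor
group fraction of ~3.5% when 5% was emitted — while centroid estimates
are barely affected.

**Focal filter.** The focal criterion ("stays within ~0.5 mm of the focal
plane") is operationalized through the blob sharpness: a trajectory is
kept when its *median* observation sharpness is within `band` (default
±40%) of the sequence's in-focus reference, the 95th percentile of all
blob sharpness. The median — not every observation, as one might first
write it — because with realistic noise a single noisy observation would
otherwise reject about a quarter of genuinely in-focus trajectories. On
synthetic data an exact mode (`mode = "exact"`) keeps droplets with
|z| ≤ 0.25 mm from the ground truth; the two modes agree on ≥ 90% of
trajectories at default render settings.

**Impact velocity** is the centroid displacement between the last two
observations times pixel size and frame rate. An option
(`velocity_at = "roi_exit"`) clips the trajectory at the ROI exit first,
for the reading under which only frames inside the ROI are "evaluated";
the default uses the overall last two frames.

## Clustering and group selection

Records from the (typically three) replicate sequences are concatenated
and clustered by Lloyd's k-means with 10 k-means++-seeded restarts,
keeping the lowest within-cluster sum of squares. Features are z-scored
log-volume and velocity: the two axes are incommensurable (nl vs m/s), so
both are standardized, and the volume enters on the log scale because
droplet volumes are strongly right-skewed across orders of magnitude —
with raw volumes the heavy tail of the dominant group makes the silhouette
criterion flip between splitting by velocity and splitting off volume
outliers from seed to seed, while log-volume selects the generative
two-group structure stably. Raw-volume clustering remains available
(`transform = "identity"`).

The number of groups is chosen from the mean silhouette over k = 2…6
(silhouettes are undefined at k = 1), taking the argmax with ties toward
smaller k; when even the best mean silhouette is below 0.5 — the
conventional boundary below which structure is considered weak — a single
group is reported. This replaces a visual reading of silhouette plots with
a reproducible rule; it is deliberately conservative, and on strongly
overlapping three-population mixtures it can prefer k = 2 where a human
reader might argue for 3.

Groups are reported in descending order of fractional volume, so group 1
is always the dominant carrier of the delivered volume; `V_g` is the exact
sum of member volumes and the `V_%` sum to 100 before rounding.

## The synthetic generator

`sample_ensemble()` draws droplets group by group until each group's
cumulative volume reaches its share of the total: volumes are log-normal
(moment-matched to the group mean ± SD; positivity and right-skew are
properties real spray distributions share), speeds are normal truncated to
positive, emission times are uniform (steady-state spray), entry positions
sit in a lateral band around the image centre, and the distance from the
focal plane is normal (`z_sd_mm`, default 0.12 mm). A configurable
fraction of droplets splits in flight into two volume-conserving children
that separate laterally.

`render_frames()` draws each droplet as a filled ellipse whose projected
area matches its volume under the volumetry model (aspect ratio 1 —
spherical — by default), advected by `velocity/frame_rate` per frame,
Gaussian-blurred by `0.5 px` in focus plus `4 px/mm` of defocus distance
(a plausible depth-of-field scale for such macro optics), over additive
Gaussian noise (SD 6 at a droplet contrast of 120 on 8 bits — high-contrast
imaging with SNR 20). Rendering is deterministic per frame given
`rng_seed`, identical between the in-memory and the constant-memory
accessor modes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: motion blur (droplets are drawn at instantaneous
positions, while a real exposure smears a 14 m/s droplet over ~1 mm;
volumes of fast droplets in real footage carry an elongation bias the
method does not correct), the target surface (droplets fly until they
leave the field of view; impact splashing and sessile deposits are
absent), lateral aerodynamic or electrostatic drift, droplet oscillation
or non-ellipsoidal shapes, and illumination drift. The detection defaults
(`polarity = "both"`) also handle dark-on-bright shadowgraphy, but the
generator's default is bright-on-dark.

## Numerical and procedural choices

* Degenerate inputs: empty frames and empty ensembles are legal
  everywhere (empty tables, not errors); single-observation trajectories
  cannot yield a velocity and are skipped; a zero flow rate, a zero
  working distance, or a tip outside the image are configuration errors.
* The per-sequence noise SD is estimated once (median of per-frame MADs
  over a subsample) — the noise is stationary by construction and the
  estimate is identical in expectation to the per-frame version.
* k-means restarts that collapse a cluster are discarded and re-seeded;
  determinism is guaranteed by running all randomness under an explicit
  seed without disturbing the caller's RNG state.
* Connected components use a run-length union-find (vertical runs united
  across adjacent columns when row ranges touch within one pixel), exact
  for 8-connectivity.
* Fractions are computed exactly and rounded only for display.

## Problem sizes used in validation

The synthetic validation harness (`simulate_spray_analysis()`) emits
600 nl over 0.1 s — about 570 droplets, ~150 of them in the minor fast
group — into a 992 × 100 px strip at the native 5.6 µm/px calibration,
and the acceptance checks take medians over 20 seeds. These sizes were
fixed by a power analysis of the estimator itself: the minor group's
volume centroid is a mean of ~40 detected log-normal draws with CV 2, and
20-seed medians of that mean land within 15% of truth ~98% of the time at
this size (~91% at two-thirds the size). The field height is reduced
rather than the resolution because coarsening the pixels raises the
4.2 pl detection floor eightfold per twofold coarsening, truncating the
0.2 nl group's left tail.

## Known limitations

* No motion-blur correction: axial extents of fast droplets are biased
  long in real footage (documented, not corrected).
* Linking is greedy; it matches an exhaustive minimal-total-distance
  assignment on sparse scenes, but dense crossings (several droplets per
  gate) can still swap identities.
* No coalescence handling: merging droplets end as one trajectory.
* The silhouette rule inherits k-means' preference for compact, equally
  scaled groups; heavily imbalanced or elongated populations may be
  merged at selection time even when a larger k is defensible.
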