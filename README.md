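# spraymode

Quantitative spray-mode analysis of electrospray (electrohydrodynamic
atomization, EHDA) droplet delivery from high-speed video.

In electrospray gene delivery, a conducting liquid is dispersed from a
capillary into charged microdroplets that accelerate toward a counter
electrode carrying the target cells. The ensemble character of those
droplets — how many, how large, how fast — is the *spray mode*, and it
decides how gently and how efficiently material is delivered. `spraymode`
turns side-view high-speed recordings of the droplet stream (typically
10,000 frames/s at a ~5.6 µm/pixel calibration) into a compact, Table-style
summary of the droplet populations.

## What the pipeline computes

For each recording the package:

1. **Detects droplets per frame** — temporal-median background subtraction,
   an adaptive threshold at *k*·(robust noise SD), 8-connected components,
   and a 10-pixel area cutoff (the volume of a 10-pixel spherical droplet
   image at 5.6 µm/pixel, 4.2 pl, is the resolution floor).
2. **Links blobs into trajectories** frame to frame (greedy gated
   nearest-neighbour with constant-velocity prediction), including in-flight
   **droplet splitting**: a parent ending in two smaller children whose
   summed area conserves the parent's.
3. **Qualifies trajectories** by traversal of the axial region of interest —
   the band from 25% to 87.5% of the working distance beyond the capillary
   tip (62.5% of the working distance) — and by staying within the ~0.5 mm
   focal range.
4. **Evaluates each qualified droplet**: the volume V_d at its first
   appearance under a rotational-symmetry model (an ellipsoid of revolution
   around the propagation direction: with axial semi-axis *a* from the
   measured diameter and projected area *A*, the lateral semi-axis is
   *b = A/(πa)* and *V = 4/3·π·a·b²*), and the impact velocity v_d from the
   displacement between the last two tracked frames.
5. **Clusters the merged replicate records** in (volume, velocity) space
   with Lloyd's k-means (standardized log-volume and velocity features,
   k-means++-seeded restarts), choosing the number of groups k from the
   mean silhouette over k = 1…6. Each group is reported as
   ⟨V_d⟩ ± SD, ⟨v_d⟩ ± SD, its total volume V_g, and its fractional
   contribution V_% to the delivered volume.

A full **synthetic spray-video generator** (`sample_ensemble()`,
`render_frames()`) emulates such recordings with exact ground truth —
log-normal droplet volumes, truncated-normal speeds, splitting events,
defocus blur, sensor noise — so every stage is testable without raw videos.

## Worked example

```r
library(spraymode)

geom <- acquisition_geometry(
  fov_width_mm = 5.565, fov_height_mm = 0.561,
  image_width = 992, image_height = 100,
  frame_rate_hz = 10000, working_distance_mm = 4, tip_position_px = 50)

pixel_size(geom)           # 5.61 um/pixel
roi_from_geometry(geom)    # ROI: 1.000 mm to 3.500 mm beyond the tip
delivery_time(25, 20)      # 75 s to deliver 25 ul at 20 ul/min
sucrose_osmolarity(12.67)  # 370.1 mOsm
detection_limit_volume(10, 5.6)  # 4.18 pl (10-px sphere)

# simulate a 3.0 kV reference spray and analyse it end to end
run <- simulate_spray_analysis(seed = 11)
run$result
#> Spray mode: 2 group(s), total evaluated volume 269.2 nl
#>   group 1 (n=199): <V_d> = 1.31 +/- 1.24 nl, <v_d> = 3.0 +/- 1.7 m/s, V_g = 260 nl (97%)
#>   group 2 (n=38): <V_d> = 0.25 +/- 0.37 nl, <v_d> = 14.3 +/- 2.9 m/s, V_g = 9 nl (3%)
```

The two recovered groups match the generating populations: a dominant
~1.4 nl population at ~3 m/s carrying almost all delivered volume, and a
minor ~0.2 nl population at ~14 m/s. (The minor group's recovered share
undershoots its emitted 5% slightly because fast droplets cross the far ROI
bound between frames more often; medians over many seeds land within the
tolerances in `scripts/acceptance.R`.)

Analysing real recordings works the same way from a YAML configuration:

```r
cfg <- read_spray_config("run.yaml")   # geometry + inputs + output_dir
res <- run_pipeline(cfg)               # writes records.csv, group_table.csv, summary.json
```

### Configuration keys

```yaml
geometry:                 # required
  fov_width_mm: 5.565     # field of view (mm)
  fov_height_mm: 3.366
  image_width: 992        # image size (px)
  image_height: 600
  frame_rate_hz: 10000
  working_distance_mm: 4  # capillary tip to target
  tip_position_px: 50     # tip position along the propagation axis
  propagation_axis: col   # "col" (default) or "row"
  direction: 1            # +1 toward increasing pixel index
spray:                    # optional run metadata (kV, ul/min, ul, ug/ml, mOsm)
  voltage_kv: 3.0
  flow_rate_ul_min: 20
detection: {threshold_k: 4, pixel_cutoff: 10, polarity: both, refine: halfmax}
tracking:  {max_velocity_ms: 20, area_tol: 0.3, max_gap: 0, velocity_at: last}
focus:     {mode: sharpness, band: 0.4, z_max_mm: 0.25}
clustering: {k_range: [1, 6], restarts: 10, seed: 1, transform: log_volume}
volume_floor_pl: 4.2
inputs: [rep1.tif, rep2.tif, rep3.tif]   # multi-page TIFF or image directories
output_dir: out/
nominal_duration_s: 2
```

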