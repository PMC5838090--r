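# Shared fixtures: geometries, small rendered sequences, record samplers.

# the study's native acquisition geometry
full_geometry <- function() {
  acquisition_geometry(5.565, 3.366, 992, 600, 10000, 4, 50)
}

# reduced-height field at the native pixel calibration (fast to render)
strip_geometry <- function(height_px = 100) {
  acquisition_geometry(5.565, 5.565 / 992 * height_px, 992, height_px,
                       10000, 4, 50)
}

# a small square field for single-droplet scenes
tile_geometry <- function(side_px = 200, frame_rate = 10000, wd_mm = 0.8) {
  fov <- 5.6e-3 * side_px
  acquisition_geometry(fov, fov, side_px, side_px, frame_rate, wd_mm, 20)
}

# render a single droplet travelling through a tile; returns the spray_stack
render_single_droplet <- function(volume_nl = 1, velocity_ms = 3, z_mm = 0,
                                  geometry = tile_geometry(),
                                  settings = render_settings(rng_seed = 99),
                                  n_frames = NULL, seed = 1) {
  ens <- data.frame(droplet_id = "d00001", group = "g",
                    emission_s = 0, entry_lateral_mm = geometry$fov_height_mm / 2,
                    velocity_ms = velocity_ms, volume_nl = volume_nl,
                    z_offset_mm = z_mm, split_time_s = NA_real_,
                    split_share1 = NA_real_)
  class(ens) <- c("spray_ensemble", "data.frame")
  render_frames(ens, geometry, settings, n_frames = n_frames)
}

# hand-built ensemble rows (bypasses sampling; fields as in sample_ensemble)
manual_ensemble <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    df <- data.frame(droplet_id = character(0), group = character(0),
                     emission_s = numeric(0), entry_lateral_mm = numeric(0),
                     velocity_ms = numeric(0), volume_nl = numeric(0),
                     z_offset_mm = numeric(0), split_time_s = numeric(0),
                     split_share1 = numeric(0))
    class(df) <- c("spray_ensemble", "data.frame")
    return(df)
  }
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(droplet_id = sprintf("d%05d", i),
               group = r$group %||% "g",
               emission_s = r$emission_s %||% 0,
               entry_lateral_mm = r$entry_lateral_mm,
               velocity_ms = r$velocity_ms,
               volume_nl = r$volume_nl,
               z_offset_mm = r$z_offset_mm %||% 0,
               split_time_s = r$split_time_s %||% NA_real_,
               split_share1 = r$split_share1 %||% NA_real_)
  }))
  class(df) <- c("spray_ensemble", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# records drawn straight from group specifications (no rendering)
sample_records <- function(groups, counts, seed) {
  spraymode:::with_seed(seed, {
    do.call(rbind, lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      data.frame(
        trajectory_id = sprintf("g%d_%03d", i, seq_len(counts[i])),
        volume_nl = spraymode:::rlnorm_matched(counts[i], g$volume_mean_nl,
                                               g$volume_sd_nl),
        velocity_ms = spraymode:::rtruncnorm_pos(counts[i], g$velocity_mean_ms,
                                                 g$velocity_sd_ms),
        replicate_id = "r1", volume_flagged = FALSE)
    }))
  })
}
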