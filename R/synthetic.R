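# Synthetic spray-video generation: ground-truth droplet ensembles and their
# rendering into high-speed frame stacks. Every downstream stage (detection,
# linking, volumetry, clustering) is validated against these stacks.

#' Specification of one droplet population
#'
#' Describes one droplet group of a spray mode by the mean and standard
#' deviation of its droplet volumes and velocities, and the share of the total
#' delivered volume it carries.
#'
#' @param name Group label.
#' @param volume_mean_nl,volume_sd_nl Droplet volume mean and sd (nl).
#' @param velocity_mean_ms,velocity_sd_ms Droplet speed mean and sd (m/s).
#' @param volume_fraction Share of the total delivered volume in `[0, 1]`.
#' @return An object of class `"group_spec"`.
#' @export
group_spec <- function(name, volume_mean_nl, volume_sd_nl,
                       velocity_mean_ms, velocity_sd_ms, volume_fraction) {
  if (volume_mean_nl <= 0 || velocity_mean_ms <= 0)
    stop("group means must be strictly positive")
  if (volume_sd_nl < 0 || velocity_sd_ms < 0)
    stop("group standard deviations must be non-negative")
  if (volume_fraction < 0 || volume_fraction > 1)
    stop("volume_fraction must lie in [0, 1]")
  structure(list(name = as.character(name),
                 volume_mean_nl = volume_mean_nl, volume_sd_nl = volume_sd_nl,
                 velocity_mean_ms = velocity_mean_ms, velocity_sd_ms = velocity_sd_ms,
                 volume_fraction = volume_fraction),
            class = "group_spec")
}

#' Reference spray-mode populations of a sucrose-based electrospray
#'
#' Droplet group statistics characterized for a 370 mOsm sucrose-based medium
#' sprayed at a working distance of 4 mm and a flow rate of 20 ul/min, at
#' three applied voltages. Each condition lists, per group, the mean +/- sd of
#' droplet volume and impact velocity, the group volume and its fractional
#' contribution to the delivered volume. These are the default conditions of
#' the synthetic generator.
#'
#' @param voltage_kv One of 2.7, 3.0 or 3.3.
#' @return A list with `groups` (list of [group_spec()]), `group_volumes_nl`,
#'   `total_volume_nl` and `voltage_kv`.
#' @examples
#' ref <- reference_spray_groups(3.0)
#' sapply(ref$groups, `[[`, "volume_mean_nl")
#' @export
reference_spray_groups <- function(voltage_kv = 3.0) {
  key <- sprintf("%.1f", voltage_kv)
  tab <- switch(key,
    "2.7" = list(v = c(2.8, 12.9, 3.2),  v_sd = c(1.3, 3.9, 4.4),
                 V = c(1.1, 0.2, 9.9),   V_sd = c(1.1, 0.7, 4.2),
                 Vg = c(611, 107, 724)),
    "3.0" = list(v = c(2.9, 14.3), v_sd = c(1.3, 3.5),
                 V = c(1.4, 0.2),  V_sd = c(1.5, 0.4),
                 Vg = c(1040, 51)),
    "3.3" = list(v = c(3.1, 15.5), v_sd = c(0.9, 2.8),
                 V = c(1.4, 0.7),  V_sd = c(1.5, 0.8),
                 Vg = c(833, 179)),
    stop("no reference spray mode for ", voltage_kv, " kV (available: 2.7, 3.0, 3.3)"))
  total <- sum(tab$Vg)
  groups <- lapply(seq_along(tab$v), function(i)
    group_spec(paste0("group", i),
               volume_mean_nl = tab$V[i], volume_sd_nl = tab$V_sd[i],
               velocity_mean_ms = tab$v[i], velocity_sd_ms = tab$v_sd[i],
               volume_fraction = tab$Vg[i] / total))
  list(groups = groups, group_volumes_nl = tab$Vg,
       total_volume_nl = total, voltage_kv = voltage_kv)
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# normal truncated to (lower, Inf), matched to the untruncated mean/sd
rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# log-normal with the given arithmetic mean and sd
rlnorm_matched <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample a ground-truth droplet ensemble
#'
#' Draws droplets group by group until each group's cumulative volume reaches
#' its share of `total_volume_nl`. Volumes are log-normal (moment-matched to
#' the group mean/sd, guaranteeing positivity and the right skew typical of
#' spray droplets); speeds are normal truncated to positive values; emission
#' times are uniform on `[0, duration_s]` (steady-state spray); distances from
#' the focal plane are normal with sd `z_sd_mm`. A fraction `split_prob` of
#' droplets is scheduled to split in flight into two children whose volume
#' shares sum to one.
#'
#' @param groups List of [group_spec()]; volume fractions must sum to 1.
#' @param duration_s Emission window in seconds.
#' @param total_volume_nl Total delivered volume across all groups (nl).
#' @param geometry An [acquisition_geometry()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param z_sd_mm Sd of the distance from the focal plane (mm).
#' @param lateral_spread_mm Half-width of the uniform band of entry positions
#'   around the lateral image centre (mm).
#' @param split_prob Probability that a droplet splits in flight.
#' @return A data.frame of class `"spray_ensemble"`, one row per droplet:
#'   `droplet_id`, `group`, `emission_s`, `entry_lateral_mm`, `velocity_ms`,
#'   `volume_nl`, `z_offset_mm`, `split_time_s` (NA if none) and
#'   `split_share1` (volume share of the first child).
#' @examples
#' geom <- acquisition_geometry(5.565, 3.366, 992, 600, 10000, 4, 50)
#' ens <- sample_ensemble(reference_spray_groups(3.0)$groups, duration_s = 0.05,
#'                        total_volume_nl = 50, geometry = geom, seed = 1)
#' nrow(ens)
#' @export
sample_ensemble <- function(groups, duration_s, total_volume_nl, geometry, seed,
                            z_sd_mm = 0.12, lateral_spread_mm = 0.15,
                            split_prob = 0) {
  if (duration_s <= 0 || total_volume_nl <= 0)
    stop("duration and total volume must be strictly positive")
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, logical(1), "group_spec")))
  fr_sum <- sum(vapply(groups, `[[`, numeric(1), "volume_fraction"))
  if (abs(fr_sum - 1) > 1e-9)
    stop("group volume fractions must sum to 1 (got ", format(fr_sum), ")")

  with_seed(seed, {
    per_group <- lapply(groups, function(g) {
      target <- g$volume_fraction * total_volume_nl
      if (target == 0) return(NULL)
      vols <- numeric(0)
      while (sum(vols) < target) {
        need <- target - sum(vols)
        n_guess <- max(16L, ceiling(1.2 * need / g$volume_mean_nl))
        vols <- c(vols, rlnorm_matched(n_guess, g$volume_mean_nl, g$volume_sd_nl))
        if (length(vols) > 1e6)
          stop("volume target unreachable for group '", g$name, "'")
      }
      n <- which(cumsum(vols) >= target)[1]   # stop at the droplet crossing the target
      vols <- vols[seq_len(n)]
      data.frame(group = g$name, volume_nl = vols,
                 velocity_ms = rtruncnorm_pos(n, g$velocity_mean_ms, g$velocity_sd_ms))
    })
    out <- do.call(rbind, per_group)
    n <- nrow(out)
    out$droplet_id <- sprintf("d%05d", seq_len(n))
    out$emission_s <- stats::runif(n, 0, duration_s)
    lat_mid <- if (geometry$propagation_axis == "col")
      geometry$fov_height_mm / 2 else geometry$fov_width_mm / 2
    out$entry_lateral_mm <- lat_mid + stats::runif(n, -lateral_spread_mm, lateral_spread_mm)
    out$z_offset_mm <- stats::rnorm(n, 0, z_sd_mm)
    splits <- stats::runif(n) < split_prob
    axial_span <- axial_image_span_mm(geometry)
    cross_s <- axial_span / 1000 / out$velocity_ms
    out$split_time_s <- ifelse(splits,
                               out$emission_s + stats::runif(n, 0.15, 0.45) * cross_s,
                               NA_real_)
    out$split_share1 <- ifelse(splits, stats::runif(n, 0.3, 0.7), NA_real_)
    rownames(out) <- NULL
    out <- out[, c("droplet_id", "group", "emission_s", "entry_lateral_mm",
                   "velocity_ms", "volume_nl", "z_offset_mm",
                   "split_time_s", "split_share1")]
    class(out) <- c("spray_ensemble", "data.frame")
    out
  })
}

# axial extent of the image beyond the capillary tip, in mm
axial_image_span_mm <- function(geometry) {
  axis_len <- if (geometry$propagation_axis == "col")
    geometry$image_width else geometry$image_height
  edge_px <- if (geometry$direction > 0) axis_len else 1
  abs(axial_mm_from_px(edge_px, geometry))
}

#' Rendering settings for synthetic spray frames
#'
#' @param background_level Background grey level.
#' @param noise_sd Sd of the additive Gaussian pixel noise.
#' @param droplet_intensity Contrast of a droplet against the background; must
#'   exceed `3 * noise_sd` for a usable fixture.
#' @param aspect_ratio Axial-to-lateral droplet elongation (1 = spherical).
#' @param defocus_blur_scale Gaussian blur sd, in pixels, added per mm of
#'   distance from the focal plane.
#' @param base_blur_px In-focus optical blur sd in pixels.
#' @param bit_depth Bits per pixel (8 or 16).
#' @param polarity `"bright"` droplets on a dark background (default) or
#'   `"dark"` on bright, as in shadowgraphy.
#' @param split_lateral_speed_ms Lateral separation speed (m/s) given to the
#'   children of a splitting droplet (one child `+`, the other `-`).
#' @param rng_seed Seed for the rendering noise.
#' @return An object of class `"render_settings"`.
#' @export
render_settings <- function(background_level = 20, noise_sd = 6,
                            droplet_intensity = 120, aspect_ratio = 1,
                            defocus_blur_scale = 4, base_blur_px = 0.5,
                            bit_depth = 8, polarity = c("bright", "dark"),
                            split_lateral_speed_ms = 0.5, rng_seed = 1) {
  polarity <- match.arg(polarity)
  if (droplet_intensity <= 3 * noise_sd)
    stop("droplet_intensity must exceed 3 * noise_sd; weaker fixtures are unusable")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (aspect_ratio <= 0 || defocus_blur_scale < 0 || base_blur_px < 0 || noise_sd < 0)
    stop("invalid render settings")
  structure(list(background_level = background_level, noise_sd = noise_sd,
                 droplet_intensity = droplet_intensity, aspect_ratio = aspect_ratio,
                 defocus_blur_scale = defocus_blur_scale, base_blur_px = base_blur_px,
                 bit_depth = as.integer(bit_depth), polarity = polarity,
                 split_lateral_speed_ms = split_lateral_speed_ms,
                 rng_seed = as.integer(rng_seed)),
            class = "render_settings")
}

# expand an ensemble into renderable entities: parents up to their split, then
# two children carrying share * volume each, laterally separating
ensemble_entities <- function(ensemble, geometry, settings) {
  span_mm <- axial_image_span_mm(geometry)
  rows <- list()
  for (i in seq_len(nrow(ensemble))) {
    d <- ensemble[i, ]
    exit_s <- d$emission_s + span_mm / 1000 / d$velocity_ms
    if (is.na(d$split_time_s) || d$split_time_s >= exit_s) {
      rows[[length(rows) + 1L]] <- data.frame(
        entity_id = d$droplet_id, parent_id = NA_character_, group = d$group,
        volume_nl = d$volume_nl, velocity_ms = d$velocity_ms,
        start_s = d$emission_s, end_s = exit_s, start_axial_mm = 0,
        lateral_mm = d$entry_lateral_mm, lateral_speed_ms = 0,
        z_offset_mm = d$z_offset_mm)
    } else {
      split_axial <- (d$split_time_s - d$emission_s) * d$velocity_ms * 1000
      rows[[length(rows) + 1L]] <- data.frame(
        entity_id = d$droplet_id, parent_id = NA_character_, group = d$group,
        volume_nl = d$volume_nl, velocity_ms = d$velocity_ms,
        start_s = d$emission_s, end_s = d$split_time_s, start_axial_mm = 0,
        lateral_mm = d$entry_lateral_mm, lateral_speed_ms = 0,
        z_offset_mm = d$z_offset_mm)
      shares <- c(d$split_share1, 1 - d$split_share1)
      for (j in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity_id = paste0(d$droplet_id, ".", j), parent_id = d$droplet_id,
          group = d$group, volume_nl = shares[j] * d$volume_nl,
          velocity_ms = d$velocity_ms, start_s = d$split_time_s,
          end_s = d$emission_s + span_mm / 1000 / d$velocity_ms,
          start_axial_mm = split_axial, lateral_mm = d$entry_lateral_mm,
          lateral_speed_ms = c(1, -1)[j] * settings$split_lateral_speed_ms,
          z_offset_mm = d$z_offset_mm)
      }
    }
  }
  do.call(rbind, rows)
}

# projected ellipse semi-axes (axial, lateral) in um for a droplet volume
droplet_semi_axes_um <- function(volume_nl, aspect_ratio) {
  v_um3 <- volume_nl * 1e6                      # 1 nl = 1e6 um^3
  b <- (3 * v_um3 / (4 * pi * aspect_ratio))^(1 / 3)
  cbind(axial = aspect_ratio * b, lateral = b)
}

# per-entity per-frame ground truth positions (px) for frames 1..n_frames
entity_truth <- function(entities, geometry, settings, n_frames) {
  px <- pixel_size(geometry)
  fr <- geometry$frame_rate_hz
  ax <- droplet_semi_axes_um(entities$volume_nl, settings$aspect_ratio)
  out <- vector("list", nrow(entities))
  lat_len <- if (geometry$propagation_axis == "col")
    geometry$image_height else geometry$image_width
  for (i in seq_len(nrow(entities))) {
    e <- entities[i, ]
    j0 <- max(1L, ceiling(e$start_s * fr + 1))          # first frame with t >= start
    j1 <- min(n_frames, ceiling(e$end_s * fr + 1) - 1)  # last frame with t < end
    if (j1 < j0) { out[[i]] <- NULL; next }
    j <- j0:j1
    t <- (j - 1) / fr
    axial_mm <- e$start_axial_mm + (t - e$start_s) * e$velocity_ms * 1000
    lateral_mm <- e$lateral_mm + (t - e$start_s) * e$lateral_speed_ms * 1000
    axial_px <- px_from_axial_mm(axial_mm, geometry)
    lateral_px <- lateral_mm * 1000 / px
    keep <- lateral_px >= 1 & lateral_px <= lat_len
    if (!any(keep)) { out[[i]] <- NULL; next }
    if (geometry$propagation_axis == "col") {
      row_px <- lateral_px; col_px <- axial_px
    } else {
      row_px <- axial_px; col_px <- lateral_px
    }
    a_px <- unname(ax[i, "axial"]) / px; b_px <- unname(ax[i, "lateral"]) / px
    out[[i]] <- data.frame(
      droplet_id = e$entity_id, parent_id = e$parent_id, group = e$group,
      frame = j[keep], row_px = row_px[keep], col_px = col_px[keep],
      area_px = pi * a_px * b_px, axial_extent_px = 2 * a_px,
      volume_nl = e$volume_nl, velocity_ms = e$velocity_ms,
      z_offset_mm = e$z_offset_mm)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(
    droplet_id = character(), parent_id = character(), group = character(),
    frame = integer(), row_px = numeric(), col_px = numeric(),
    area_px = numeric(), axial_extent_px = numeric(), volume_nl = numeric(),
    velocity_ms = numeric(), z_offset_mm = numeric())
  res[order(res$frame, res$droplet_id), , drop = FALSE]
}

# separable Gaussian blur of a small patch (sd in px); returns same size.
# Convolution matrices are memoized per (size, sigma) since each droplet
# keeps its patch size and defocus along its whole flight.
blur_patch <- function(patch, sigma, cache = NULL) {
  if (sigma < 0.05) return(patch)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  toep <- function(n) {
    key <- sprintf("%d_%.4f", n, sigma)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    d <- outer(seq_len(n), seq_len(n), `-`)
    ki <- pmin(pmax(d + half + 1L, 1L), length(k))
    m <- k[ki]
    m[abs(d) > half] <- 0
    m <- matrix(m, n, n)
    if (!is.null(cache)) cache[[key]] <- m
    m
  }
  toep(nrow(patch)) %*% patch %*% toep(ncol(patch))
}

# render one frame (no noise / background): sum of droplet patches
render_droplet_layer <- function(truth_f, geometry, settings, kern_cache = NULL) {
  h <- geometry$image_height; w <- geometry$image_width
  layer <- matrix(0, h, w)
  if (nrow(truth_f) == 0) return(layer)
  px <- pixel_size(geometry)
  for (i in seq_len(nrow(truth_f))) {
    b <- truth_f[i, ]
    a_px <- b$axial_extent_px / 2
    b_px <- b$area_px / (pi * a_px)
    if (geometry$propagation_axis == "col") {
      sr <- b_px; sc <- a_px
    } else {
      sr <- a_px; sc <- b_px
    }
    if (2 * max(sr, sc) > min(h, w))
      stop("droplet larger than the image; refine the geometry or volumes")
    sigma <- sqrt(settings$base_blur_px^2 +
                  (settings$defocus_blur_scale * abs(b$z_offset_mm))^2)
    pad <- ceiling(3 * sigma) + 2L
    r0 <- floor(b$row_px - sr) - pad; r1 <- ceiling(b$row_px + sr) + pad
    c0 <- floor(b$col_px - sc) - pad; c1 <- ceiling(b$col_px + sc) + pad
    rr <- r0:r1; cc <- c0:c1
    inside <- outer(((rr - b$row_px) / sr)^2, ((cc - b$col_px) / sc)^2, `+`) <= 1
    patch <- settings$droplet_intensity * inside
    patch <- blur_patch(patch, sigma, kern_cache)
    rk <- rr >= 1 & rr <= h; ck <- cc >= 1 & cc <= w
    if (!any(rk) || !any(ck)) next
    layer[rr[rk], cc[ck]] <- layer[rr[rk], cc[ck]] + patch[rk, ck, drop = FALSE]
  }
  layer
}

#' Render a droplet ensemble into a synthetic high-speed frame stack
#'
#' Draws every droplet as a filled ellipse whose projected area matches its
#' volume under the ellipsoid-of-revolution volume model at the configured
#' aspect ratio, advected along the propagation axis by
#' `velocity / frame_rate` per frame. A scheduled split replaces the parent
#' ellipse by two children that conserve volume and separate laterally.
#' Droplets off the focal plane are Gaussian-blurred in proportion to their
#' distance from it; frames carry additive Gaussian noise and are quantized to
#' the configured bit depth. Droplets are advected until they leave the field
#' of view; the target surface is not modelled.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param geometry An [acquisition_geometry()].
#' @param settings A [render_settings()].
#' @param n_frames Number of frames; defaults to just enough for every droplet
#'   (faster than 0.25 m/s) to cross the field of view.
#' @param output `"array"` materializes the stack (height x width x frames);
#'   `"function"` returns a frame accessor `frames(i)` that renders frame `i`
#'   on demand (identical pixel values, constant memory).
#' @return An object of class `"spray_stack"`: list with `frames` (array or
#'   accessor function), `n_frames`, `geometry`, `settings` and `truth`, the
#'   per-droplet per-frame ground-truth table.
#' @examples
#' geom <- acquisition_geometry(1.12, 1.12, 200, 200, 10000, 0.8, 20)
#' ens <- sample_ensemble(list(group_spec("g", 0.1, 0, 3, 0, 1)),
#'                        duration_s = 0.002, total_volume_nl = 0.2,
#'                        geometry = geom, seed = 1, z_sd_mm = 0)
#' stk <- render_frames(ens, geom, render_settings())
#' dim(stk$frames)
#' @export
render_frames <- function(ensemble, geometry, settings = render_settings(),
                          n_frames = NULL, output = c("array", "function")) {
  output <- match.arg(output)
  stopifnot(inherits(settings, "render_settings"))
  fr <- geometry$frame_rate_hz
  entities <- if (nrow(ensemble) > 0)
    ensemble_entities(ensemble, geometry, settings)
  else NULL
  if (is.null(n_frames)) {
    if (is.null(entities) || nrow(entities) == 0) {
      n_frames <- 10L
    } else {
      slowest_s <- axial_image_span_mm(geometry) / 1000 / 0.25
      cap <- ceiling((max(ensemble$emission_s) + slowest_s) * fr) + 1
      n_frames <- min(ceiling(max(entities$end_s) * fr) + 1, cap)
    }
  }
  n_frames <- as.integer(n_frames)
  truth <- if (is.null(entities)) entity_truth(
    data.frame(), geometry, settings, n_frames)
  else entity_truth(entities, geometry, settings, n_frames)
  # fastest droplet must not cross the whole image within one frame
  if (nrow(truth) > 0) {
    max_step_px <- max(ensemble$velocity_ms) / fr * 1e6 / pixel_size(geometry)
    axis_len <- if (geometry$propagation_axis == "col")
      geometry$image_width else geometry$image_height
    if (max_step_px >= axis_len)
      stop("velocities not representable: displacement per frame exceeds the image extent")
  }
  truth_by_frame <- split(truth, factor(truth$frame, levels = seq_len(n_frames)))
  qmax <- 2^settings$bit_depth - 1
  sgn <- if (settings$polarity == "bright") 1 else -1
  base <- if (settings$polarity == "bright") settings$background_level else
    qmax - settings$background_level
  kern_cache <- new.env(parent = emptyenv())
  render_one <- function(i) {
    tf <- truth_by_frame[[i]]
    layer <- render_droplet_layer(tf, geometry, settings, kern_cache)
    with_seed(settings$rng_seed + i, {
      x <- round(base + sgn * layer +
                   stats::rnorm(length(layer), 0, settings$noise_sd))
      x[x < 0] <- 0
      x[x > qmax] <- qmax
      matrix(x, nrow(layer), ncol(layer))
    })
  }
  frames <- if (output == "array") {
    arr <- array(0, dim = c(geometry$image_height, geometry$image_width, n_frames))
    for (i in seq_len(n_frames)) arr[, , i] <- render_one(i)
    arr
  } else {
    render_one
  }
  structure(list(frames = frames, n_frames = n_frames, geometry = geometry,
                 settings = settings, truth = truth),
            class = "spray_stack")
}

#' @export
print.spray_stack <- function(x, ...) {
  cat(sprintf("Synthetic spray stack: %d frames of %d x %d px, %d droplet-frame truth rows\n",
              x$n_frames, x$geometry$image_height, x$geometry$image_width,
              nrow(x$truth)))
  invisible(x)
}
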