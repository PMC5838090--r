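# Readers and writers: TIFF stacks / image directories in, CSV and JSON out,
# YAML run configuration.

#' Read a high-speed image stack
#'
#' Accepts a multi-page TIFF file or a directory of single-frame images
#' (TIFF or PNG, lexicographic frame order). 8- and 16-bit greyscale frames
#' are returned at their native integer scale.
#'
#' @param path Path to a TIFF file or image directory.
#' @return A `height x width x n_frames` array.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such stack: ", path)
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      round(img * 255)                       # PNG is normalized; assume 8-bit
    } else {
      img <- tiff::readTIFF(f, as.is = TRUE)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    }
  }
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no frames found in ", path)
    lapply(files, read_one)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    lapply(pages, function(img) if (length(dim(img)) == 3) img[, , 1] else img)
  }
  if (length(frames) == 0) stop("empty stack: ", path)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed frame shapes in ", path)
  array(unlist(frames), dim = c(dims[1, 1], dims[2, 1], length(frames)))
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param frames A `spray_stack`, array, or frame accessor source.
#' @param path Output TIFF path.
#' @param bit_depth Bits per sample (8 or 16); taken from a `spray_stack`'s
#'   render settings when available.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, bit_depth = NULL) {
  if (inherits(frames, "spray_stack") && is.null(bit_depth))
    bit_depth <- frames$settings$bit_depth
  if (is.null(bit_depth)) bit_depth <- 8L
  src <- as_frame_source(frames)
  qmax <- 2^bit_depth - 1
  pages <- lapply(seq_len(src$n_frames), function(i) src$get(i) / qmax)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Write a synthetic fixture: frames, ground truth and provenance
#'
#' Persists a rendered [render_frames()] stack as `frames.tif`, its
#' ground-truth table as `truth.csv`, and the generation parameters as a
#' `params.json` sidecar.
#'
#' @param stack A `spray_stack`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spray_fixture <- function(stack, dir) {
  stopifnot(inherits(stack, "spray_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(stack, file.path(dir, "frames.tif"))
  utils::write.csv(stack$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  params <- c(stack$settings,
              list(n_frames = stack$n_frames,
                   geometry = unclass(stack$geometry)))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# default analysis settings; a YAML config overrides fields selectively
default_config <- function() {
  list(
    detection = list(threshold_k = 4, pixel_cutoff = 10, polarity = "both",
                     refine = "halfmax"),
    tracking = list(max_velocity_ms = 20, area_tol = 0.3, max_gap = 0,
                    velocity_at = "last"),
    focus = list(mode = "sharpness", band = 0.4, z_max_mm = 0.25),
    clustering = list(k_range = c(1, 6), restarts = 10, seed = 1,
                      transform = "log_volume"),
    volume_floor_pl = 4.2
  )
}

#' Read and validate a run configuration
#'
#' Loads a YAML (or JSON) configuration with the acquisition geometry,
#' optional spray parameters, analysis settings, input stack paths and
#' output directory. Numeric settings are validated against the
#' preconditions of the operations that consume them; see the README for the
#' full key reference.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated config list of class `"spray_config"` with a
#'   `geometry` element that is an [acquisition_geometry()].
#' @export
read_spray_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  build_spray_config(raw)
}

#' Build and validate a run configuration from a plain list
#'
#' The programmatic counterpart of [read_spray_config()]: merges the given
#' fields over the package defaults and validates them.
#'
#' @param raw A list with at least a `geometry` block.
#' @return A validated `spray_config` list.
#' @export
build_spray_config <- function(raw) {
  if (is.null(raw$geometry)) stop("configuration must contain a 'geometry' block")
  g <- raw$geometry
  geometry <- acquisition_geometry(
    fov_width_mm = g$fov_width_mm, fov_height_mm = g$fov_height_mm,
    image_width = g$image_width, image_height = g$image_height,
    frame_rate_hz = g$frame_rate_hz,
    working_distance_mm = g$working_distance_mm,
    tip_position_px = g$tip_position_px,
    propagation_axis = if (is.null(g$propagation_axis)) "col" else g$propagation_axis,
    direction = if (is.null(g$direction)) 1 else g$direction)
  cfg <- default_config()
  for (blk in c("detection", "tracking", "focus", "clustering"))
    for (key in names(raw[[blk]])) cfg[[blk]][[key]] <- raw[[blk]][[key]]
  if (!is.null(raw$volume_floor_pl)) cfg$volume_floor_pl <- raw$volume_floor_pl
  with(cfg, {
    stopifnot(detection$threshold_k > 0, detection$pixel_cutoff >= 1,
              tracking$max_velocity_ms > 0, tracking$area_tol >= 0,
              tracking$max_gap >= 0, focus$band > 0, focus$z_max_mm > 0,
              clustering$restarts >= 1, volume_floor_pl >= 0,
              length(clustering$k_range) >= 1)
  })
  spray <- if (!is.null(raw$spray))
    spray_parameters(raw$spray$voltage_kv, raw$spray$flow_rate_ul_min,
                     raw$spray$delivered_volume_ul %||% NA_real_,
                     raw$spray$plasmid_ug_ml %||% NA_real_,
                     raw$spray$osmolarity_mosm %||% NA_real_)
  else NULL
  structure(c(list(geometry = geometry, spray = spray,
                   inputs = raw$inputs, output_dir = raw$output_dir,
                   nominal_duration_s = raw$nominal_duration_s), cfg),
            class = "spray_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
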