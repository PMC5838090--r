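#' Acquisition geometry of a high-speed spray recording
#'
#' Bundles the optical and temporal calibration of one recording: field of
#' view, image size, frame rate, working distance (capillary tip to target),
#' the pixel position of the capillary tip along the propagation axis, and
#' which image axis droplets propagate along.
#'
#' The pixel sizes derived from the width and from the height of the field of
#' view must agree within 2% (near-square pixels); otherwise the configuration
#' is rejected.
#'
#' @param fov_width_mm,fov_height_mm Field of view in mm.
#' @param image_width,image_height Image size in pixels (width = columns).
#' @param frame_rate_hz Frame rate in Hz.
#' @param working_distance_mm Axial distance from capillary tip to target (mm).
#' @param tip_position_px Position of the capillary outlet, in pixels, along
#'   the propagation axis (column index if `propagation_axis = "col"`).
#' @param propagation_axis `"col"` if droplets travel along the image width
#'   (the default), `"row"` if along the height.
#' @param direction `+1` if droplets move toward increasing pixel index along
#'   the propagation axis, `-1` otherwise.
#'
#' @return An object of class `"acquisition_geometry"`.
#' @examples
#' geom <- acquisition_geometry(5.565, 3.366, 992, 600, 10000, 4, 50)
#' pixel_size(geom)
#' @export
acquisition_geometry <- function(fov_width_mm, fov_height_mm,
                                 image_width, image_height,
                                 frame_rate_hz, working_distance_mm,
                                 tip_position_px,
                                 propagation_axis = c("col", "row"),
                                 direction = 1) {
  propagation_axis <- match.arg(propagation_axis)
  num <- c(fov_width_mm = fov_width_mm, fov_height_mm = fov_height_mm,
           image_width = image_width, image_height = image_height,
           frame_rate_hz = frame_rate_hz,
           working_distance_mm = working_distance_mm)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all geometry lengths, pixel counts and the frame rate must be strictly positive")
  if (!direction %in% c(-1, 1)) stop("'direction' must be +1 or -1")
  axis_len <- if (propagation_axis == "col") image_width else image_height
  if (!is.finite(tip_position_px) || tip_position_px < 1 || tip_position_px > axis_len)
    stop("'tip_position_px' must lie inside the image along the propagation axis")
  geom <- structure(list(
    fov_width_mm = fov_width_mm, fov_height_mm = fov_height_mm,
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    frame_rate_hz = frame_rate_hz, working_distance_mm = working_distance_mm,
    tip_position_px = tip_position_px,
    propagation_axis = propagation_axis, direction = direction
  ), class = "acquisition_geometry")
  pixel_size(geom)  # enforces the 2% square-pixel gate
  geom
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("Acquisition geometry: %g x %g mm FOV, %d x %d px (%.2f um/px), %g Hz\n",
              x$fov_width_mm, x$fov_height_mm, x$image_width, x$image_height,
              pixel_size(x), x$frame_rate_hz))
  cat(sprintf("  working distance %g mm; tip at px %g along the %s axis (direction %+d)\n",
              x$working_distance_mm, x$tip_position_px, x$propagation_axis, x$direction))
  invisible(x)
}

#' Pixel size of a recording
#'
#' Mean of the width-derived and height-derived pixel sizes, in micrometres
#' per pixel. The two estimates must agree within 2%.
#'
#' @param geometry An [acquisition_geometry()].
#' @return Pixel size in um/pixel.
#' @examples
#' geom <- acquisition_geometry(5.565, 3.366, 992, 600, 10000, 4, 50)
#' pixel_size(geom)  # ~5.6 um/px
#' @export
pixel_size <- function(geometry) {
  pw <- 1000 * geometry$fov_width_mm / geometry$image_width
  ph <- 1000 * geometry$fov_height_mm / geometry$image_height
  if (abs(pw - ph) / mean(c(pw, ph)) > 0.02)
    stop(sprintf(paste0("width- and height-derived pixel sizes disagree by more than 2%% ",
                        "(%.4f vs %.4f um/px); check the field of view / image size"), pw, ph))
  mean(c(pw, ph))
}

#' Axial region of interest from the working distance
#'
#' The evaluation region covers 62.5% of the working distance, starting 25%
#' beyond the capillary tip and ending 12.5% ahead of the target.
#'
#' @param geometry An [acquisition_geometry()], or a single positive working
#'   distance in mm.
#' @return A list of class `"roi_bounds"` with `axial_start_mm` and
#'   `axial_end_mm`, both measured in mm beyond the capillary tip.
#' @examples
#' roi_from_geometry(acquisition_geometry(5.565, 3.366, 992, 600, 10000, 4, 50))
#' @export
roi_from_geometry <- function(geometry) {
  wd <- if (inherits(geometry, "acquisition_geometry")) geometry$working_distance_mm else geometry
  if (!is.numeric(wd) || length(wd) != 1 || !is.finite(wd) || wd <= 0)
    stop("working distance must be a single strictly positive length in mm")
  structure(list(axial_start_mm = 0.25 * wd, axial_end_mm = 0.875 * wd),
            class = "roi_bounds")
}

#' @export
print.roi_bounds <- function(x, ...) {
  cat(sprintf("ROI: %.3f mm to %.3f mm beyond the capillary tip\n",
              x$axial_start_mm, x$axial_end_mm))
  invisible(x)
}

#' Delivery time of a sprayed volume
#'
#' Time to deliver a volume at a constant flow rate, `t = V / (dV/dt)`.
#'
#' @param volume_ul Delivered volume in microlitres.
#' @param flow_rate_ul_min Flow rate in microlitres per minute.
#' @return Delivery time in seconds.
#' @examples
#' delivery_time(25, 20)  # 75 s
#' @export
delivery_time <- function(volume_ul, flow_rate_ul_min) {
  if (any(flow_rate_ul_min <= 0)) stop("flow rate must be strictly positive")
  if (any(volume_ul < 0)) stop("volume must be non-negative")
  60 * volume_ul / flow_rate_ul_min
}

#' Osmolarity of a sucrose solution
#'
#' Sucrose (molar mass 342.30 g/mol) does not dissociate in solution, so its
#' osmolarity equals its molarity.
#'
#' @param grams_per_100ml Sucrose concentration in g per 100 ml.
#' @return Osmolarity in mOsm/l.
#' @examples
#' sucrose_osmolarity(12.67)  # ~370 mOsm
#' @export
sucrose_osmolarity <- function(grams_per_100ml) {
  if (any(grams_per_100ml < 0)) stop("concentration must be non-negative")
  grams_per_100ml * 10 / 342.30 * 1000
}

#' Procedural spray parameters
#'
#' Run metadata for an electrospray delivery: applied voltage, flow rate,
#' delivered volume, plasmid concentration and medium osmolarity. These are
#' carried into result tables; they do not enter the image computations.
#'
#' @param voltage_kv Applied voltage between capillary and counter electrode (kV).
#' @param flow_rate_ul_min Flow rate (ul/min).
#' @param delivered_volume_ul Delivered volume (ul).
#' @param plasmid_ug_ml Plasmid concentration (ug/ml); optional.
#' @param osmolarity_mosm Medium osmolarity (mOsm); optional.
#' @return An object of class `"spray_parameters"`.
#' @examples
#' spray_parameters(3.0, 20, 25, 100, 370)
#' @export
spray_parameters <- function(voltage_kv, flow_rate_ul_min,
                             delivered_volume_ul = NA_real_,
                             plasmid_ug_ml = NA_real_,
                             osmolarity_mosm = NA_real_) {
  if (!is.finite(voltage_kv) || voltage_kv <= 0 ||
      !is.finite(flow_rate_ul_min) || flow_rate_ul_min <= 0)
    stop("voltage and flow rate must be strictly positive for an active spray")
  vals <- c(delivered_volume_ul, plasmid_ug_ml, osmolarity_mosm)
  if (any(vals < 0, na.rm = TRUE)) stop("spray parameters must be non-negative")
  structure(list(voltage_kv = voltage_kv, flow_rate_ul_min = flow_rate_ul_min,
                 delivered_volume_ul = delivered_volume_ul,
                 plasmid_ug_ml = plasmid_ug_ml,
                 osmolarity_mosm = osmolarity_mosm),
            class = "spray_parameters")
}

# axial coordinate (mm beyond the tip) of pixel positions along the
# propagation axis; `px` is a column index for "col" geometries, row for "row"
axial_mm_from_px <- function(px, geometry) {
  geometry$direction * (px - geometry$tip_position_px) * pixel_size(geometry) / 1000
}

# inverse of axial_mm_from_px
px_from_axial_mm <- function(mm, geometry) {
  geometry$tip_position_px + geometry$direction * mm * 1000 / pixel_size(geometry)
}
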