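#' Droplet volume model
#'
#' Converts the per-frame pixel measurements of a droplet image (projected
#' cross-sectional area and diameter along the propagation direction) into a
#' volume, assuming rotational symmetry of the droplet around its direction
#' of propagation. With `a` the semi-axis along propagation (half the measured
#' axial diameter) and `A` the projected area, the lateral semi-axis is
#' `b = A / (pi * a)` and the volume `V = 4/3 * pi * a * b^2`.
#'
#' @param pixel_size_um Pixel size in um/pixel.
#' @param floor_pl Lowest reliably resolvable volume in picolitres; droplet
#'   records at or below this floor are discarded downstream. Default 4.2 pl,
#'   the volume of a 10-pixel spherical droplet image at 5.6 um/pixel.
#' @return An object of class `"volume_model"`.
#' @examples
#' vm <- volume_model(5.6)
#' volume_from_projection(385, 22, vm)  # ~1000 pl = 1 nl
#' @export
volume_model <- function(pixel_size_um, floor_pl = 4.2) {
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel size must be strictly positive")
  if (!is.finite(floor_pl) || floor_pl < 0) stop("volume floor must be non-negative")
  structure(list(pixel_size_um = pixel_size_um, model = "ellipsoid-of-revolution",
                 floor_pl = floor_pl),
            class = "volume_model")
}

#' Droplet volume from its projected image
#'
#' Ellipsoid-of-revolution volume from a blob's pixel area and axial extent;
#' see [volume_model()] for the geometry. Vectorized over `area_px` and
#' `axial_extent_px`.
#'
#' A consistency flag is attached (attribute `"flagged"`) for measurements
#' whose implied aspect ratio is extreme (lateral semi-axis more than 10x the
#' axial one or vice versa), which usually indicates a segmentation artifact.
#'
#' @param area_px Projected cross-sectional area in pixels.
#' @param axial_extent_px Diameter along the propagation direction in pixels.
#' @param model A [volume_model()].
#' @return Volume(s) in picolitres (1 pl = 1000 um^3).
#' @examples
#' vm <- volume_model(1)
#' volume_from_projection(314.159, 20, vm)  # sphere r = 10 um -> ~4.19 pl
#' volume_from_projection(314.159, 40, vm)  # prolate 20 x 5 um -> ~2.09 pl
#' @export
volume_from_projection <- function(area_px, axial_extent_px, model) {
  stopifnot(inherits(model, "volume_model"))
  if (any(area_px < 1) || any(axial_extent_px < 1))
    stop("area and axial extent must each be at least one pixel")
  px <- model$pixel_size_um
  a <- axial_extent_px * px / 2          # um, semi-axis along propagation
  A <- area_px * px^2                    # um^2, projected area
  b <- A / (pi * a)                      # um, lateral semi-axis
  v_um3 <- 4 / 3 * pi * a * b^2
  v <- v_um3 / 1000                      # pl (1 pl = 1000 um^3)
  structure(v, flagged = (b > 10 * a) | (b < a / 10))
}

#' Detection-limit volume of a pixel-area cutoff
#'
#' The smallest droplet the detector can accept covers `pixel_cutoff` pixels.
#' This converts that area to a volume for a stated droplet shape: a sphere
#' (radius `r = sqrt(A/pi)`), or an ellipsoid of revolution with given
#' semi-axes `a` (axial) and `b` (lateral), which must satisfy
#' `pi * a * b = A` within 5%.
#'
#' @param pixel_cutoff Area cutoff in pixels (>= 1).
#' @param pixel_size_um Pixel size in um/pixel.
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param semi_axes_um For `shape = "ellipsoid"`, numeric `c(a, b)` in um.
#' @return Volume in picolitres.
#' @examples
#' detection_limit_volume(10, 5.6)                               # ~4.2 pl
#' detection_limit_volume(10, 5.6, "ellipsoid", c(20, 5))        # ~2.1 pl
#' @export
detection_limit_volume <- function(pixel_cutoff, pixel_size_um,
                                   shape = c("sphere", "ellipsoid"),
                                   semi_axes_um = NULL) {
  shape <- match.arg(shape)
  if (pixel_cutoff < 1) stop("pixel cutoff must be at least 1")
  if (pixel_size_um <= 0) stop("pixel size must be strictly positive")
  A <- pixel_cutoff * pixel_size_um^2    # um^2
  if (shape == "sphere") {
    r <- sqrt(A / pi)
    v_um3 <- 4 / 3 * pi * r^3
  } else {
    if (is.null(semi_axes_um) || length(semi_axes_um) != 2 || any(semi_axes_um <= 0))
      stop("ellipsoid shape needs semi_axes_um = c(a, b) in um")
    a <- semi_axes_um[1]; b <- semi_axes_um[2]
    if (abs(pi * a * b - A) / A > 0.05)
      stop(sprintf("ellipsoid axes imply a projected area of %.1f um^2, inconsistent with the %.1f um^2 cutoff area",
                   pi * a * b, A))
    v_um3 <- 4 / 3 * pi * a * b^2
  }
  v_um3 / 1000
}
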