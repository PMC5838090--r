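# Frame-to-frame trajectory linking with droplet-splitting support, the
# ROI-traversal and focal-range qualification filters, and conversion of
# qualified trajectories into droplet records (volume at first appearance,
# velocity at impact).

new_spray_trajectories <- function(observations, meta) {
  structure(list(observations = observations, meta = meta),
            class = "spray_trajectories")
}

#' @export
print.spray_trajectories <- function(x, ...) {
  nq <- sum(x$meta$qualified, na.rm = TRUE)
  cat(sprintf("%d trajectories (%d observations; %d split products; %s qualified)\n",
              nrow(x$meta), nrow(x$observations), sum(!is.na(x$meta$parent_id)),
              if (all(is.na(x$meta$qualified))) "not yet assessed" else nq))
  invisible(x)
}

# observations of one trajectory, ordered by frame
trajectory_obs <- function(trajectories, id) {
  o <- trajectories$observations
  o[o$trajectory_id == id, , drop = FALSE]
}

# subset a trajectory set to the given ids
filter_trajectories <- function(trajectories, keep_ids) {
  new_spray_trajectories(
    trajectories$observations[trajectories$observations$trajectory_id %in% keep_ids, ,
                              drop = FALSE],
    trajectories$meta[trajectories$meta$trajectory_id %in% keep_ids, , drop = FALSE])
}

# axial centroid coordinate (px along propagation axis) of blob rows
blob_axial_px <- function(blobs, geometry) {
  if (geometry$propagation_axis == "col") blobs$col else blobs$row
}

#' Link per-frame blobs into droplet trajectories
#'
#' Greedy nearest-neighbour assignment from each frame to the next within a
#' gating radius of `max_velocity / frame_rate` (converted to pixels),
#' forbidding backward axial motion beyond 1 pixel. For a track with at
#' least two observations the neighbour distance is measured from the
#' constant-velocity prediction of its next position (standard particle
#' tracking practice; new tracks fall back to the last observed position),
#' which disambiguates crossing and newly emitted droplets; the gating
#' radius itself always constrains the raw displacement. Ties are broken by
#' smallest distance, then smallest area difference. Droplet
#' splitting is handled: when at least two blobs of the next frame fall
#' inside one parent's gate and their summed area does not exceed the
#' parent's area by more than `area_tol` (area conservation as the proxy for
#' volume conservation), the parent trajectory ends and the children start
#' with their `parent_id` set. Unassigned blobs start new trajectories.
#'
#' @param blobs A blob table from [detect_stack()] (`frame`, `row`, `col`,
#'   `area_px`, `axial_extent_px`, `sharpness`).
#' @param geometry An [acquisition_geometry()].
#' @param max_velocity_ms Largest trackable droplet speed (m/s, default 20).
#' @param area_tol Relative tolerance of the split area-conservation check.
#' @param max_gap Largest number of missed frames bridged (default 0: a
#'   trajectory ends as soon as a frame has no match).
#' @param accel_tol Fraction of the gating radius an established track's
#'   observation may deviate from its constant-velocity prediction (frame-to-
#'   frame speed changes are small at high frame rates).
#' @param replicate_id Label of the source sequence, carried into records.
#' @return An object of class `"spray_trajectories"`: a list with
#'   `observations` (blob table plus `trajectory_id`) and `meta`
#'   (`trajectory_id`, `parent_id`, `qualified`, `replicate_id`).
#' @export
link_trajectories <- function(blobs, geometry, max_velocity_ms = 20,
                              area_tol = 0.3, max_gap = 0, accel_tol = 0.35,
                              replicate_id = "r1") {
  if (max_velocity_ms <= 0) stop("max_velocity_ms must be strictly positive")
  obs_cols <- c("frame", "row", "col", "area_px", "axial_extent_px",
                "lateral_extent_px", "sharpness")
  empty <- new_spray_trajectories(
    cbind(data.frame(trajectory_id = character(0)),
          blobs[0, intersect(obs_cols, names(blobs)), drop = FALSE]),
    data.frame(trajectory_id = character(0), parent_id = character(0),
               qualified = logical(0), replicate_id = character(0)))
  if (is.null(blobs) || nrow(blobs) == 0) return(empty)
  blobs <- blobs[order(blobs$frame), , drop = FALSE]
  gate_px <- max_velocity_ms / geometry$frame_rate_hz * 1e6 / pixel_size(geometry)

  n_tracks <- 0L
  track_rows <- list()        # per track: integer vector of blob row indices
  track_parent <- character(0)
  track_last_frame <- integer(0)
  new_track <- function(blob_row, parent = NA_character_) {
    n_tracks <<- n_tracks + 1L
    track_rows[[n_tracks]] <<- blob_row
    track_parent[n_tracks] <<- parent
    track_last_frame[n_tracks] <<- blobs$frame[blob_row]
    n_tracks
  }

  frames <- sort(unique(blobs$frame))
  by_frame <- split(seq_len(nrow(blobs)), blobs$frame)
  for (f in frames) {
    rows_f <- by_frame[[as.character(f)]]
    heads <- which(track_last_frame >= f - 1 - max_gap & track_last_frame < f)
    if (length(heads) == 0) {
      for (b in rows_f) new_track(b)
      next
    }
    head_last <- vapply(heads, function(h) track_rows[[h]][length(track_rows[[h]])], 0L)
    hx <- blobs$row[head_last]; hy <- blobs$col[head_last]
    ha <- blobs$area_px[head_last]
    hax <- blob_axial_px(blobs[head_last, , drop = FALSE], geometry)
    # constant-velocity prediction for established tracks; a track whose
    # predicted centre lies outside the image has left the field of view and
    # must not capture another droplet's blob
    px_pred <- hx; py_pred <- hy
    established <- logical(length(heads))
    pred_exited <- logical(length(heads))
    axis_len <- if (geometry$propagation_axis == "col")
      geometry$image_width else geometry$image_height
    for (hi in seq_along(heads)) {
      rows_h <- track_rows[[heads[hi]]]
      if (length(rows_h) >= 2) {
        established[hi] <- TRUE
        prev <- rows_h[length(rows_h) - 1L]
        dt_h <- blobs$frame[head_last[hi]] - blobs$frame[prev]
        step <- (f - track_last_frame[heads[hi]]) / dt_h
        px_pred[hi] <- hx[hi] + step * (blobs$row[head_last[hi]] - blobs$row[prev])
        py_pred[hi] <- hy[hi] + step * (blobs$col[head_last[hi]] - blobs$col[prev])
        pred_ax <- if (geometry$propagation_axis == "col") py_pred[hi] else px_pred[hi]
        pred_exited[hi] <- pred_ax < 1 || pred_ax > axis_len
      }
    }
    bx <- blobs$row[rows_f]; by <- blobs$col[rows_f]
    ba <- blobs$area_px[rows_f]
    bax <- blob_axial_px(blobs[rows_f, , drop = FALSE], geometry)
    elapsed <- f - track_last_frame[heads]
    disp <- sqrt(outer(hx, bx, `-`)^2 + outer(hy, by, `-`)^2)
    dist <- sqrt(outer(px_pred, bx, `-`)^2 + outer(py_pred, by, `-`)^2)
    forward <- geometry$direction * outer(hax, bax, function(a, b) b - a) >= -1
    gated <- disp <= gate_px * elapsed & forward
    # established tracks must also be found near their prediction (droplet
    # speed barely changes between frames at 10 kHz)
    accel_gate <- pmax(5, accel_tol * gate_px) * elapsed
    gated[established, ] <- gated[established, , drop = FALSE] &
      (dist[established, , drop = FALSE] <= accel_gate[established])
    gated[pred_exited, ] <- FALSE

    # greedy one-to-one assignment by (distance, |area difference|)
    cand <- which(gated, arr.ind = TRUE)
    assign_head <- rep(NA_integer_, length(heads))   # blob row index per head
    blob_used <- rep(FALSE, length(rows_f))
    if (nrow(cand) > 0) {
      adiff <- abs(ha[cand[, 1]] - ba[cand[, 2]])
      ord <- order(dist[cand], adiff)
      for (ci in ord) {
        hi <- cand[ci, 1]; bi <- cand[ci, 2]
        if (is.na(assign_head[hi]) && !blob_used[bi]) {
          assign_head[hi] <- bi
          blob_used[bi] <- TRUE
        }
      }
    }

    # split detection: candidate children are the blob assigned to the head
    # plus any still-unassigned blobs in its gate
    split_children <- vector("list", length(heads))
    for (hi in seq_along(heads)) {
      in_gate <- which(gated[hi, ] & !blob_used)
      cand_children <- c(assign_head[hi], in_gate)
      cand_children <- cand_children[!is.na(cand_children)]
      # a genuine split conserves area and every child is distinctly smaller
      # than the parent; a continuation next to a bystander blob is not one
      if (length(cand_children) >= 2 &&
          sum(ba[cand_children]) <= ha[hi] * (1 + area_tol) &&
          all(ba[cand_children] <= 0.9 * ha[hi])) {
        split_children[[hi]] <- cand_children
        blob_used[cand_children] <- TRUE
        assign_head[hi] <- NA_integer_
      }
    }

    for (hi in seq_along(heads)) {
      h <- heads[hi]
      if (!is.null(split_children[[hi]])) {
        parent_label <- sprintf("t%05d", h)
        for (bi in split_children[[hi]]) new_track(rows_f[bi], parent = parent_label)
      } else if (!is.na(assign_head[hi])) {
        track_rows[[h]] <- c(track_rows[[h]], rows_f[assign_head[hi]])
        track_last_frame[h] <- f
      }
    }
    for (bi in which(!blob_used)) new_track(rows_f[bi])
  }

  ids <- sprintf("t%05d", seq_len(n_tracks))
  obs <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    o <- blobs[track_rows[[i]], intersect(obs_cols, names(blobs)), drop = FALSE]
    cbind(data.frame(trajectory_id = ids[i]), o)
  }))
  rownames(obs) <- NULL
  meta <- data.frame(trajectory_id = ids, parent_id = track_parent,
                     qualified = NA, replicate_id = replicate_id)
  new_spray_trajectories(obs, meta)
}

# per-trajectory first/last axial positions in mm beyond the tip
trajectory_axial_range <- function(trajectories, geometry) {
  o <- trajectories$observations
  ax <- axial_mm_from_px(blob_axial_px(o, geometry), geometry)
  first <- tapply(ax, o$trajectory_id, function(x) x[1])
  last <- tapply(ax, o$trajectory_id, function(x) x[length(x)])
  data.frame(trajectory_id = names(first),
             first_axial_mm = as.numeric(first),
             last_axial_mm = as.numeric(last))
}

#' Qualify trajectories by ROI traversal
#'
#' A droplet is evaluated only if its first appearance lies ahead of the ROI
#' and its last appearance beyond it (strict inequalities). Split children
#' inherit the entry position of their ultimate parent for the entry test, so
#' a droplet born inside the ROI from a parent that entered ahead of it still
#' qualifies if it leaves the ROI.
#'
#' @param trajectories A [link_trajectories()] result.
#' @param roi An `roi_bounds` object from [roi_from_geometry()].
#' @param geometry An [acquisition_geometry()].
#' @return The trajectory set with the `qualified` flag set in `meta`.
#' @export
roi_filter <- function(trajectories, roi, geometry) {
  meta <- trajectories$meta
  if (nrow(meta) == 0) return(trajectories)
  rng <- trajectory_axial_range(trajectories, geometry)
  rng <- rng[match(meta$trajectory_id, rng$trajectory_id), ]
  entry <- rng$first_axial_mm
  # walk each split chain up to its root for the inherited entry position
  root <- meta$trajectory_id
  parent <- meta$parent_id[match(root, meta$trajectory_id)]
  while (any(!is.na(parent))) {
    root <- ifelse(is.na(parent), root, parent)
    parent <- meta$parent_id[match(root, meta$trajectory_id)]
  }
  entry_root <- rng$first_axial_mm[match(root, rng$trajectory_id)]
  entry <- ifelse(is.na(entry_root), entry, entry_root)
  meta$qualified <- entry < roi$axial_start_mm & rng$last_axial_mm > roi$axial_end_mm
  new_spray_trajectories(trajectories$observations, meta)
}

#' Filter trajectories by focal range
#'
#' The focal criterion keeps only droplets that stay close to the focal plane
#' throughout their flight. In `"sharpness"` mode (usable on real recordings)
#' a trajectory is kept when its median boundary sharpness lies within
#' `band` (relative) of the sequence's in-focus reference sharpness, taken
#' as the 95th percentile of all blob sharpness values (the median over the
#' trajectory makes the criterion robust to single noisy observations). In `"exact"`
#' mode (synthetic data only) the trajectory is matched to the ground truth
#' and kept when its droplet's distance from the focal plane is at most
#' `z_max_mm` (default 0.25 mm, i.e. a focal range of 0.5 mm).
#'
#' @param trajectories A [link_trajectories()] result.
#' @param band Relative sharpness tolerance (default 0.4).
#' @param mode `"sharpness"` or `"exact"`.
#' @param truth Ground-truth table of a `spray_stack` (for `"exact"`).
#' @param z_max_mm Focal half-range for `"exact"` mode.
#' @return The trajectory set restricted to in-focus trajectories.
#' @export
focal_filter <- function(trajectories, band = 0.4,
                         mode = c("sharpness", "exact"),
                         truth = NULL, z_max_mm = 0.25) {
  mode <- match.arg(mode)
  meta <- trajectories$meta
  if (nrow(meta) == 0) return(trajectories)
  o <- trajectories$observations
  if (mode == "sharpness") {
    ref <- stats::quantile(o$sharpness, 0.95, names = FALSE)
    # the median over the trajectory is robust to single noisy observations
    ok <- tapply(o$sharpness, o$trajectory_id,
                 function(sh) {
                   m <- stats::median(sh)
                   m >= (1 - band) * ref & m <= (1 + band) * ref
                 })
    keep <- names(ok)[as.logical(ok)]
  } else {
    if (is.null(truth)) stop("'exact' mode needs the ground-truth table")
    keep <- character(0)
    for (id in meta$trajectory_id) {
      oo <- o[o$trajectory_id == id, , drop = FALSE]
      tt <- truth[truth$frame == oo$frame[1], , drop = FALSE]
      if (nrow(tt) == 0) next
      d2 <- (tt$row_px - oo$row[1])^2 + (tt$col_px - oo$col[1])^2
      if (abs(tt$z_offset_mm[which.min(d2)]) <= z_max_mm) keep <- c(keep, id)
    }
  }
  filter_trajectories(trajectories, keep)
}

#' Impact velocity of a trajectory
#'
#' Droplet speed at target impact: the Euclidean centroid displacement
#' between the last two observations, scaled by the pixel size and frame
#' rate.
#'
#' @param observations Observation table of a single trajectory, ordered by
#'   frame (e.g. one trajectory's rows of `trajectories$observations`).
#' @param geometry An [acquisition_geometry()].
#' @return Speed in m/s.
#' @examples
#' # a displacement of 53.57 px at 5.6 um/px and 10 kHz is 3.0 m/s
#' @export
impact_velocity <- function(observations, geometry) {
  n <- nrow(observations)
  if (n < 2) stop("impact velocity needs at least two observations")
  dr <- observations$row[n] - observations$row[n - 1]
  dc <- observations$col[n] - observations$col[n - 1]
  dt <- (observations$frame[n] - observations$frame[n - 1]) / geometry$frame_rate_hz
  sqrt(dr^2 + dc^2) * pixel_size(geometry) * 1e-6 / dt
}

#' Evaluate qualified trajectories into droplet records
#'
#' One record per qualified trajectory with at least two observations: the
#' volume is estimated at the droplet's first appearance (where droplets are
#' close to the focal plane) under the ellipsoid-of-revolution model, the
#' velocity from the last two frames ([impact_velocity()]). Records outside
#' the reliable evaluation window are dropped: volumes at or below the
#' resolution floor (default 4.2 pl) and velocities of zero or above the
#' largest trackable speed (default 20 m/s).
#'
#' Near the emission point a droplet image can momentarily merge with a
#' neighbour's; such a blob is not an ellipse and its axial extent corrupts
#' the volume. When the first observation's fill ratio (pixel area over the
#' area of the ellipse spanned by its axial and lateral extents) is below
#' 0.75, the volume is taken from the earliest observation with a consistent
#' fill ratio instead (falling back to the first if none is).
#'
#' @param trajectories A qualified trajectory set ([roi_filter()] /
#'   [focal_filter()] output).
#' @param geometry An [acquisition_geometry()].
#' @param model A [volume_model()]; defaults to the geometry's pixel size
#'   with a 4.2 pl floor.
#' @param max_velocity_ms Largest trackable speed (m/s).
#' @param velocity_at `"last"` uses the last two observations of the
#'   trajectory; `"roi_exit"` clips the trajectory at the ROI exit first
#'   (then `roi` must be given).
#' @param roi `roi_bounds`, required for `velocity_at = "roi_exit"`.
#' @return A data.frame of droplet records: `trajectory_id`, `volume_nl`,
#'   `velocity_ms`, `replicate_id`, `volume_flagged`.
#' @export
make_records <- function(trajectories, geometry, model = NULL,
                         max_velocity_ms = 20,
                         velocity_at = c("last", "roi_exit"), roi = NULL) {
  velocity_at <- match.arg(velocity_at)
  if (is.null(model)) model <- volume_model(pixel_size(geometry))
  meta <- trajectories$meta
  keep <- meta$trajectory_id[!is.na(meta$qualified) & meta$qualified]
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    oo <- trajectory_obs(trajectories, keep[i])
    if (nrow(oo) < 2) next
    # volume at the first appearance, unless that observation is shape- or
    # size-inconsistent with the rest of the track (transient merge with a
    # neighbouring droplet image, or a cross-droplet first link)
    fill_ok <- if (!is.null(oo$lateral_extent_px))
      oo$area_px / (pi / 4 * oo$axial_extent_px * oo$lateral_extent_px) >= 0.75
    else rep(TRUE, nrow(oo))
    area_ok <- {
      med <- stats::median(oo$area_px)
      oo$area_px >= 0.6 * med & oo$area_px <= 5 / 3 * med
    }
    vol_obs <- if (any(fill_ok & area_ok)) which(fill_ok & area_ok)[1]
    else if (any(fill_ok)) which(fill_ok)[1] else 1L
    v_pl <- volume_from_projection(oo$area_px[vol_obs], oo$axial_extent_px[vol_obs],
                                   model)
    vel_obs <- oo
    if (velocity_at == "roi_exit") {
      if (is.null(roi)) stop("velocity_at = 'roi_exit' needs the ROI bounds")
      ax <- axial_mm_from_px(blob_axial_px(oo, geometry), geometry)
      inside <- which(ax <= roi$axial_end_mm)
      if (length(inside) >= 2) vel_obs <- oo[inside, , drop = FALSE]
    }
    vel <- impact_velocity(vel_obs, geometry)
    if (vel <= 0 || vel > max_velocity_ms) next
    if (v_pl <= model$floor_pl) next
    out[[i]] <- data.frame(
      trajectory_id = keep[i], volume_nl = as.numeric(v_pl) / 1000,
      velocity_ms = vel,
      replicate_id = meta$replicate_id[match(keep[i], meta$trajectory_id)],
      volume_flagged = as.logical(attr(v_pl, "flagged")))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(trajectory_id = character(0), volume_nl = numeric(0),
                      velocity_ms = numeric(0), replicate_id = character(0),
                      volume_flagged = logical(0))
  rownames(res) <- NULL
  res
}
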