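# Per-frame droplet segmentation: temporal-median background, adaptive
# thresholding, 8-connected components, and the per-blob measurements the
# tracker and volumeter consume.

# normalize the many acceptable stack representations to a frame accessor
as_frame_source <- function(frames, n_frames = NULL) {
  if (is.list(frames) && !inherits(frames, "spray_stack") && is.function(frames$get))
    return(frames)
  if (inherits(frames, "spray_stack")) {
    src <- as_frame_source(frames$frames, frames$n_frames)
    return(src)
  }
  if (is.array(frames) && length(dim(frames)) == 3) {
    d <- dim(frames)
    return(list(get = function(i) frames[, , i], n_frames = d[3],
                height = d[1], width = d[2]))
  }
  if (is.function(frames)) {
    if (is.null(n_frames)) stop("a frame-accessor function needs 'n_frames'")
    f1 <- frames(1)
    return(list(get = frames, n_frames = as.integer(n_frames),
                height = nrow(f1), width = ncol(f1)))
  }
  stop("unsupported frame stack representation")
}

#' Estimate the static background of a frame stack
#'
#' Per-pixel temporal median over an evenly spaced subsample of frames.
#' Droplets are transient, so pixels they occupy in fewer than half of the
#' sampled frames fall back to the true background level.
#'
#' @param frames A `spray_stack`, a `height x width x n` array, or a frame
#'   accessor function (then pass `n_frames`).
#' @param n_sample Number of frames in the subsample (default 40, or all
#'   frames if fewer).
#' @param n_frames Stack length when `frames` is a function.
#' @return A background image (matrix).
#' @export
estimate_background <- function(frames, n_sample = 40, n_frames = NULL) {
  src <- as_frame_source(frames, n_frames)
  if (src$n_frames < 10)
    stop("background estimation needs at least 10 frames")
  pick <- unique(round(seq(1, src$n_frames, length.out = min(n_sample, src$n_frames))))
  sub <- vapply(pick, function(i) as.numeric(src$get(i)),
                numeric(src$height * src$width))
  med <- apply(sub, 1, stats::median)
  matrix(med, src$height, src$width)
}

# 8-connected component labels for foreground pixels given by sorted linear
# indices `idx` of an nr x nc image; returns small-integer labels per pixel.
# Classic run-length strategy: vertical pixel runs within each column are
# atomic; runs in adjacent columns whose row ranges come within one pixel of
# each other are united (union-find over runs).
label_components8 <- function(idx, nr, npx) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  col <- (idx - 1L) %/% nr
  row <- (idx - 1L) %% nr
  newrun <- c(TRUE, diff(idx) != 1L | diff(col) != 0L)
  run <- cumsum(newrun)
  nruns <- run[n]
  starts <- which(newrun)
  ends <- c(starts[-1] - 1L, n)
  r1 <- row[starts]; r2 <- row[ends]; rcol <- col[starts]
  parent <- seq_len(nruns)
  findroot <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  by_col <- split(seq_len(nruns), rcol)
  cols_present <- as.integer(names(by_col))
  for (ci in seq_along(cols_present)) {
    cj <- match(cols_present[ci] + 1L, cols_present)
    if (is.na(cj)) next
    a <- by_col[[ci]]; b <- by_col[[cj]]
    ia <- 1L; ib <- 1L
    while (ia <= length(a) && ib <= length(b)) {
      ra <- a[ia]; rb <- b[ib]
      if (r2[ra] + 1L < r1[rb]) { ia <- ia + 1L }
      else if (r2[rb] + 1L < r1[ra]) { ib <- ib + 1L }
      else {                          # row ranges touch under 8-connectivity
        pa <- findroot(ra); pb <- findroot(rb)
        if (pa != pb) parent[max(pa, pb)] <- min(pa, pb)
        if (r2[ra] <= r2[rb]) ia <- ia + 1L else ib <- ib + 1L
      }
    }
  }
  roots <- vapply(seq_len(nruns), findroot, 0L)
  match(roots, unique(roots))[run]
}

#' Detect droplet blobs in one frame
#'
#' Segments the background-subtracted frame at an adaptive threshold of
#' `threshold_k` times the robust noise sd (MAD) of the difference image,
#' labels 8-connected components, and discards components smaller than
#' `pixel_cutoff` pixels. For each surviving blob it measures the
#' intensity-weighted sub-pixel centroid, pixel area, extent along the
#' propagation axis, and a focus proxy: the mean gradient magnitude on the
#' blob boundary.
#'
#' By default (`refine = "halfmax"`) area, axial extent and centroid are
#' measured on the pixels at or above half of the blob's peak
#' background-subtracted intensity, which makes the area estimate independent
#' of the threshold height (the full-width-at-half-maximum convention); with
#' `refine = "none"` they are measured on the raw thresholded component.
#'
#' @param frame Frame matrix.
#' @param background Background image from [estimate_background()] (or a
#'   scalar level).
#' @param geometry An [acquisition_geometry()].
#' @param threshold_k Threshold in units of the robust noise sd (default 4).
#' @param pixel_cutoff Minimum blob area in pixels (default 10).
#' @param polarity Sign of droplet contrast to segment: `"both"` uses the
#'   absolute difference, `"bright"`/`"dark"` only one sign.
#' @param refine Blob measurement refinement, see above.
#' @param noise_sd Robust noise sd of the difference image; estimated from
#'   the frame itself (MAD) when `NULL`. [detect_stack()] estimates it once
#'   per sequence, the noise being stationary.
#' @return A data.frame with one row per blob: `row`, `col` (sub-pixel
#'   centroid), `area_px`, `axial_extent_px`, `lateral_extent_px`,
#'   `sharpness`, `peak`.
#' @export
detect_blobs <- function(frame, background, geometry, threshold_k = 4,
                         pixel_cutoff = 10, polarity = c("both", "bright", "dark"),
                         refine = c("halfmax", "none"), noise_sd = NULL) {
  polarity <- match.arg(polarity)
  refine <- match.arg(refine)
  if (length(background) > 1 && !all(dim(frame) == dim(background)))
    stop("frame and background must have the same shape")
  if (pixel_cutoff < 1) stop("pixel_cutoff must be at least 1")
  d <- frame - background
  s <- switch(polarity, both = abs(d), bright = pmax(d, 0), dark = pmax(-d, 0))
  sigma <- if (is.null(noise_sd)) stats::mad(d) else noise_sd
  if (sigma == 0) sigma <- stats::sd(d)
  empty <- data.frame(row = numeric(0), col = numeric(0), area_px = numeric(0),
                      axial_extent_px = numeric(0), lateral_extent_px = numeric(0),
                      sharpness = numeric(0), peak = numeric(0))
  if (!is.finite(sigma) || sigma == 0) return(empty)
  idx <- which(s > threshold_k * sigma)
  if (length(idx) == 0) return(empty)
  nr <- nrow(frame)
  lab <- label_components8(idx, nr, length(frame))
  # drop coarse components that cannot reach the cutoff
  sizes <- tabulate(lab)
  keep_lab <- which(sizes >= pixel_cutoff)
  if (length(keep_lab) == 0) return(empty)
  rows_all <- ((idx - 1L) %% nr) + 1L
  cols_all <- ((idx - 1L) %/% nr) + 1L
  sv <- s[idx]
  groups <- split(seq_along(idx), lab)[as.character(keep_lab)]
  inmask <- logical(length(frame))     # reusable membership mask for sharpness
  n_max <- length(keep_lab)
  o_row <- o_col <- o_area <- o_ax <- o_lat <- o_sharp <- o_peak <- numeric(n_max)
  nb <- 0L
  axis_is_col <- geometry$propagation_axis == "col"
  for (j in seq_len(n_max)) {
    sel <- groups[[j]]
    pk <- max(sv[sel])
    if (refine == "halfmax") sel <- sel[sv[sel] >= 0.5 * pk]
    if (length(sel) < pixel_cutoff) next
    rr <- rows_all[sel]; cc <- cols_all[sel]; wts <- sv[sel]
    nb <- nb + 1L
    o_row[nb] <- sum(rr * wts) / sum(wts)
    o_col[nb] <- sum(cc * wts) / sum(wts)
    o_area[nb] <- length(sel)
    ext_c <- diff(range(cc)) + 1; ext_r <- diff(range(rr)) + 1
    o_ax[nb] <- if (axis_is_col) ext_c else ext_r
    o_lat[nb] <- if (axis_is_col) ext_r else ext_c
    o_sharp[nb] <- blob_sharpness(s, rr, cc, nr, inmask)
    o_peak[nb] <- pk
  }
  if (nb == 0) return(empty)
  keep <- seq_len(nb)
  data.frame(row = o_row[keep], col = o_col[keep], area_px = o_area[keep],
             axial_extent_px = o_ax[keep], lateral_extent_px = o_lat[keep],
             sharpness = o_sharp[keep], peak = o_peak[keep])
}

# mean gradient magnitude (central differences of the contrast image) over
# the blob's boundary pixels (those with a 4-neighbour outside the blob);
# `inmask` is a reusable full-image logical scratch vector
blob_sharpness <- function(s, rr, cc, nr, inmask = NULL) {
  nc <- ncol(s)
  key <- (cc - 1L) * nr + rr
  if (is.null(inmask)) inmask <- logical(nr * nc)
  inmask[key] <- TRUE
  inset <- function(r2, c2) inmask[(c2 - 1L) * nr + r2]
  boundary <- !(inset(pmax(rr - 1, 1), cc) & inset(pmin(rr + 1, nr), cc) &
                inset(rr, pmax(cc - 1, 1)) & inset(rr, pmin(cc + 1, nc)))
  inmask[key] <- FALSE                  # reset the scratch for the next blob
  rb <- rr[boundary]; cb <- cc[boundary]
  gx <- (s[cbind(rb, pmin(cb + 1, nc))] - s[cbind(rb, pmax(cb - 1, 1))]) / 2
  gy <- (s[cbind(pmin(rb + 1, nr), cb)] - s[cbind(pmax(rb - 1, 1), cb)]) / 2
  mean(sqrt(gx^2 + gy^2))
}

#' Detect blobs across a whole stack
#'
#' Runs [detect_blobs()] on every frame against a common background
#' (estimated with [estimate_background()] unless supplied).
#'
#' @inheritParams detect_blobs
#' @inheritParams estimate_background
#' @param frames A `spray_stack`, array, or frame accessor function.
#' @param background Optional precomputed background image.
#' @param ... Passed on to [detect_blobs()].
#' @return A data.frame of blobs with a leading `frame` column.
#' @export
detect_stack <- function(frames, geometry, background = NULL, n_frames = NULL,
                         n_sample = 40, ...) {
  src <- as_frame_source(frames, n_frames)
  if (is.null(background)) background <- estimate_background(src, n_sample = n_sample)
  # stationary noise: estimate its robust sd once, over a frame subsample
  pick <- unique(round(seq(1, src$n_frames, length.out = min(8, src$n_frames))))
  sigma <- stats::median(vapply(pick, function(i)
    stats::mad(src$get(i) - background), numeric(1)))
  out <- vector("list", src$n_frames)
  for (i in seq_len(src$n_frames)) {
    b <- detect_blobs(src$get(i), background, geometry, noise_sd = sigma, ...)
    if (nrow(b) > 0) out[[i]] <- cbind(frame = i, b)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                      area_px = numeric(0), axial_extent_px = numeric(0),
                      lateral_extent_px = numeric(0), sharpness = numeric(0),
                      peak = numeric(0))
  rownames(res) <- NULL
  res
}
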