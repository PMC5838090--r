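# helpers to fabricate blob tables directly (detector-independent tests)
blob_row <- function(frame, row, col, area = 100, ext = 11, sharp = 50) {
  data.frame(frame = frame, row = row, col = col, area_px = area,
             axial_extent_px = ext, lateral_extent_px = ext, sharpness = sharp,
             peak = 100)
}

test_that("a single rendered droplet yields exactly one full-length trajectory", {
  geom <- tile_geometry(400)
  stk <- render_single_droplet(0.5, 2, geometry = geom, n_frames = 12,
                               settings = render_settings(rng_seed = 3))
  blobs <- detect_stack(stk, geom)
  trajs <- link_trajectories(blobs, geom)
  expect_equal(nrow(trajs$meta), 1)
  expect_equal(nrow(trajs$observations), length(unique(stk$truth$frame)))
})

test_that("a splitting parent produces two children with parent_id set", {
  geom <- full_geometry()
  blobs <- rbind(
    blob_row(1, 300, 100, area = 100),
    blob_row(2, 300, 150, area = 100),
    blob_row(3, 290, 200, area = 60, ext = 9),
    blob_row(3, 310, 200, area = 45, ext = 8))
  trajs <- link_trajectories(blobs, geom, area_tol = 0.3)
  expect_equal(nrow(trajs$meta), 3)
  kids <- trajs$meta[!is.na(trajs$meta$parent_id), ]
  expect_equal(nrow(kids), 2)
  expect_equal(unique(kids$parent_id), trajs$meta$trajectory_id[1])
  # the parent's own observations end at the split
  parent_obs <- trajs$observations[
    trajs$observations$trajectory_id == trajs$meta$trajectory_id[1], ]
  expect_equal(max(parent_obs$frame), 2)
})

test_that("area sub-additivity gates the split decision", {
  geom <- full_geometry()
  # children sum to 140 > 100 * 1.3: not a split; nearest becomes the
  # continuation, the other a new trajectory
  blobs <- rbind(
    blob_row(1, 300, 100, area = 100),
    blob_row(2, 295, 150, area = 80, ext = 10),
    blob_row(2, 305, 152, area = 60, ext = 9))
  trajs <- link_trajectories(blobs, geom, area_tol = 0.3)
  expect_equal(sum(!is.na(trajs$meta$parent_id)), 0)
  expect_equal(nrow(trajs$meta), 2)
})

test_that("well-separated droplets never cross-link and match the exhaustive oracle", {
  geom <- full_geometry()
  gate <- 20 / geom$frame_rate_hz * 1e6 / pixel_size(geom)
  blobs <- rbind(
    blob_row(1, 100, 100), blob_row(1, 500, 100),
    blob_row(2, 100, 150), blob_row(2, 500, 155))
  trajs <- link_trajectories(blobs, geom)
  expect_equal(nrow(trajs$meta), 2)
  obs <- trajs$observations
  for (id in trajs$meta$trajectory_id)
    expect_equal(length(unique(round(obs$row[obs$trajectory_id == id], -2))), 1)
})

test_that("greedy linking equals exhaustive minimal-distance assignment on sparse scenes", {
  geom <- tile_geometry(600, frame_rate = 1000, wd_mm = 3)
  gate <- 5 / geom$frame_rate_hz * 1e6 / pixel_size(geom)  # ~893 px... use small v
  mismatches <- 0
  set.seed(404)
  for (case in 1:100) {
    n <- sample(2:5, 1)
    # separation > 2 gate guarantees identifiability; gate from max_velocity 0.5 m/s
    max_v <- 0.5
    gate <- max_v / geom$frame_rate_hz * 1e6 / pixel_size(geom)  # ~89 px
    rows <- runif(n, 30, 570); cols <- runif(n, 30, 300)
    # enforce pairwise separation
    ok <- FALSE
    while (!ok) {
      rows <- runif(n, 30, 570); cols <- runif(n, 30, 300)
      ok <- n == 1 || min(dist(cbind(rows, cols))) > 2.2 * gate
    }
    step <- runif(n, 0.3 * gate, 0.95 * gate)
    blobs <- rbind(
      do.call(rbind, lapply(1:n, function(i) blob_row(1, rows[i], cols[i]))),
      do.call(rbind, lapply(1:n, function(i) blob_row(2, rows[i], cols[i] + step[i]))))
    trajs <- link_trajectories(blobs, geom, max_velocity_ms = max_v)
    heads <- blobs[blobs$frame == 1, ]
    nxt <- blobs[blobs$frame == 2, ]
    oracle <- exhaustive_assignment(heads, nxt, gate, geom)
    # greedy assignment: head i continued by which frame-2 blob?
    obs <- trajs$observations
    greedy <- vapply(seq_len(n), function(i) {
      id <- obs$trajectory_id[obs$frame == 1 & obs$row == heads$row[i]]
      o2 <- obs[obs$trajectory_id == id & obs$frame == 2, ]
      if (nrow(o2) == 0) NA_integer_ else which(nxt$row == o2$row & nxt$col == o2$col)
    }, integer(1))
    if (!identical(greedy, oracle)) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("every blob belongs to exactly one trajectory", {
  geom <- strip_geometry()
  ens <- sample_ensemble(reference_spray_groups(3.0)$groups, 0.02, 120, geom,
                         seed = 5)
  stk <- render_frames(ens, geom, render_settings(rng_seed = 5), output = "function")
  blobs <- detect_stack(stk, geom)
  trajs <- link_trajectories(blobs, geom)
  expect_equal(nrow(trajs$observations), nrow(blobs))
  key <- with(trajs$observations, paste(frame, row, col))
  expect_equal(anyDuplicated(key), 0)
})

test_that("ROI qualification demands strict entry-before and exit-after", {
  geom <- full_geometry()                      # ROI [1.0, 3.5] mm; tip at 50 px
  px_of <- function(mm) spraymode:::px_from_axial_mm(mm, geom)
  mk <- function(mms, row = 300) do.call(rbind, lapply(seq_along(mms), function(i)
    blob_row(i, row, px_of(mms[i]))))
  trajs <- link_trajectories(mk(c(0.5, 1.7, 2.9, 3.8)), geom)
  trajs <- roi_filter(trajs, roi_from_geometry(geom), geometry = geom)
  expect_true(all(trajs$meta$qualified))
  trajs2 <- link_trajectories(mk(c(1.2, 2.4, 3.6)), geom)   # starts inside
  trajs2 <- roi_filter(trajs2, roi_from_geometry(geom), geometry = geom)
  expect_false(any(trajs2$meta$qualified))
  trajs3 <- link_trajectories(mk(c(0.5, 1.7, 2.9, 3.4)), geom)  # ends inside
  trajs3 <- roi_filter(trajs3, roi_from_geometry(geom), geometry = geom)
  expect_false(any(trajs3$meta$qualified))
})

test_that("split children inherit the parent's entry position for the ROI test", {
  geom <- full_geometry()
  px_of <- function(mm) spraymode:::px_from_axial_mm(mm, geom)
  blobs <- rbind(
    blob_row(1, 300, px_of(0.6), area = 100),
    blob_row(2, 300, px_of(1.4), area = 100),
    blob_row(3, 290, px_of(2.2), area = 55, ext = 9),
    blob_row(3, 310, px_of(2.2), area = 40, ext = 8),
    blob_row(4, 290, px_of(3.0), area = 55, ext = 9),
    blob_row(4, 310, px_of(3.0), area = 40, ext = 8),
    blob_row(5, 290, px_of(3.7), area = 55, ext = 9),
    blob_row(5, 310, px_of(3.7), area = 40, ext = 8))
  trajs <- link_trajectories(blobs, geom, max_velocity_ms = 20)
  trajs <- roi_filter(trajs, roi_from_geometry(geom), geometry = geom)
  kids <- trajs$meta[!is.na(trajs$meta$parent_id), ]
  expect_equal(nrow(kids), 2)
  expect_true(all(kids$qualified))             # born at 2.2 mm, inherited entry 0.6 mm
  expect_false(trajs$meta$qualified[is.na(trajs$meta$parent_id)])  # parent never exits
})

test_that("the exact focal mode keeps |z| <= 0.25 mm and drops the rest", {
  geom <- tile_geometry(300)
  st <- render_settings(rng_seed = 8)
  for (z in c(0, 0.4)) {
    stk <- render_single_droplet(0.5, 2, z_mm = z, geometry = geom, n_frames = 12,
                                 settings = st)
    blobs <- detect_stack(stk, geom)
    trajs <- link_trajectories(blobs, geom)
    trajs$meta$qualified <- TRUE
    kept <- focal_filter(trajs, mode = "exact", truth = stk$truth)
    expect_equal(nrow(kept$meta), if (z <= 0.25) 1 else 0)
  }
})

test_that("sharpness-mode and exact-mode focal filtering agree on most droplets", {
  geom <- strip_geometry()
  ref <- reference_spray_groups(3.0)
  agree <- replicate(2, {
    s <- sample.int(1000, 1)
    ens <- sample_ensemble(ref$groups, 0.05, 220, geom, seed = s)
    stk <- render_frames(ens, geom, render_settings(rng_seed = s), output = "function")
    blobs <- detect_stack(stk, geom)
    trajs <- link_trajectories(blobs, geom)
    trajs$meta$qualified <- TRUE
    ids <- trajs$meta$trajectory_id
    keep_sharp <- ids %in% focal_filter(trajs, mode = "sharpness")$meta$trajectory_id
    keep_exact <- ids %in% focal_filter(trajs, mode = "exact",
                                        truth = stk$truth)$meta$trajectory_id
    mean(keep_sharp == keep_exact)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("impact velocity converts the last two centroids at scale", {
  geom <- full_geometry()
  obs <- blob_row(1:2, c(300, 300), c(100, 153.57))
  expect_equal(impact_velocity(obs, geom), 53.57 * 5.60994 * 1e-6 * 1e4,
               tolerance = 1e-6)
  expect_equal(round(impact_velocity(obs, geom), 1), 3.0)
  obs2 <- blob_row(1:2, c(300, 300), c(100, 350))
  expect_equal(round(impact_velocity(obs2, geom), 1), 14.0)
  obs0 <- blob_row(1:2, c(300, 300), c(100, 100))
  expect_equal(impact_velocity(obs0, geom), 0)
  expect_error(impact_velocity(blob_row(1, 300, 100), geom), "two observations")
})

test_that("records drop out-of-window velocities and sub-floor volumes", {
  geom <- full_geometry()
  px_of <- function(mm) spraymode:::px_from_axial_mm(mm, geom)
  path <- c(0.5, 1.6, 2.7, 3.8)
  mk_trajs <- function(area, ext, last_jump_px = NULL) {
    b <- do.call(rbind, lapply(seq_along(path), function(i)
      blob_row(i, 300, px_of(path[i]), area = area, ext = ext)))
    if (!is.null(last_jump_px)) b$col[length(path)] <- b$col[3] + last_jump_px
    trajs <- link_trajectories(b, geom, max_velocity_ms = 30)
    roi_filter(trajs, roi_from_geometry(geom), geometry = geom)
  }
  ok <- make_records(mk_trajs(385, 22), geom)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$volume_nl, 1, tolerance = 0.1)      # ~385 px / 22 px at 5.6 um
  # velocity beyond 20 m/s (jump of ~375 px = 21 m/s)
  fast <- make_records(mk_trajs(385, 22, last_jump_px = 375), geom)
  expect_equal(nrow(fast), 0)
  # volume at the 4.2 pl floor: 10 px, 4 px extent is ~2.6 pl
  small <- make_records(mk_trajs(10, 4), geom)
  expect_equal(nrow(small), 0)
})

test_that("recovered trajectory counts and velocities track the ground truth", {
  # sparse split-free sequences: in-focus droplets well above 20 px
  geom <- strip_geometry()
  hits <- c(); vel_err <- c()
  for (s in c(41, 42, 43)) {
    ens <- sample_ensemble(list(group_spec("g", 0.5, 0.2, 3, 0.8, 1)),
                           0.06, 3, geom, seed = s, z_sd_mm = 0,
                           lateral_spread_mm = 0.12)
    stk <- render_frames(ens, geom, render_settings(rng_seed = s), output = "function")
    blobs <- detect_stack(stk, geom)
    trajs <- link_trajectories(blobs, geom)
    # full-length trajectories (>= 8 obs) should match the droplet count
    len <- table(trajs$observations$trajectory_id)
    hits <- c(hits, sum(len >= 8) == nrow(ens))
    trajs <- roi_filter(trajs, roi_from_geometry(geom), geometry = geom)
    rec <- make_records(trajs, geom)
    for (id in rec$trajectory_id) {
      oo <- trajs$observations[trajs$observations$trajectory_id == id, ]
      tt <- stk$truth[stk$truth$frame == oo$frame[1], ]
      d2 <- (tt$row_px - oo$row[1])^2 + (tt$col_px - oo$col[1])^2
      vel_err <- c(vel_err, abs(rec$velocity_ms[rec$trajectory_id == id] -
                                tt$velocity_ms[which.min(d2)]) /
                             tt$velocity_ms[which.min(d2)])
    }
  }
  expect_gte(mean(hits), 2 / 3)
  expect_lt(median(vel_err), 0.10)
})
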