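test_that("ensemble sampling is deterministic and hits the volume stopping rule", {
  geom <- strip_geometry()
  g <- list(group_spec("A", 1, 0.5, 3, 1, 1.0))
  e1 <- sample_ensemble(g, 0.05, 100, geom, seed = 7)
  e2 <- sample_ensemble(g, 0.05, 100, geom, seed = 7)
  expect_identical(e1, e2)
  tot <- sum(e1$volume_nl)
  expect_gte(tot, 100)
  expect_lt(tot - e1$volume_nl[nrow(e1)], 100)   # overshoot at most one droplet
  e3 <- sample_ensemble(g, 0.05, 100, geom, seed = 8)
  expect_false(identical(e1$volume_nl, e3$volume_nl))
})

test_that("group volume fractions are reproduced across seeds", {
  geom <- strip_geometry()
  ref <- reference_spray_groups(3.0)   # 1.4 nl @ 2.9 m/s (95%), 0.2 nl @ 14.3 (5%)
  fr <- sapply(1:8, function(s) {
    e <- sample_ensemble(ref$groups, 0.05, 1091, geom, seed = s)
    v <- tapply(e$volume_nl, e$group, sum)
    100 * v / sum(v)
  })
  expect_equal(mean(fr["group1", ]), 95, tolerance = 3 / 95)
  expect_equal(mean(fr["group2", ]), 5, tolerance = 3 / 5)
})

test_that("group specifications validate their invariants", {
  expect_error(group_spec("x", 0, 1, 3, 1, 0.5), "positive")
  expect_error(group_spec("x", 1, -1, 3, 1, 0.5))
  expect_error(group_spec("x", 1, 1, 3, 1, 1.5))
  g <- list(group_spec("a", 1, 0, 3, 0, 0.6), group_spec("b", 1, 0, 3, 0, 0.3))
  expect_error(sample_ensemble(g, 0.01, 10, strip_geometry(), 1), "sum to 1")
})

test_that("an empty ensemble renders to pure noise around the background level", {
  geom <- tile_geometry(80)
  ens <- manual_ensemble()
  st <- render_settings(background_level = 30, noise_sd = 5, rng_seed = 3)
  stk <- render_frames(ens, geom, st, n_frames = 12)
  m <- mean(stk$frames)
  expect_lt(abs(m - 30), 3 * 5 / sqrt(length(stk$frames)) + 0.5)  # + quantization
  expect_equal(nrow(stk$truth), 0)
})

test_that("a droplet advances by velocity over frame rate in the truth table", {
  geom <- tile_geometry(400)
  stk <- render_single_droplet(volume_nl = 1, velocity_ms = 3, geometry = geom)
  tr <- stk$truth
  steps <- diff(tr$col_px)
  # 3 m/s at 10 kHz and 5.6 um/px
  expect_equal(steps, rep(3 / 10000 / 5.6e-6, length(steps)), tolerance = 1e-9)
  expect_equal(steps[1], 53.57, tolerance = 1e-3)
})

test_that("rendered blob areas match the projected ellipse areas", {
  geom <- tile_geometry(300)
  st <- render_settings(noise_sd = 0.1, rng_seed = 5)
  for (v in c(0.02, 0.1, 1, 4)) {       # 0.02 nl ~ 40 px upward
    stk <- render_single_droplet(volume_nl = v, velocity_ms = 1, geometry = geom,
                                 settings = st, n_frames = 3)
    fr <- stk$frames[, , 2]
    area <- sum(fr > st$background_level + st$droplet_intensity / 2)
    expect_equal(area, stk$truth$area_px[1], tolerance = 0.15)
  }
})

test_that("a 4.2 pl sphere renders to about the 10-pixel detection cutoff", {
  geom <- tile_geometry(100)
  st <- render_settings(noise_sd = 0.1, rng_seed = 6)
  stk <- render_single_droplet(volume_nl = 0.0042, velocity_ms = 1,
                               geometry = geom, settings = st, n_frames = 3)
  fr <- stk$frames[, , 2]
  area <- sum(fr > st$background_level + st$droplet_intensity / 2)
  expect_gte(area, 7)
  expect_lte(area, 14)
})

test_that("split children conserve volume and separate into distinct blobs", {
  geom <- tile_geometry(400, wd_mm = 1.8)
  ens <- manual_ensemble(list(entry_lateral_mm = geom$fov_height_mm / 2,
                              velocity_ms = 2, volume_nl = 1,
                              split_time_s = 0.4e-3, split_share1 = 0.6))
  stk <- render_frames(ens, geom, render_settings(rng_seed = 11))
  tr <- stk$truth
  kids <- unique(tr$droplet_id[!is.na(tr$parent_id)])
  expect_length(kids, 2)
  kid_vols <- sapply(kids, function(k) tr$volume_nl[tr$droplet_id == k][1])
  expect_equal(sum(kid_vols), 1, tolerance = 1e-9)
  expect_equal(sort(unname(kid_vols)), c(0.4, 0.6), tolerance = 1e-9)
  # after the split the parent no longer appears
  split_frame <- min(tr$frame[!is.na(tr$parent_id)])
  expect_false(any(tr$droplet_id == "d00001" & tr$frame >= split_frame))
})

test_that("rendering is deterministic and identical between array and accessor modes", {
  geom <- tile_geometry(120)
  ens <- sample_ensemble(list(group_spec("g", 0.2, 0.1, 2, 0.5, 1)),
                         0.004, 1, geom, seed = 4)
  s1 <- render_frames(ens, geom, render_settings(rng_seed = 21))
  s2 <- render_frames(ens, geom, render_settings(rng_seed = 21))
  expect_identical(s1$frames, s2$frames)
  s3 <- render_frames(ens, geom, render_settings(rng_seed = 21), output = "function",
                      n_frames = s1$n_frames)
  for (i in c(1, 3, s1$n_frames))
    expect_identical(s1$frames[, , i], s3$frames(i))
})

test_that("render settings enforce contrast and sane parameters", {
  expect_error(render_settings(noise_sd = 10, droplet_intensity = 25), "3 \\* noise_sd")
  expect_error(render_settings(bit_depth = 12))
  expect_error(render_settings(aspect_ratio = 0))
})

test_that("oversized droplets and unrepresentable velocities are rejected", {
  geom <- tile_geometry(60)
  ens <- manual_ensemble(list(entry_lateral_mm = geom$fov_height_mm / 2,
                              velocity_ms = 1, volume_nl = 500))
  expect_error(render_frames(ens, geom, render_settings(rng_seed = 1)), "larger")
  fastgeom <- tile_geometry(60, frame_rate = 100)   # 1 m/s covers > 60 px per frame
  ens2 <- manual_ensemble(list(entry_lateral_mm = fastgeom$fov_height_mm / 2,
                               velocity_ms = 8, volume_nl = 0.01))
  expect_error(render_frames(ens2, fastgeom, render_settings(rng_seed = 1)),
               "not representable")
})
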