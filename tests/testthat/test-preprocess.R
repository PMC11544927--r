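cfg <- test_config()

test_that("frame-power normalization removes global intensity fluctuations", {
  set.seed(1)
  base <- matrix(runif(64, 0.5, 1), 8)
  arr <- array(0, c(8, 8, 10))
  gains <- seq(1, 1.1, length.out = 10) # 1 %/frame drift
  for (i in 1:10) arr[, , i] <- base * gains[i]
  v <- contrast_video(arr, 1e-5, "raw", pixel_size = 100)
  nv <- normalize_frame_power(v)
  # scale invariance: per-pixel temporal variation removed
  tsd <- apply(nv$frames, c(1, 2), sd)
  expect_lt(max(tsd) / mean(nv$frames), 1e-10)
  # multiplying a frame by a constant leaves its normalized version unchanged
  arr2 <- arr; arr2[, , 10] <- arr2[, , 10] * 7.3
  nv2 <- normalize_frame_power(contrast_video(arr2, 1e-5, "raw", pixel_size = 100))
  expect_equal(nv2$frames[, , 10], nv$frames[, , 10], tolerance = 1e-12)
  expect_equal(nv$provenance, "normalized")

  arr3 <- arr; arr3[, , 2] <- 0
  expect_error(normalize_frame_power(contrast_video(arr3, 1e-5, "raw")), "frame 2")
})

test_that("temporal median background correction yields contrast", {
  # static video -> exactly zero contrast
  arr <- array(rep(matrix(runif(49, 0.5, 1.5), 7), 9), c(7, 7, 9))
  v <- contrast_video(arr, 1e-5, "normalized")
  bc <- temporal_median_background(v, window = 5L)
  expect_equal(max(abs(bc$frames)), 0)
  expect_equal(bc$provenance, "background_corrected")

  # a single-frame impulse survives its frame and vanishes elsewhere
  arr2 <- array(1, c(5, 5, 9))
  arr2[3, 3, 4] <- 2
  bc2 <- temporal_median_background(contrast_video(arr2, 1e-5, "normalized"), 5L)
  expect_equal(bc2$frames[3, 3, 4], 1)
  expect_lt(max(abs(bc2$frames[, , -4])), 1e-12)

  expect_error(temporal_median_background(v, window = 4L), "odd")
  arr4 <- arr; arr4[1, 1, ] <- 0
  expect_error(temporal_median_background(contrast_video(arr4, 1e-5, "normalized"), 5L),
               "median")
})

test_that("a diffusing particle's contrast survives background correction", {
  # near-focus particle sweeping across the field: its compact iPSF occupies
  # each pixel far less than half the window, so the median sees background
  cfg2 <- optical_config(focal_plane_z = 1200)
  px <- cfg2$pixel_size
  xs <- seq(8, 40, length.out = 15) * px
  traj <- structure(data.frame(frame = 1:15, t = (0:14) * 1e-5, x = xs,
                               y = rep(24 * px, 15), z = rep(1200, 15)),
                    dt = 1e-5, class = c("trajectory3d", "data.frame"))
  truth <- render_video(traj, cfg2, camera = NULL, image_size = 49L)
  raw <- truth
  raw$frames <- (1 + truth$frames) * 0.8 # detected counts on a flat reference
  raw$provenance <- "raw"
  bc <- temporal_median_background(normalize_frame_power(raw), window = 15L)
  i <- 8
  sel <- abs(truth$frames[, , i]) > 0.02
  expect_gt(sum(sel), 10)
  expect_lt(max(abs(bc$frames[, , i][sel] - truth$frames[, , i][sel])) /
              max(abs(truth$frames[, , i])), 0.05)
})

test_that("RVT matches its brute-force oracle and localizes ring patterns", {
  set.seed(21)
  img <- matrix(rnorm(32 * 32), 32)
  expect_lt(max(abs(rvt_map(img, 2, 6) - bf_rvt(img, 2, 6))), 1e-10)

  # perfectly centered synthetic ring
  n <- 41
  d <- sqrt(outer(((0:40) - 20)^2, ((0:40) - 20)^2, "+"))
  ring <- exp(-(d - 8)^2 / 2)
  loc <- rvt_localize(ring, 2, 15)
  expect_lt(abs(loc$x - 20), 0.01)
  expect_lt(abs(loc$y - 20), 0.01)

  # integer translation moves the estimate identically
  d2 <- sqrt(outer(((0:40) - 18)^2, ((0:40) - 23)^2, "+")) # center (23, 18)
  ring2 <- exp(-(d2 - 8)^2 / 2)
  loc2 <- rvt_localize(ring2, 2, 15)
  expect_lt(abs(loc2$x - (loc$x + 3)), 0.05)
  expect_lt(abs(loc2$y - (loc$y - 2)), 0.05)

  # no-detection flagging with a high confidence floor
  flat <- matrix(0, 32, 32)
  nod <- rvt_localize(flat, 2, 6, confidence_floor = 10)
  expect_false(nod$ok)
  expect_true(is.na(nod$x))
})

test_that("RVT localizes rendered iPSFs to sub-0.1 px accuracy", {
  px <- cfg$pixel_size
  set.seed(5)
  errs <- replicate(20, {
    ctr <- c(24, 24) + runif(2, -0.5, 0.5)
    traj <- simulate_trajectory(0, 1e-5, 2,
                                start = c(ctr[1] * px, ctr[2] * px, runif(1, 800, 4500)),
                                diameter = 40)
    fr <- render_video(traj, cfg, camera = NULL, image_size = 49L)$frames[, , 1]
    loc <- rvt_localize(fr, 2, 20)
    sqrt((loc$x - ctr[1])^2 + (loc$y - ctr[2])^2)
  })
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("profile series reproduce the model along a height ramp", {
  px <- cfg$pixel_size
  zv <- seq(1500, 1800, by = 20)
  traj <- structure(data.frame(frame = seq_along(zv), t = seq_along(zv) * 1e-5,
                               x = rep(24 * px, length(zv)),
                               y = rep(24 * px, length(zv)), z = zv),
                    dt = 1e-5, class = c("trajectory3d", "data.frame"))
  vid <- render_video(traj, cfg, camera = NULL, image_size = 49L)
  ctr <- data.frame(x_px = rep(24, length(zv)), y_px = rep(24, length(zv)))
  prof <- extract_profiles(vid, ctr, n_bins = 24L)
  stack <- build_model_stack(cfg, 1500, 1800, 20, image_size = 49L, n_bins = 24L)
  for (i in seq_along(zv))
    expect_gt(bf_pearson(prof$profiles[i, ], stack$profiles[i, ]), 0.999)

  # static particle: all rows identical within numerical noise
  vstat <- render_video(traj[c(3, 3, 3), ] |>
                          (\(d) { d$frame <- 1:3; d })(), cfg,
                        camera = NULL, image_size = 49L)
  pstat <- extract_profiles(vstat, ctr[1:3, ], n_bins = 24L)
  expect_lt(max(abs(sweep(pstat$profiles, 2, pstat$profiles[1, ]))), 1e-12)
})

test_that("overlapping defocused particles barely perturb central profiles", {
  px <- cfg$pixel_size
  z0 <- 1500
  f1 <- render_static_frame(cfg, z0, center_px = c(40, 40), image_size = 81L)
  f2 <- render_static_frame(cfg, 5200, center_px = c(70, 40), image_size = 81L)
  ctr <- data.frame(x_px = 40, y_px = 40)
  v1 <- contrast_video(array(f1, c(81, 81, 1)), 1e-5, "background_corrected",
                       pixel_size = px)
  v12 <- contrast_video(array(f1 + f2, c(81, 81, 1)), 1e-5, "background_corrected",
                        pixel_size = px)
  p1 <- extract_profiles(v1, ctr, n_bins = 20L)
  p12 <- extract_profiles(v12, ctr, n_bins = 20L)
  # inner radii exclude the intruder's rings (30 px away)
  inner <- 1:12
  expect_lt(max(abs(p12$profiles[1, inner] - p1$profiles[1, inner])) /
              max(abs(p1$profiles[1, inner])), 0.05)
})
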