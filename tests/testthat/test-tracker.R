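cfg <- test_config()

test_that("correlation map equals the brute-force Pearson oracle", {
  set.seed(3)
  stack <- build_model_stack(cfg, 3000, 3006, 1, image_size = 41L, n_bins = 20L)
  M <- stack$profiles
  P <- M[c(2, 5, 7, 1, 4), ] + matrix(rnorm(100, sd = 0.01), 5)
  cm <- correlation_map(P, stack, blur_offsets = 0, weights = NULL)
  expect_lt(max(abs(cm$rho - bf_corrmap(P, M))), 1e-12)
  expect_true(all(cm$rho >= -1 & cm$rho <= 1))

  # exact model rows give rho = 1 at their own height, -rows give -1
  cm2 <- correlation_map(M[c(3, 6), ], stack, blur_offsets = 0, weights = NULL)
  expect_equal(cm2$rho[1, 3], 1)
  expect_equal(cm2$rho[2, 6], 1)
  cm3 <- correlation_map(-M[3, , drop = FALSE], stack, blur_offsets = 0,
                         weights = NULL)
  expect_equal(cm3$rho[1, 3], -1)

  # zero-variance profiles are flagged, not propagated as NaN
  P2 <- rbind(M[2, ], rep(0.5, 20))
  cm4 <- correlation_map(P2, stack, blur_offsets = 0, weights = NULL)
  expect_equal(cm4$flagged_frames, 2L)
  expect_true(all(is.finite(cm4$rho)))
})

test_that("count-weighted correlation matches a weighted oracle", {
  set.seed(8)
  stack <- build_model_stack(cfg, 3000, 3004, 1, image_size = 41L, n_bins = 20L)
  w <- stack$bin_counts
  P <- stack$profiles[c(1, 4), ] + matrix(rnorm(40, sd = 0.01), 2)
  cm <- correlation_map(P, stack, blur_offsets = 0, weights = w)
  bf_wp <- function(x, y, w) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  for (i in 1:2) for (j in 1:5)
    expect_equal(cm$rho[i, j], bf_wp(P[i, ], stack$profiles[j, ], w),
                 tolerance = 1e-12)
})

test_that("region labeling scores components like a hand enumeration", {
  rho <- matrix(-1, 4, 6)
  rho[1, 1:2] <- c(0.9, 0.8)   # blob A, frames 1-2
  rho[2, 2] <- 0.7
  rho[3:4, 5:6] <- c(0.5, 0.6, 0.4, 0.3) # blob B, frames 3-4
  map <- structure(list(rho = rho, z_grid = 1:6, flagged_frames = integer(0)),
                   class = "correlation_map")
  lab <- label_regions(map)
  expect_equal(lab$n_regions, 2L)
  # hand scores: A = max(0.9, 0.8) + 0.7 = 1.6
  # B fills (3,5)=0.5, (4,5)=0.6, (3,6)=0.4, (4,6)=0.3 -> 0.5 + 0.6 = 1.1
  expect_equal(sort(lab$scores, decreasing = TRUE), c(1.6, 1.1))
  expect_equal(lab$scores[lab$selected], 1.6)
  expect_true(all(lab$mask[1, 1:2]))

  # single positive stripe: one region, score = sum of per-frame maxima
  rho2 <- matrix(-1, 5, 4); rho2[, 2] <- seq(0.5, 0.9, by = 0.1)
  map2 <- structure(list(rho = rho2, z_grid = 1:4, flagged_frames = integer(0)),
                    class = "correlation_map")
  lab2 <- label_regions(map2)
  expect_equal(lab2$n_regions, 1L)
  expect_equal(lab2$scores, sum(seq(0.5, 0.9, by = 0.1)))

  # 8-connectivity joins diagonal neighbors
  rho3 <- matrix(-1, 2, 2); rho3[1, 1] <- 0.5; rho3[2, 2] <- 0.5
  map3 <- structure(list(rho = rho3, z_grid = 1:2, flagged_frames = integer(0)),
                    class = "correlation_map")
  expect_equal(label_regions(map3)$n_regions, 1L)

  expect_error(label_regions(structure(list(rho = matrix(-1, 2, 2), z_grid = 1:2,
                                            flagged_frames = integer(0)),
                                       class = "correlation_map")), "no region")
})

test_that("branch graphs represent sections and count paths correctly", {
  # single branch: one source->branch->sink chain, distance = sum(1 - rho)
  m <- matrix(FALSE, 5, 10); m[, 4:5] <- TRUE
  map <- rho_for_mask(m, hi = 0.8)
  g <- build_branch_graph(map, m)
  expect_equal(nrow(g$branches), 1L)
  expect_equal(count_paths(g), 1)
  expect_equal(g$branches$cost, 5 * (1 - 0.8), tolerance = 1e-9)

  # one two-branch episode: 2 paths and 4 branches (before, two parallel, after)
  m2 <- toggle_mask(1)
  g2 <- build_branch_graph(rho_for_mask(m2), m2)
  expect_equal(count_paths(g2), 2)
  expect_equal(nrow(g2$branches), 4L)

  # rho identically maximal on all branches -> all distances ~ 0
  g2z <- build_branch_graph(rho_for_mask(m2, hi = 1), m2)
  expect_true(all(igraph::E(g2z$graph)$weight < 1e-6))

  # 23 episodes: 2^23 paths exactly
  m23 <- toggle_mask(23)
  g23 <- build_branch_graph(rho_for_mask(m23), m23)
  expect_identical(count_paths(g23), 2^23)
  expect_identical(count_paths(g23), 8388608)
})

test_that("path counting matches exhaustive enumeration on random graphs", {
  set.seed(17)
  for (rep in 1:8) {
    n <- 30
    m <- matrix(FALSE, n, 40)
    z <- 20
    for (i in 1:n) {
      k <- sample(1:3, 1)
      lo <- sort(sample(seq(5, 30, by = 6), k))
      for (l in lo) m[i, l:(l + 3)] <- TRUE
    }
    map <- rho_for_mask(m, hi = 0.5)
    g <- try(build_branch_graph(map, m), silent = TRUE)
    if (inherits(g, "try-error")) next
    for (s in seq_len(nrow(g$segments))) {
      npaths <- igraph::all_simple_paths(g$graph, g$segments$source[s],
                                         g$segments$sink[s], mode = "out")
      expect_equal(count_paths(g)[s], length(npaths))
    }
  }
})

test_that("Dijkstra debranching matches exhaustive path search", {
  set.seed(23)
  for (rep in 1:6) {
    m <- toggle_mask(sample(2:5, 1))
    rho <- matrix(-0.5, nrow(m), ncol(m))
    rho[m] <- runif(sum(m), 0.1, 0.99)
    map <- structure(list(rho = rho, z_grid = seq_len(ncol(m)),
                          flagged_frames = integer(0)),
                     class = "correlation_map")
    g <- build_branch_graph(map, m)
    deb <- shortest_path_debranch(g)
    # chosen path cost equals the minimum over all enumerated paths
    costs <- bf_all_paths(g, 1)
    chosen <- sum(1 - deb$assignment$maxrho)
    expect_lt(abs(chosen - min(costs)), 1e-6)
    # equivalently: it maximizes the summed per-frame maximum correlation
    expect_equal(nrow(deb$assignment), nrow(m))
  }
})

test_that("exact branch ties resolve deterministically to the lower height", {
  m <- toggle_mask(1)
  map <- rho_for_mask(m, hi = 0.9) # both branches identical
  g <- build_branch_graph(map, m)
  deb <- shortest_path_debranch(g)
  mid <- deb$assignment[deb$assignment$frame == 3, ]
  expect_equal(mid$lo, 10L) # lower-z sub-branch spans columns 10-12
  expect_equal(mid$hi, 12L)
})

test_that("adaptive polynomial refinement is exact on polynomials", {
  z <- seq(100, 120, by = 1)
  z0 <- 110.37
  rho <- 1 - 1e-4 * (z - z0)^2
  r <- refine_axial(rho, z)
  expect_lt(abs(r$z - z0), 1e-6)

  # flat column flagged degenerate, center returned
  rf <- refine_axial(rep(0.5, 11), seq_len(11))
  expect_equal(rf$flag, "degenerate")
  expect_equal(rf$z, 6)

  # single point: unrefined
  r1 <- refine_axial(0.8, 42)
  expect_equal(r1$flag, "unrefined")
  expect_equal(r1$z, 42)
})

test_that("refinement against the model beats the grid resolution", {
  # profile generated at an off-grid height; dense-grid argmax as oracle
  z_true <- 2600.43
  stack <- build_model_stack(cfg, 2580, 2620, 1, image_size = 41L, n_bins = 20L)
  dense <- build_model_stack(cfg, 2598, 2603, 0.01, image_size = 41L, n_bins = 20L)
  radii <- stack$radii
  prof_at <- function(z) {
    s2 <- build_model_stack(cfg, z, z + 0.5, 1, image_size = 41L, n_bins = 20L)
    s2$profiles[1, ]
  }
  v <- prof_at(z_true)
  loc <- localize_profile(v, stack)
  # oracle: argmax over the 0.01 nm grid
  wm <- dense$bin_counts
  rho_dense <- apply(dense$profiles, 1, function(m) {
    mw <- sum(wm * m) / sum(wm); vw <- sum(wm * v) / sum(wm)
    sum(wm * (m - mw) * (v - vw)) /
      sqrt(sum(wm * (m - mw)^2) * sum(wm * (v - vw)^2))
  })
  z_oracle <- dense$z_grid[which.max(rho_dense)]
  expect_lt(abs(loc$z - z_oracle), 0.5)
  expect_lt(abs(loc$z - z_true), 0.5)
})

test_that("correlation stripes along height have the carrier period", {
  cfar <- optical_config(focal_plane_z = 0) # stripes 5-6 um beyond focus
  stack <- build_model_stack(cfar, 5200, 6200, 1, image_size = 61L, n_bins = 20L)
  i0 <- which(stack$z_grid == 5700)
  cm <- correlation_map(stack$profiles[i0, , drop = FALSE], stack,
                        blur_offsets = 0, weights = NULL)
  per <- estimate_period(stack$z_grid, cm$rho[1, ])
  expect_lt(abs(per - 515 / (2 * 1.33)) / (515 / (2 * 1.33)), 0.02)
})

test_that("noiseless ramp tracking recovers heights below grid resolution and
           the debranched track obeys the stripe-linking bound", {
  px <- cfg$pixel_size
  zv <- round(seq(1000, 2600, length.out = 60)) # away from the focal plane
  traj <- structure(data.frame(frame = seq_along(zv), t = seq_along(zv) * 1e-5,
                               x = rep(40 * px, 60), y = rep(40 * px, 60), z = zv),
                    dt = 1e-5, class = c("trajectory3d", "data.frame"))
  vid <- render_video(traj, cfg, camera = NULL, image_size = 81L)
  ctr <- data.frame(x_px = rep(40, 60), y_px = rep(40, 60))
  prof <- extract_profiles(vid, ctr, n_bins = 40L)
  stack <- build_model_stack(cfg, 700, 2900, 1, image_size = 81L, n_bins = 40L)
  ax <- track_axial(prof, stack)
  expect_true(all(is.finite(ax$z_nm)))
  expect_lt(max(abs(ax$z_nm - zv)), stack$z_step)
  expect_true(all(abs(diff(ax$z_nm)) < 515 / (2 * 1.33)))
})

test_that("the graph tracker avoids cross-stripe jumps that frame-wise argmax
           makes", {
  # a weak scatterer (15 nm) at the experimental noise level: per-frame
  # argmax flips between stripes, the global path does not
  px <- cfg$pixel_size
  set.seed(31)
  sc <- scatterer_amplitude(cfg, 15)
  zv <- round(seq(2600, 3800, length.out = 120)) # through the focal plane
  traj <- structure(data.frame(frame = seq_along(zv), t = seq_along(zv) * 1e-5,
                               x = rep(40 * px, 120), y = rep(40 * px, 120), z = zv),
                    dt = 1e-5, class = c("trajectory3d", "data.frame"))
  vid <- render_video(traj, cfg, camera_config(), noise_seed = 77,
                      image_size = 81L, scatterer = sc)
  ctr <- data.frame(x_px = rep(40, 120), y_px = rep(40, 120))
  prof <- extract_profiles(vid, ctr, n_bins = 40L)
  stack <- build_model_stack(cfg, 2200, 4200, 1, image_size = 81L, n_bins = 40L,
                             scatterer = sc)

  naive <- apply(prof$profiles, 1, function(v) localize_profile(v, stack)$z)
  ax <- track_axial(prof, stack)
  jump <- 515 / (4 * 1.33)
  naive_jumps <- sum(abs(diff(naive)) > jump, na.rm = TRUE)
  graph_jumps <- sum(abs(diff(ax$z_nm)) > jump, na.rm = TRUE)
  expect_gt(naive_jumps, 0)
  expect_equal(graph_jumps, 0)
})
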