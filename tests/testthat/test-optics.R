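test_that("homodyne contrast follows (s^2 + 2 r s cos phi)/r^2", {
  expect_equal(ipsf_contrast(field_amplitudes(1, 0, 0.3)), 0)
  expect_equal(ipsf_contrast(field_amplitudes(1, 0.1, 0)), 0.21)
  expect_equal(ipsf_contrast(field_amplitudes(1, 0.1, pi)), -0.19)
  # contrast bounded below by -1 (nonnegative detected intensity)
  for (phi in seq(0, 2 * pi, length.out = 17))
    expect_gte(ipsf_contrast(field_amplitudes(0.04, 0.03, phi)), -1)
  expect_error(ipsf_contrast(field_amplitudes(0, 0.1, 0)), "reference")
})

test_that("config invariants are enforced", {
  expect_error(optical_config(numerical_aperture = 1.6), "aperture")
  expect_error(optical_config(wavelength = -1), "wavelength")
  expect_error(optical_config(pixel_size = 0), "pixel_size")
})

cfg <- test_config()

test_that("model images are circularly symmetric with a central peak", {
  img <- compute_ipsf_image(cfg, 3200, image_size = 41L) # in focus
  n <- 41L
  c0 <- floor(n / 2)
  pk <- which(abs(img) == max(abs(img)), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(c0 + 1L, c0 + 1L))
  # azimuthal variance at fixed radius is numerically zero
  d2 <- ((0:(n - 1)) - c0)^2
  rr <- round(sqrt(outer(d2, d2, "+")), 9)
  for (rv in c(5, 10, 15)) {
    vals <- img[rr == rv]
    expect_gt(length(vals), 3)
    expect_lt(var(vals) / mean(vals^2), 1e-6)
  }
})

test_that("contrast scales linearly with scatterer strength when s << r", {
  sc <- scatterer_amplitude(cfg, 40) * 1e-3 # deep Rayleigh limit
  i1 <- compute_ipsf_image(cfg, 800, scatterer = sc, image_size = 31L)
  i2 <- compute_ipsf_image(cfg, 800, scatterer = 2 * sc, image_size = 31L)
  s_over_r <- Mod(2 * sc) / abs((cfg$n_medium - cfg$n_glass) / (cfg$n_medium + cfg$n_glass))
  expect_lt(max(abs(i2 / i1 - 2)) / 2, 5 * s_over_r)
  expect_error(compute_ipsf_image(cfg, -5), "particle_z")
  expect_error(compute_ipsf_image(cfg, 5, image_size = 40L), "odd")
})

test_that("central contrast oscillates at the lambda/(2 n_m) carrier", {
  c2 <- optical_config(focal_plane_z = 0)
  z <- seq(3000, 5000, by = 1)
  sc <- scatterer_amplitude(c2, 40)
  E <- vapply(z, function(zp)
    ipsf_field_radial(c2, 0, zp, scatterer = sc), complex(1))
  C <- ispt3d:::.contrast_of(ispt3d:::.pupil(c2), E)
  period <- estimate_period(z, C)
  expect_lt(abs(period - 515 / (2 * 1.33)) / (515 / (2 * 1.33)), 0.02)
})

test_that("radial averaging matches a per-pixel brute-force oracle", {
  set.seed(42)
  img <- matrix(rnorm(31 * 31), 31)
  px <- 100
  rp <- radial_average(img, center = c(14.3, 15.8), n_bins = 12,
                       r_max = 1200, pixel_size = px)
  bf <- bf_radial_average(img, c(14.3, 15.8), 12, 1200, px)
  nonempty <- bf$counts > 0
  expect_equal(rp$values[nonempty], bf$values[nonempty], tolerance = 1e-12)
  expect_equal(rp$counts, bf$counts)

  # constant image -> all bins equal the constant
  rp2 <- radial_average(matrix(3.5, 21, 21), n_bins = 8, r_max = 10, pixel_size = 1)
  expect_equal(rp2$values, rep(3.5, 8))

  # ring of ones at radius 10 px peaks in the bin containing r = 10
  n <- 41
  d <- sqrt(outer(((0:40) - 20)^2, ((0:40) - 20)^2, "+"))
  ring <- (abs(d - 10) <= 0.5) * 1
  rp3 <- radial_average(ring, center = c(20, 20), n_bins = 20, r_max = 20,
                        pixel_size = 1)
  expect_equal(which.max(rp3$values), 11L) # bin [10, 11)

  expect_error(radial_average(img, center = c(15, 15), n_bins = 10,
                              r_max = 5000, pixel_size = px), "edge")
})

test_that("model stack rows reproduce rendered images and carry the fringe
           structure", {
  stack <- build_model_stack(cfg, 4500, 5000, 1, image_size = 61L, n_bins = 30L)
  # row equals compute_ipsf_image + radial_average (re-sampled identically)
  img <- compute_ipsf_image(cfg, 4700, image_size = 61L)
  rp <- radial_average(img, n_bins = 30L, r_max = 30 * cfg$pixel_size,
                       pixel_size = cfg$pixel_size)
  row <- ispt3d:::.recenter_profile(rp$mean_radii, rp$values, rp$radii)
  expect_lt(max(abs(row - stack$profiles[201, ])), 1e-6)

  # self correlation of every row is exactly 1
  for (i in c(1, 250, 501))
    expect_equal(bf_pearson(stack$profiles[i, ], stack$profiles[i, ]), 1)

  # rows one carrier period apart stay strongly correlated
  per <- 515 / (2 * 1.33)
  r1 <- stack$profiles[1, ]
  r2 <- stack$profiles[1 + round(per), ]
  expect_gt(bf_pearson(r1, r2), 0.9)
})

test_that("the stack is asymmetric about the focal plane", {
  stack <- build_model_stack(cfg, 2200, 4200, 1, image_size = 61L, n_bins = 30L)
  zf <- 3200
  for (dz in c(600, 800, 1000)) {
    a <- stack$profiles[which(stack$z_grid == zf + dz), ]
    b <- stack$profiles[which(stack$z_grid == zf - dz), ]
    expect_lt(bf_pearson(a, b), 1 - 1e-3)
  }
})

test_that("global stack Pearson matches the direct formula", {
  set.seed(7)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(12), 3, 4)
  expect_equal(stack_pearson(A, B), bf_pearson(A, B), tolerance = 1e-12)
  expect_equal(stack_pearson(A, A), 1)
  expect_equal(stack_pearson(A, -A), -1)
  expect_error(stack_pearson(matrix(1, 2, 2), A[1:2, 1:2]), "variance")
  expect_error(stack_pearson(A, B[, 1:3]), "shape")
})

test_that("calibration recovers on-grid truth and shows the index-compensation
           ridge", {
  base <- test_config()
  zfs <- seq(-1500, 1500, by = 250)
  radii <- (1:25 - 0.5) * base$pixel_size
  truth <- model_focal_stack(base, zfs, radii, particle_z = 20)
  ngs <- base$n_glass + c(-2e-3, 0, 2e-3)
  nos <- base$n_oil + c(-2e-3, 0, 2e-3)
  cal <- calibrate_model(truth, list(n_glass = ngs, n_oil = nos), base)
  expect_equal(cal$best$n_glass, base$n_glass)
  expect_equal(cal$best$n_oil, base$n_oil)
  expect_equal(cal$max_correlation, 1.0, tolerance = 1e-12)

  # the correlation surface falls off slower along n_g + n_o = const
  surf <- cal$correlation[, , 1]
  along_anti <- min(surf[1, 3], surf[3, 1])
  along_diag <- max(surf[1, 1], surf[3, 3])
  expect_gt(along_anti, along_diag)

  # with shot noise the recovered optimum stays within one grid step
  set.seed(11)
  noisy <- truth + matrix(rnorm(length(truth), sd = 6.56e-3), nrow(truth))
  attributes(noisy) <- attributes(truth)
  cal2 <- calibrate_model(noisy, list(n_glass = ngs, n_oil = nos), base)
  expect_lte(abs(cal2$best$n_glass - base$n_glass), 2e-3)
  expect_lte(abs(cal2$best$n_oil - base$n_oil), 2e-3)
})
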