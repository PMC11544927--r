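# Localization-error studies: axial error versus focal plane and height,
# versus shot noise (axial against lateral), and versus a deliberate lateral
# center offset. These reproduce, at configurable scale, the robustness
# analyses of the tracking algorithm.

# Gaussian pixel noise of sd sigma, azimuthally averaged into annulus bins of
# n_k pixels, is exactly Gaussian per bin with sd sigma/sqrt(n_k) and
# independent across bins (disjoint pixel sets). The profile-level studies
# exploit this identity instead of rendering full frames per realization.
.bin_noise <- function(sigma, counts) rnorm(length(counts), sd = sigma / sqrt(pmax(counts, 1L)))

#' Axial localization error versus focal plane and particle height
#'
#' For a laterally fixed particle (no lateral localization error) and a fixed
#' shot-noise level, generates `n_realizations` noisy radial profiles per
#' (z_f, z_p) cell, localizes each frame-wise against the model stack of that
#' focal plane, and reports the standard deviation of the recovered-minus-true
#' height per cell together with the grand mean over the grid.
#'
#' @param config an [optical_config()]
#' @param z_f_values focal-plane positions (nm)
#' @param z_p_values particle heights (nm)
#' @param sigma_n normalized shot-noise standard deviation
#' @param n_realizations noise realizations per cell
#' @param seed RNG seed
#' @param diameter particle diameter (nm)
#' @param z_margin stack margin beyond the height range (nm)
#' @param z_step stack grid step (nm)
#' @param image_size,n_bins rendering size (px) and radial bins of the
#'   profiles; the defaults use the full radial extent of a 128 px frame
#'   about its center, as a fixed-particle cross-section provides
#' @return an `error_study`: list with `grid` (data frame z_f, z_p, sd_nm,
#'   n_used), `grand_mean` (nm), `failures`
#' @export
axial_error_study <- function(config,
                              z_f_values = seq(-2000, 2000, by = 1000),
                              z_p_values = seq(250, 3750, by = 500),
                              sigma_n = shot_noise_sigma(camera_config()),
                              n_realizations = 100L, seed = 1L,
                              diameter = 40, z_margin = 400, z_step = 1,
                              image_size = 121L, n_bins = 60L) {
  set.seed(seed)
  sc <- scatterer_amplitude(config, diameter)
  rows <- list()
  failures <- 0L
  for (zf in z_f_values) {
    cfg <- config
    cfg$focal_plane_z <- zf
    stack <- build_model_stack(cfg, max(0, min(z_p_values) - z_margin),
                               max(z_p_values) + z_margin, z_step,
                               image_size = image_size, n_bins = n_bins,
                               r_max = n_bins * config$pixel_size,
                               scatterer = sc)
    for (zp in z_p_values) {
      row <- which.min(abs(stack$z_grid - zp))
      z_true <- stack$z_grid[row]
      clean <- stack$profiles[row, ]
      errs <- vapply(seq_len(n_realizations), function(q) {
        prof <- clean + .bin_noise(sigma_n, stack$bin_counts)
        loc <- localize_profile(prof, stack)
        if (is.na(loc$z)) NA_real_ else loc$z - z_true
      }, numeric(1))
      bad <- sum(is.na(errs))
      failures <- failures + bad
      rows[[length(rows) + 1L]] <-
        data.frame(z_f = zf, z_p = z_true, sd_nm = sd(errs[!is.na(errs)]),
                   n_used = n_realizations - bad)
    }
  }
  grid <- do.call(rbind, rows)
  structure(list(grid = grid, grand_mean = mean(grid$sd_nm),
                 failures = failures, sigma_n = sigma_n, seed = seed),
            class = "error_study")
}

# render a laterally fixed axial z-ramp as a noiseless contrast video
.render_ramp <- function(config, z_values, scatterer, image_size, center_px) {
  px <- config$pixel_size
  p <- .pupil(config)
  xs <- (0:(image_size - 1)) * px
  rmat <- sqrt(outer((xs - center_px[2] * px)^2, (xs - center_px[1] * px)^2, "+"))
  arr <- array(0, dim = c(image_size, image_size, length(z_values)))
  for (i in seq_along(z_values)) {
    fine <- .field_fine(config, z_values[i], config$focal_plane_z, scatterer,
                        max(rmat) + 2 * px)
    arr[, , i] <- matrix(.contrast_of(p, .field_interp(fine, as.vector(rmat))),
                         image_size, image_size)
  }
  contrast_video(arr, frame_interval = NA_real_,
                 provenance = "background_corrected", pixel_size = px)
}

#' Lateral and axial localization error versus shot noise
#'
#' Simulates a particle moving linearly along the optical axis through
#' `z_p_range` (laterally fixed, focal plane from the configuration), adds
#' pixel noise at each level, localizes laterally with the radial variance
#' transform, extracts radial profiles about the estimated centers and runs
#' the full graph-based axial tracker. Reports RMS lateral and axial errors
#' per noise level, averaged over the height range.
#'
#' The ramp step is kept below a quarter of the interferometric fringe period
#' so that correlation-map stripes link between consecutive frames.
#'
#' @param config an [optical_config()]; its `focal_plane_z` is used
#' @param sigma_levels normalized shot-noise standard deviations
#' @param z_p_range height range c(min, max) (nm)
#' @param n_steps ramp frames per realization
#' @param n_realizations noise realizations per level
#' @param seed RNG seed
#' @param diameter particle diameter (nm)
#' @param image_size frame side (px)
#' @param n_bins,r_max profile binning (see [extract_profiles()])
#' @param z_step stack grid step (nm)
#' @return data frame: `sigma_n`, `lateral_rms_nm`, `axial_rms_nm`
#' @export
noise_sweep_study <- function(config, sigma_levels = c(1e-3, 3.43e-3, 1.18e-2),
                              z_p_range = c(40, 8000), n_steps = 200L,
                              n_realizations = 1L, seed = 1L, diameter = 40,
                              image_size = 128L, n_bins = 40L, r_max = NULL,
                              z_step = 1) {
  set.seed(seed)
  px <- config$pixel_size
  sc <- scatterer_amplitude(config, diameter)
  if (is.null(r_max)) r_max <- n_bins * px
  z_values <- seq(z_p_range[1], z_p_range[2], length.out = n_steps)
  z_values <- round(z_values / z_step) * z_step
  stack <- build_model_stack(config, max(0, z_p_range[1] - 400),
                             z_p_range[2] + 400, z_step,
                             n_bins = n_bins, r_max = r_max, scatterer = sc)
  c0 <- floor(image_size / 2)
  clean <- .render_ramp(config, z_values, sc, image_size, c(c0, c0))
  out <- lapply(sigma_levels, function(sig) {
    lat2 <- c(); axi2 <- c()
    for (q in seq_len(n_realizations)) {
      noisy <- clean
      noisy$frames <- clean$frames +
        array(rnorm(length(clean$frames), sd = sig), dim = dim(clean$frames))
      lat <- track_lateral(noisy, start_guess = c(c0, c0))
      prof <- extract_profiles(noisy, lat, n_bins = n_bins, r_max = r_max)
      ax <- track_axial(prof, stack)
      zr <- .subpixel_refine_frames(noisy, cbind(lat$x_px, lat$y_px), ax$z_nm,
                                    config, sc, n_bins = n_bins, r_max = r_max,
                                    z_step = z_step)
      zfit <- ifelse(is.finite(zr), zr, ax$z_nm)
      lat2 <- c(lat2, ((lat$x_px - c0)^2 + (lat$y_px - c0)^2) * px^2)
      axi2 <- c(axi2, (zfit - z_values)^2)
    }
    data.frame(sigma_n = sig,
               lateral_rms_nm = sqrt(mean(lat2, na.rm = TRUE)),
               axial_rms_nm = sqrt(mean(axi2, na.rm = TRUE)))
  })
  do.call(rbind, out)
}

#' Mean absolute axial error versus lateral-center offset
#'
#' With zero shot noise, simulates a linear axial ramp, extracts radial
#' profiles about a center deliberately displaced from the true iPSF center,
#' runs the full graph-based axial tracker, and reports the mean absolute
#' height error over the ramp for each offset. Quantifies how lateral
#' localization error corrupts the azimuthal average and thus the axial
#' assignment.
#'
#' @param config an [optical_config()]; its `focal_plane_z` is used
#' @param offsets lateral center offsets (nm)
#' @param z_p_range height range c(min, max) (nm)
#' @param n_steps ramp frames
#' @param diameter particle diameter (nm)
#' @param image_size frame side (px)
#' @param n_bins,r_max profile binning
#' @param z_step stack grid step (nm)
#' @return data frame: `offset_nm`, `mean_abs_error_nm`
#' @export
lateral_offset_study <- function(config, offsets = seq(0, 150, by = 25),
                                 z_p_range = c(40, 8000), n_steps = 200L,
                                 diameter = 40, image_size = 128L,
                                 n_bins = 40L, r_max = NULL, z_step = 1) {
  px <- config$pixel_size
  sc <- scatterer_amplitude(config, diameter)
  if (is.null(r_max)) r_max <- n_bins * px
  z_values <- seq(z_p_range[1], z_p_range[2], length.out = n_steps)
  z_values <- round(z_values / z_step) * z_step
  stack <- build_model_stack(config, max(0, z_p_range[1] - 400),
                             z_p_range[2] + 400, z_step,
                             n_bins = n_bins, r_max = r_max, scatterer = sc)
  c0 <- floor(image_size / 2)
  clean <- .render_ramp(config, z_values, sc, image_size, c(c0, c0))
  res <- matrix(NA_real_, length(z_values), length(offsets))
  for (io in seq_along(offsets)) {
    ctr <- data.frame(x_px = rep(c0 + offsets[io] / px, length(z_values)),
                      y_px = rep(c0, length(z_values)))
    prof <- extract_profiles(clean, ctr, n_bins = n_bins, r_max = r_max)
    ax <- track_axial(prof, stack)
    res[, io] <- abs(ax$z_nm - z_values)
  }
  data.frame(offset_nm = offsets,
             mean_abs_error_nm = colMeans(res, na.rm = TRUE))
}
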