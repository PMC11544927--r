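#' Build a radial iPSF model stack over particle heights
#'
#' Computes the modeled azimuthally averaged radial contrast profile
#' RP_m(z_p, r) on a uniform z grid, for the focal plane of the configuration.
#' Each row equals the radial average of the model contrast image at that
#' height, using the exact pixel-radius binning of a centered odd image (so a
#' rendered, noiseless frame at a grid height reproduces the row).
#'
#' Stacks are deterministic for a fixed configuration and are the expensive
#' reusable object of the pipeline; see [model_stack_cached()] for a keyed
#' disk cache.
#'
#' @param config an [optical_config()]
#' @param z_min,z_max z_p range (nm), `z_min < z_max`, `z_min >= 0`
#' @param z_step grid spacing (nm); 1 nm is the reference sampling
#' @param image_size odd rendering size (px) defining the pixel binning
#' @param n_bins number of radial bins (default: one per pixel of radius)
#' @param r_max outer radius (nm); default `n_bins` pixels
#' @param scatterer complex scatterer amplitude
#' @param focal_z focal plane (nm); default from config
#' @return a `radial_model_stack`: list with `z_grid`, `radii`, `profiles`
#'   (length(z_grid) x length(radii)), `z_step`, `bin_counts`, `config`,
#'   `focal_z`, `scatterer`
#' @export
build_model_stack <- function(config, z_min, z_max, z_step = 1,
                              image_size = 81L, n_bins = 40L, r_max = NULL,
                              scatterer = scatterer_amplitude(config),
                              focal_z = config$focal_plane_z) {
  stopifnot(inherits(config, "optical_config"))
  .assert(z_min < z_max, "z_min must be smaller than z_max")
  .assert(z_min >= 0, "z_min must be >= 0")
  .assert(z_step > 0, "z_step must be positive")
  if (is.null(r_max)) r_max <- n_bins * config$pixel_size
  z_grid <- seq(z_min, z_max, by = z_step)
  bn <- .center_binning(image_size, config$pixel_size, n_bins, r_max)
  E <- .field_stack(config, z_grid, bn$unique_radii, focal_z, scatterer)
  p <- .pupil(config)
  profiles <- .contrast_of(p, E) %*% bn$W
  profiles <- t(apply(profiles, 1, .recenter_profile,
                      mean_r = bn$mean_radii, centers = bn$radii))
  structure(list(z_grid = z_grid, radii = bn$radii, profiles = profiles,
                 z_step = z_step, bin_counts = bn$counts,
                 image_size = as.integer(image_size),
                 config = config, focal_z = focal_z, scatterer = scatterer),
            class = "radial_model_stack")
}

#' @export
print.radial_model_stack <- function(x, ...) {
  cat(sprintf("<radial_model_stack> %d heights [%g, %g] nm (step %g), %d radii <= %.0f nm, z_f = %g nm\n",
              length(x$z_grid), min(x$z_grid), max(x$z_grid), x$z_step,
              length(x$radii), max(x$radii) + x$radii[1], x$focal_z))
  invisible(x)
}

#' Global Pearson correlation between two profile stacks
#'
#' Pearson correlation over all matrix entries, used to compare a measured
#' focal stack with a modeled one during calibration.
#'
#' @param stack_a,stack_b matrices (or `radial_model_stack` objects) of equal
#'   shape
#' @return correlation in `[-1, 1]`
#' @export
stack_pearson <- function(stack_a, stack_b) {
  a <- if (inherits(stack_a, "radial_model_stack")) stack_a$profiles else as.matrix(stack_a)
  b <- if (inherits(stack_b, "radial_model_stack")) stack_b$profiles else as.matrix(stack_b)
  .assert(all(dim(a) == dim(b)), "stacks must have identical shapes")
  av <- as.vector(a); bv <- as.vector(b)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("undefined correlation: a stack has zero variance", call. = FALSE)
  cor(av, bv)
}

#' Model radial profiles over a focal-plane scan
#'
#' The calibration measurement keeps the particle at a fixed height (its
#' radius, sitting on the coverslip) and scans the focal plane. This helper
#' generates the corresponding model stack: one radial profile per focal
#' position, evaluated at the given radii.
#'
#' @param config an [optical_config()]
#' @param z_f_grid focal-plane positions (nm)
#' @param radii radial sample points (nm)
#' @param particle_z fixed particle height (nm), typically the particle radius
#' @param scatterer complex scatterer amplitude
#' @return matrix, `length(z_f_grid)` x `length(radii)`, with attributes
#'   `z_f_grid`, `radii`, `particle_z`
#' @export
model_focal_stack <- function(config, z_f_grid, radii, particle_z = 20,
                              scatterer = scatterer_amplitude(config)) {
  p <- .pupil(config)
  base <- p$w * p$A * p$k / p$N0 * scatterer *
    exp(1i * (p$W_ab + p$k0 * particle_z * p$carrier_coef))
  Jb <- t(besselJ(outer(radii, p$k * p$k0), 0) * rep(base, each = length(radii)))
  Ph <- exp(1i * outer(z_f_grid, -p$k0 * (config$n_oil / config$n_medium) * p$czo))
  structure(.contrast_of(p, Ph %*% Jb),
            z_f_grid = z_f_grid, radii = radii, particle_z = particle_z)
}

#' Calibrate model parameters against a measured focal stack
#'
#' Grid search over coverslip index n_g, oil index n_o and glass thickness t_g
#' maximizing the global Pearson correlation between the measured focal-scan
#' stack and the model ([model_focal_stack()]). The correlation surface
#' typically shows a ridge along n_g + n_o ~ const: what matters most is the
#' total phase accumulated in glass and oil, so an increase in one index can be
#' compensated by a decrease in the other.
#'
#' @param measured_stack matrix of measured radial profiles (focal positions x
#'   radii), e.g. a [model_focal_stack()] output or an experimental equivalent
#' @param search_grid named list with numeric vectors `n_glass`, `n_oil` and
#'   optionally `t_glass`
#' @param config base [optical_config()] supplying all other parameters
#' @param z_f_grid focal positions of the measured rows (nm); defaults to the
#'   `z_f_grid` attribute of `measured_stack`
#' @param radii radial sample points (nm); defaults to the `radii` attribute
#' @param particle_z fixed particle height (nm); defaults to the attribute or
#'   20 nm
#' @return list with `best` (named list n_glass, n_oil, t_glass),
#'   `correlation` (array over the grid), `max_correlation`, and the grids
#' @export
calibrate_model <- function(measured_stack, search_grid, config,
                            z_f_grid = attr(measured_stack, "z_f_grid"),
                            radii = attr(measured_stack, "radii"),
                            particle_z = attr(measured_stack, "particle_z") %||% 20) {
  .assert(!is.null(z_f_grid) && !is.null(radii),
          "z_f_grid and radii must be supplied (or attached to measured_stack)")
  ng <- search_grid$n_glass %||% config$n_glass
  no <- search_grid$n_oil %||% config$n_oil
  tg <- search_grid$t_glass %||% config$t_glass
  .assert(length(ng) > 0 && length(no) > 0 && length(tg) > 0, "grids must be nonempty")
  surf <- array(NA_real_, dim = c(length(ng), length(no), length(tg)),
                dimnames = list(n_glass = ng, n_oil = no, t_glass = tg))
  sc <- scatterer_amplitude(config)
  for (it in seq_along(tg)) for (io in seq_along(no)) for (ig in seq_along(ng)) {
    cfg <- config
    cfg$n_glass <- ng[ig]; cfg$n_oil <- no[io]; cfg$t_glass <- tg[it]
    val <- tryCatch({
      m <- model_focal_stack(cfg, z_f_grid, radii, particle_z, sc)
      stack_pearson(measured_stack, m)
    }, error = function(e) {
      warning(sprintf("grid point (n_g=%g, n_o=%g, t_g=%g) skipped: %s",
                      ng[ig], no[io], tg[it], conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    surf[ig, io, it] <- val
  }
  best <- which(surf == max(surf, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(best = list(n_glass = ng[best[1]], n_oil = no[best[2]], t_glass = tg[best[3]]),
       max_correlation = max(surf, na.rm = TRUE),
       correlation = surf,
       grids = list(n_glass = ng, n_oil = no, t_glass = tg))
}
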