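# Scalar angular-spectrum engine for the interferometric PSF.
#
# The scattered field of a point dipole at height z_p above the water--glass
# interface is written as a pupil integral over the conserved transverse
# refractive index kappa = n sin(theta) (kappa <= min(NA, n_m); supercritical
# collection angles carry no propagating far field from the particle):
#
#   E_sca(r) = s / N0 * Int_0^kmax A(kappa) J0(k0 kappa r) exp(i Phi(kappa)) kappa dkappa
#
# with aplanatic apodization sqrt(cos theta_o), Fresnel amplitude transmission
# through the water-glass and glass-oil interfaces, and the phase
#
#   Phi = k0 [ z_p (n_m + sqrt(n_m^2 - kappa^2))            carrier + return path
#            - z_f (n_o/n_m) sqrt(n_o^2 - kappa^2)          defocus (focus at z_p = z_f)
#            + t_g sqrt(n_g^2-kappa^2) - t_g* sqrt(n_g*^2-kappa^2)
#            + L_oil (sqrt(n_o^2-kappa^2) - sqrt(n_o*^2-kappa^2)) ]   aberration
#
# The reference field is the plane-wave Fresnel reflection at the water--glass
# interface, r = (n_m - n_g)/(n_m + n_g), carrying the on-axis (kappa = 0)
# aberration phase. N0 normalizes the in-focus, aberration-free on-axis
# amplitude to |s|, so the scatterer amplitude is expressed relative to the
# incident field.

.pupil_key <- function(config) {
  config_hash(config[c("wavelength", "numerical_aperture", "n_medium", "n_glass",
                       "n_oil", "t_glass", "design_n_glass", "design_t_glass",
                       "design_n_oil", "oil_path", "n_nodes")])
}

.pupil <- function(config) {
  key <- paste0("pupil_", .pupil_key(config))
  hit <- .ispt_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (config$numerical_aperture >= config$n_oil)
    stop("invalid aperture: NA must be smaller than n_oil", call. = FALSE)
  kmax <- min(config$numerical_aperture, config$n_medium)
  gl <- pracma::gaussLegendre(config$n_nodes, 0, kmax)
  k <- gl$x
  w <- gl$w
  k0 <- 2 * pi / config$wavelength
  czm <- sqrt(config$n_medium^2 - k^2)
  czg <- sqrt(config$n_glass^2 - k^2)
  czo <- sqrt(config$n_oil^2 - k^2)
  czgd <- sqrt(config$design_n_glass^2 - k^2)
  czod <- sqrt(config$design_n_oil^2 - k^2)
  t_wg <- 2 * czm / (czm + czg)
  t_go <- 2 * czg / (czg + czo)
  A <- sqrt(czo / config$n_oil) * t_wg * t_go
  W_ab <- k0 * (config$t_glass * czg - config$design_t_glass * czgd +
                  config$oil_path * (czo - czod))
  p <- list(
    k = k, w = w, k0 = k0, czm = czm, czo = czo, A = A, W_ab = W_ab,
    N0 = sum(w * A * k),
    carrier_coef = config$n_medium + czm,
    ref_amp = (config$n_medium - config$n_glass) / (config$n_medium + config$n_glass),
    ref_phase = k0 * (config$t_glass * config$n_glass -
                        config$design_t_glass * config$design_n_glass +
                        config$oil_path * (config$n_oil - config$design_n_oil)))
  .ispt_cache[[key]] <- p
  p
}

.ref_field <- function(p) p$ref_amp * exp(1i * p$ref_phase)

# contrast image/profile from a complex scattered field (vector/matrix)
.contrast_of <- function(p, Es) {
  Er <- .ref_field(p)
  (Mod(Es)^2 + 2 * Re(Es * Conj(Er))) / Mod(Er)^2
}

# per-node integrand weight for a given (z_p, z_f) and complex scatterer s
.pupil_weights <- function(p, config, particle_z, focal_z, scatterer) {
  ph <- p$k0 * particle_z * p$carrier_coef -
    p$k0 * focal_z * (config$n_oil / config$n_medium) * p$czo + p$W_ab
  p$w * p$A * p$k * (scatterer * exp(1i * ph)) / p$N0
}

#' Scattered iPSF field at given radial distances
#'
#' Evaluates the complex scattered field of a point scatterer at height
#' `particle_z` above the coverslip, at radial distances `radii` from the iPSF
#' center in the sample plane, for a focal plane at `focal_z`. Exact Bessel
#' evaluation; intended for model building and tests. See the package vignette
#' for the model.
#'
#' @param config an [optical_config()]
#' @param radii radial distances from the iPSF center (nm)
#' @param particle_z particle height z_p above the interface (nm, >= 0)
#' @param focal_z focal-plane position z_f (nm); defaults to the config value
#' @param scatterer complex scattered-field amplitude (see
#'   [scatterer_amplitude()])
#' @return complex vector of field values, same length as `radii`
#' @export
ipsf_field_radial <- function(config, radii, particle_z,
                              focal_z = config$focal_plane_z,
                              scatterer = scatterer_amplitude(config)) {
  stopifnot(inherits(config, "optical_config"))
  .assert(particle_z >= 0, "particle_z must be >= 0 (particle in the medium)")
  p <- .pupil(config)
  g <- .pupil_weights(p, config, particle_z, focal_z, scatterer)
  J <- besselJ(outer(radii, p$k * p$k0), 0)
  as.vector(J %*% g)
}

# field stack over a z_p grid at fixed radii: one complex GEMM.
# Returns a length(z_grid) x length(radii) complex matrix.
.field_stack <- function(config, z_grid, radii, focal_z, scatterer,
                         block = 2500L) {
  p <- .pupil(config)
  base <- p$w * p$A * p$k / p$N0 * scatterer *
    exp(1i * (p$W_ab - p$k0 * focal_z * (config$n_oil / config$n_medium) * p$czo))
  Jb <- t(besselJ(outer(radii, p$k * p$k0), 0) * rep(base, each = length(radii)))
  out <- matrix(0i, length(z_grid), length(radii))
  i <- 1L
  while (i <= length(z_grid)) {
    j <- min(i + block - 1L, length(z_grid))
    Ph <- exp(1i * outer(z_grid[i:j], p$k0 * p$carrier_coef))
    out[i:j, ] <- Ph %*% Jb
    i <- j + 1L
  }
  out
}

# complex field on a fine radial grid (step = pixel/8), cached Bessel table
.field_fine <- function(config, particle_z, focal_z, scatterer, r_max) {
  dr <- config$pixel_size / 8
  n_fine <- ceiling(r_max / dr) + 4L
  key <- paste0("jfine_", .pupil_key(config), "_", n_fine)
  p <- .pupil(config)
  Jf <- .ispt_cache[[key]]
  r_fine <- (seq_len(n_fine) - 1) * dr
  if (is.null(Jf)) {
    Jf <- besselJ(outer(r_fine, p$k * p$k0), 0)
    .ispt_cache[[key]] <- Jf
  }
  g <- .pupil_weights(p, config, particle_z, focal_z, scatterer)
  list(r = r_fine, E = as.vector(Jf %*% g))
}

# spline-interpolated complex field at arbitrary radii, given a fine table
.field_interp <- function(fine, radii) {
  complex(real = spline(fine$r, Re(fine$E), xout = radii)$y,
          imaginary = spline(fine$r, Im(fine$E), xout = radii)$y)
}
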