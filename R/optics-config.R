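#' Optical configuration of the iSCAT imaging system
#'
#' Collects every optical and sample parameter entering the interferometric
#' point-spread-function (iPSF) model: vacuum wavelength, numerical aperture,
#' refractive indices of the sample medium (water), coverslip glass and
#' immersion oil, the coverslip thickness, the design (nominal) values the
#' objective is corrected for, the pixel pitch referred to the sample plane and
#' the signed focal-plane position `focal_plane_z` measured from the
#' water--glass interface upward into the water.
#'
#' All lengths are in nanometers. Defaults reproduce a high-NA oil-immersion
#' iSCAT setup at 515 nm with the calibrated glass/oil indices
#' (n_g = 1.52696, n_o = 1.51833, t_g = 170 um) and a 128 px field of view
#' covering 13 um (pixel pitch 13000/128 nm).
#'
#' The scatterer is parameterized by its complex refractive index
#' (`particle_index`, default gold at 515 nm); the scattered-field amplitude
#' follows from the Rayleigh polarizability (see [scatterer_amplitude()]).
#'
#' @param wavelength vacuum wavelength (nm)
#' @param numerical_aperture objective NA; must be < `n_oil`
#' @param n_medium refractive index of the sample medium (water)
#' @param n_glass,n_oil actual coverslip and immersion-oil indices
#' @param t_glass actual coverslip thickness (nm)
#' @param design_n_glass,design_t_glass,design_n_oil nominal values the
#'   objective is aberration-corrected for
#' @param oil_path nominal immersion-oil path length (nm) over which an oil
#'   index deviation accumulates phase
#' @param pixel_size sample-plane pixel pitch (nm/px)
#' @param focal_plane_z signed focal-plane position z_f (nm) relative to the
#'   water--glass interface
#' @param n_nodes number of Gauss--Legendre nodes for the pupil integral
#' @param particle_index complex refractive index of the particle material
#'   (default: gold at 515 nm)
#' @param collection_efficiency multiplicative factor on the scattered
#'   amplitude for non-ideal optical transmission (1 = ideal)
#' @return an object of class `optical_config`
#' @export
optical_config <- function(wavelength = 515,
                           numerical_aperture = 1.4,
                           n_medium = 1.33,
                           n_glass = 1.52696,
                           n_oil = 1.51833,
                           t_glass = 170e3,
                           design_n_glass = 1.5255,
                           design_t_glass = 170e3,
                           design_n_oil = 1.518,
                           oil_path = 130e3,
                           pixel_size = 13000 / 128,
                           focal_plane_z = 0,
                           n_nodes = 256L,
                           particle_index = complex(real = 0.50, imaginary = 2.10),
                           collection_efficiency = 1) {
  .assert(wavelength > 0, "wavelength must be positive")
  .assert(numerical_aperture > 0, "numerical aperture must be positive")
  .assert(numerical_aperture < n_oil,
          "invalid aperture: NA must be smaller than the immersion-oil index")
  .assert(all(c(n_medium, n_glass, n_oil, design_n_glass, design_n_oil) > 1),
          "all refractive indices must exceed 1")
  .assert(pixel_size > 0, "pixel_size must be positive")
  .assert(t_glass > 0 && design_t_glass > 0, "glass thickness must be positive")
  .assert(n_nodes >= 16, "n_nodes must be at least 16")
  cfg <- list(
    wavelength = wavelength, numerical_aperture = numerical_aperture,
    n_medium = n_medium, n_glass = n_glass, n_oil = n_oil, t_glass = t_glass,
    design_n_glass = design_n_glass, design_t_glass = design_t_glass,
    design_n_oil = design_n_oil, oil_path = oil_path,
    pixel_size = pixel_size, focal_plane_z = focal_plane_z,
    n_nodes = as.integer(n_nodes), particle_index = particle_index,
    collection_efficiency = collection_efficiency)
  class(cfg) <- "optical_config"
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  lambda = %g nm, NA = %g, n_m = %g, n_g = %g, n_o = %g\n",
              x$wavelength, x$numerical_aperture, x$n_medium, x$n_glass, x$n_oil))
  cat(sprintf("  t_g = %g um (design %g um, n_g* = %g, n_o* = %g)\n",
              x$t_glass / 1e3, x$design_t_glass / 1e3, x$design_n_glass, x$design_n_oil))
  cat(sprintf("  pixel = %.4g nm, z_f = %g nm, pupil nodes = %d\n",
              x$pixel_size, x$focal_plane_z, x$n_nodes))
  invisible(x)
}

#' Interferometric field amplitudes
#'
#' The two field amplitudes of the homodyne iSCAT detection relative to the
#' incident field -- the reference reflectivity r and the scattered amplitude
#' s -- together with their phase difference phi.
#'
#' @param ref_amplitude |E_ref|/|E_inc| (>= 0)
#' @param sca_amplitude |E_sca|/|E_inc| (>= 0)
#' @param phase_diff phase difference phi between E_ref and E_sca (rad)
#' @return an object of class `field_amplitudes`
#' @export
field_amplitudes <- function(ref_amplitude, sca_amplitude, phase_diff = 0) {
  .assert(ref_amplitude >= 0, "ref_amplitude must be >= 0")
  .assert(sca_amplitude >= 0, "sca_amplitude must be >= 0")
  structure(list(ref_amplitude = ref_amplitude, sca_amplitude = sca_amplitude,
                 phase_diff = phase_diff),
            class = "field_amplitudes")
}

#' iSCAT contrast of a homodyne field pair
#'
#' The detected intensity is |E_ref + E_sca|^2; normalizing to the reference
#' intensity I_ref = |E_ref|^2 gives the contrast
#' C = (I_det - I_ref)/I_ref = (s^2 + 2 r s cos(phi)) / r^2.
#'
#' @param amps a [field_amplitudes()] object
#' @return the dimensionless, signed contrast C
#' @examples
#' ipsf_contrast(field_amplitudes(1, 0.1, 0))    # 0.21
#' ipsf_contrast(field_amplitudes(1, 0.1, pi))   # -0.19
#' @export
ipsf_contrast <- function(amps) {
  stopifnot(inherits(amps, "field_amplitudes"))
  r <- amps$ref_amplitude
  s <- amps$sca_amplitude
  if (r == 0) stop("no reference field: ref_amplitude is zero", call. = FALSE)
  (s^2 + 2 * r * s * cos(amps$phase_diff)) / r^2
}

#' Scatterer field amplitude of a Rayleigh particle
#'
#' First-principles scattered-field amplitude (relative to the incident
#' field) of a subwavelength sphere imaged in focus: the Rayleigh
#' polarizability alpha = 4 pi a^3 (eps_p - eps_m)/(eps_p + 2 eps_m)
#' (complex, carrying the scattering phase -- near-plasmonic for gold at
#' 515 nm), refocused by the collection optics with the scalar Debye factor
#' of the model's own pupil (apodization and interface transmissions
#' included):
#'
#'   s = (k_m^3 alpha / 4 pi) * (N0 / n_m^2) * collection_efficiency
#'
#' with k_m the wavenumber in the medium and N0 the pupil's amplitude
#' integral. For a 40 nm gold particle this gives |s|/r ~ 1, i.e. an order-one
#' peak in-focus contrast relative to the weak water--glass reference
#' reflection.
#'
#' @param config an [optical_config()]
#' @param diameter particle diameter (nm)
#' @return a complex scalar amplitude
#' @export
scatterer_amplitude <- function(config, diameter = 40) {
  stopifnot(inherits(config, "optical_config"))
  p <- .pupil(config)
  a <- diameter / 2
  eps_p <- config$particle_index^2
  eps_m <- config$n_medium^2
  alpha <- 4 * pi * a^3 * (eps_p - eps_m) / (eps_p + 2 * eps_m)
  k_m <- 2 * pi * config$n_medium / config$wavelength
  (k_m^3 * alpha / (4 * pi)) * (p$N0 / config$n_medium^2) *
    config$collection_efficiency
}
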