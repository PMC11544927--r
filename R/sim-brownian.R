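#' Camera configuration
#'
#' @param full_well electrons per pixel at saturation
#' @param frame_rate frames per second (Hz)
#' @param exposure exposure time (s); defaults to the frame interval
#' @param background_fill fraction of the full well used by the reference
#'   level (1 = background at saturation)
#' @return a `camera_config`
#' @export
camera_config <- function(full_well = 23200, frame_rate = 1e5,
                          exposure = NULL, background_fill = 1) {
  exposure <- exposure %||% (1 / frame_rate)
  .assert(full_well > 0, "full_well must be positive")
  .assert(exposure <= 1 / frame_rate + 1e-12, "exposure cannot exceed the frame interval")
  .assert(background_fill > 0 && background_fill <= 1,
          "background_fill must be in (0, 1]")
  structure(list(full_well = full_well, frame_rate = frame_rate,
                 exposure = exposure, background_fill = background_fill),
            class = "camera_config")
}

#' Normalized shot-noise standard deviation
#'
#' Photon (shot) noise on the reference-normalized intensity. With N_e
#' electrons collected per pixel at the reference level, Poisson statistics
#' give a relative standard deviation of 1/sqrt(N_e). A 23,200-electron full
#' well at saturation yields sigma_n = 6.56e-3.
#'
#' @param camera a [camera_config()]
#' @return normalized noise standard deviation (dimensionless)
#' @export
shot_noise_sigma <- function(camera) {
  stopifnot(inherits(camera, "camera_config"))
  ne <- camera$full_well * camera$background_fill
  if (ne < 1) stop("effective electron count must be >= 1", call. = FALSE)
  1 / sqrt(ne)
}

#' Per-axis Brownian step standard deviation
#'
#' Displacements of a freely diffusing particle between frames separated by
#' `dt` are normally distributed per axis with standard deviation
#' sqrt(2 D dt).
#'
#' @param D diffusion coefficient (um^2/s)
#' @param dt time interval (s)
#' @return step standard deviation in nm
#' @export
brownian_step_sigma <- function(D, dt) {
  .assert(D >= 0, "D must be >= 0")
  .assert(dt > 0, "dt must be positive")
  1e3 * sqrt(2 * D * dt)
}

#' Stokes--Einstein diffusion coefficient
#'
#' D = k_B T / (3 pi eta d) for a sphere of hydrodynamic diameter d.
#'
#' @param diameter hydrodynamic diameter (nm)
#' @param temperature temperature (K)
#' @param viscosity dynamic viscosity (Pa s); default water at 297 K
#' @return diffusion coefficient (um^2/s)
#' @export
stokes_einstein_D <- function(diameter, temperature = 297,
                              viscosity = 0.911e-3) {
  .assert(diameter > 0 && temperature > 0 && viscosity > 0,
          "all arguments must be positive")
  kB <- 1.380649e-23
  d_m <- diameter * 1e-9
  D_m2s <- kB * temperature / (3 * pi * viscosity * d_m)
  D_m2s * 1e12
}

#' Simulate a 3D Brownian trajectory
#'
#' I.i.d. Gaussian increments per axis with standard deviation sqrt(2 D dt);
#' the axial coordinate is reflected at the coverslip (z = 0) and the lateral
#' coordinates at the walls of `lateral_bounds`, via the standard folding map
#' of the unconstrained walk.
#'
#' A warning is emitted when the per-frame axial step scale exceeds an eighth
#' of the interferometric fringe period lambda/(2 n) -- the regime where
#' correlation-map stripes may no longer link between consecutive frames.
#'
#' @param D diffusion coefficient (um^2/s)
#' @param dt frame interval (s)
#' @param n_frames number of frames (>= 2)
#' @param start length-3 start position (x, y, z) in nm, z >= 0
#' @param seed optional RNG seed for reproducibility
#' @param lateral_bounds c(xmin, xmax, ymin, ymax) reflecting box (nm), or NULL
#' @param diameter particle diameter (nm), stored as metadata
#' @param fringe_period interferometric fringe period lambda/(2 n) used for
#'   the linking-validity warning (nm)
#' @return a `trajectory3d`: data frame with columns `frame`, `t`, `x`, `y`,
#'   `z` (nm) and metadata attributes
#' @export
simulate_trajectory <- function(D, dt, n_frames, start = c(0, 0, 0),
                                seed = NULL, lateral_bounds = NULL,
                                diameter = NA_real_,
                                fringe_period = 515 / (2 * 1.33)) {
  .assert(n_frames >= 2, "n_frames must be >= 2")
  .assert(start[3] >= 0, "start z must be >= 0")
  if (!is.null(lateral_bounds)) {
    .assert(start[1] >= lateral_bounds[1] && start[1] <= lateral_bounds[2] &&
              start[2] >= lateral_bounds[3] && start[2] <= lateral_bounds[4],
            "start must lie inside lateral_bounds")
  }
  if (!is.null(seed)) set.seed(seed)
  sig <- brownian_step_sigma(D, dt)
  if (sig > fringe_period / 4)
    warning(sprintf(paste0("per-frame step sd (%.1f nm) exceeds an eighth of the ",
                           "fringe period lambda/(2n) (%.1f nm); stripe linking ",
                           "between frames may fail"), sig, fringe_period / 4),
            call. = FALSE)
  n <- as.integer(n_frames)
  steps <- matrix(rnorm(3 * (n - 1), sd = sig), ncol = 3)
  cs <- apply(steps, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = 3)
  pos <- rbind(start, sweep(cs, 2, start, "+"))
  pos[, 3] <- .reflect_floor(pos[, 3])
  if (!is.null(lateral_bounds)) {
    pos[, 1] <- .reflect(pos[, 1], lateral_bounds[1], lateral_bounds[2])
    pos[, 2] <- .reflect(pos[, 2], lateral_bounds[3], lateral_bounds[4])
  }
  out <- data.frame(frame = seq_len(n), t = (seq_len(n) - 1) * dt,
                    x = pos[, 1], y = pos[, 2], z = pos[, 3])
  rownames(out) <- NULL
  structure(out, D = D, dt = dt, diameter = diameter, seed = seed,
            class = c("trajectory3d", "data.frame"))
}
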