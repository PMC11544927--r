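#' Construct a contrast video object
#'
#' @param frames 3D array (height x width x frames) of pixel values
#' @param frame_interval time between frames (s)
#' @param provenance one of `"raw"`, `"normalized"`, `"background_corrected"`
#' @param pixel_size nm per pixel
#' @return a `contrast_video`
#' @export
contrast_video <- function(frames, frame_interval,
                           provenance = c("raw", "normalized", "background_corrected"),
                           pixel_size = NA_real_) {
  provenance <- match.arg(provenance)
  .assert(length(dim(frames)) == 3, "frames must be a height x width x time array")
  structure(list(frames = frames, frame_interval = frame_interval,
                 provenance = provenance, pixel_size = pixel_size),
            class = "contrast_video")
}

#' @export
print.contrast_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<contrast_video> %d frames of %dx%d px, dt = %g s, %s\n",
              d[3], d[1], d[2], x$frame_interval, x$provenance))
  invisible(x)
}

.video_nframes <- function(video) dim(video$frames)[3]

#' Render a synthetic iSCAT contrast video of a diffusing particle
#'
#' Renders the model iPSF at each frame's true (x, y, z) position (exact in z,
#' dense radial spline in r) and adds white Gaussian noise of standard
#' deviation [shot_noise_sigma()] to every pixel of the normalized contrast
#' frames -- the Gaussian limit of photon shot noise at large electron counts.
#'
#' Positions are in nm with the image origin at pixel (0, 0); the field of
#' view spans `image_size * pixel_size` nm per side. Optional motion blur:
#' with `blur_substeps = m`, consecutive groups of m trajectory frames are
#' rendered and averaged into one output frame (simulate the trajectory at
#' `dt/m` accordingly).
#'
#' @param traj a [simulate_trajectory()] result (positions in nm)
#' @param config an [optical_config()]
#' @param camera a [camera_config()] providing the noise level, or NULL for a
#'   noiseless render
#' @param noise_seed RNG seed for the noise stream
#' @param image_size frame side length (px)
#' @param diameter particle diameter (nm) for the scattering amplitude;
#'   defaults to the trajectory metadata or 40 nm
#' @param scatterer complex amplitude overriding `diameter`
#' @param blur_substeps trajectory frames averaged per output frame
#' @param z_max_render maximum supported height (nm); frames beyond raise an
#'   error naming the frame
#' @return a `contrast_video` with provenance `"background_corrected"`
#' @export
render_video <- function(traj, config, camera = NULL, noise_seed = NULL,
                         image_size = 128L, diameter = NULL, scatterer = NULL,
                         blur_substeps = 1L, z_max_render = 40e3) {
  stopifnot(inherits(config, "optical_config"))
  n <- nrow(traj)
  px <- config$pixel_size
  fov <- image_size * px
  .assert(all(traj$x >= 0 & traj$x < fov & traj$y >= 0 & traj$y < fov),
          "trajectory lateral positions must lie inside the field of view")
  bad <- which(traj$z < 0 | traj$z > z_max_render)
  if (length(bad) > 0)
    stop(sprintf("particle z out of rendering range at frame %d (z = %.1f nm)",
                 bad[1], traj$z[bad[1]]), call. = FALSE)
  if (is.null(scatterer)) {
    d <- diameter %||% attr(traj, "diameter")
    if (is.null(d) || is.na(d)) d <- 40
    scatterer <- scatterer_amplitude(config, d)
  }
  p <- .pupil(config)
  m <- as.integer(blur_substeps)
  n_out <- n %/% m
  .assert(n_out >= 1, "fewer trajectory frames than blur substeps")
  xs <- (0:(image_size - 1)) * px
  r_need <- sqrt(2) * fov + 2 * px
  out <- array(0, dim = c(image_size, image_size, n_out))
  for (i in seq_len(n)) {
    fine <- .field_fine(config, traj$z[i], config$focal_plane_z, scatterer, r_need)
    rmat <- sqrt(outer((xs - traj$y[i])^2, (xs - traj$x[i])^2, "+"))
    Em <- .field_interp(fine, as.vector(rmat))
    fr <- matrix(.contrast_of(p, Em), image_size, image_size)
    k <- (i - 1L) %/% m + 1L
    if (k <= n_out) out[, , k] <- out[, , k] + fr / m
  }
  if (!is.null(camera)) {
    sig <- shot_noise_sigma(camera)
    if (!is.null(noise_seed)) set.seed(noise_seed)
    out <- out + array(rnorm(length(out), sd = sig), dim = dim(out))
  }
  contrast_video(out, frame_interval = attr(traj, "dt") * m,
                 provenance = "background_corrected", pixel_size = px)
}
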