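#' Full 3D tracking of a contrast video
#'
#' Convenience composition of the pipeline on a background-corrected contrast
#' video: lateral localization ([track_lateral()]), radial-profile extraction
#' ([extract_profiles()]), and axial tracking against a model stack
#' ([track_axial()]). Returns one row per frame with both lateral and axial
#' coordinates.
#'
#' @param video a `contrast_video` (provenance `"background_corrected"`)
#' @param config an [optical_config()] (its `focal_plane_z` must match the
#'   recording)
#' @param stack a `radial_model_stack`, or NULL to build one over `z_range`
#' @param z_range c(z_min, z_max) height range of interest (nm) when `stack`
#'   is NULL
#' @param diameter particle diameter (nm) for the model stack amplitude
#' @param n_bins,r_max profile binning (defaults: 40 one-pixel bins)
#' @param cache_dir stack cache directory (NULL disables caching)
#' @param start_guess optional (x, y) 0-based px prior for the first frame
#' @param subpixel_refine logical; re-bin the model with each frame's
#'   sub-pixel center fraction and re-refine the height in a narrow window
#'   (removes the annulus-sampling systematic near the focal plane)
#' @param ... further arguments passed to [track_lateral()]
#' @return a data frame `frame`, `t`, `x_nm`, `y_nm`, `z_nm`, `peak_rho`,
#'   `branch`, `segment`, `confidence`, with the `axial_track` attached as
#'   attribute `axial`
#' @export
track_video <- function(video, config, stack = NULL, z_range = NULL,
                        diameter = 40, n_bins = 40L, r_max = NULL,
                        cache_dir = file.path(tempdir(), "ispt3d_cache"),
                        start_guess = NULL, subpixel_refine = TRUE, ...) {
  stopifnot(inherits(video, "contrast_video"))
  if (is.null(stack)) {
    .assert(!is.null(z_range), "either a model stack or z_range must be given")
    stack <- model_stack_cached(config, z_range[1], z_range[2], 1,
                                cache_dir = cache_dir,
                                n_bins = n_bins,
                                r_max = r_max %||% (n_bins * config$pixel_size),
                                scatterer = scatterer_amplitude(config, diameter))
  }
  lat <- track_lateral(video, start_guess = start_guess, ...)
  prof <- extract_profiles(video, lat, n_bins = n_bins, r_max = r_max)
  ax <- track_axial(prof, stack)
  if (subpixel_refine) {
    zr <- .subpixel_refine_frames(video, cbind(lat$x_px, lat$y_px), ax$z_nm,
                                  stack$config, stack$scatterer,
                                  n_bins = n_bins,
                                  r_max = r_max %||% (n_bins * config$pixel_size),
                                  z_step = stack$z_step)
    ax$z_nm <- ifelse(is.finite(zr), zr, ax$z_nm)
  }
  out <- data.frame(frame = lat$frame,
                    t = (lat$frame - 1) * video$frame_interval,
                    x_nm = lat$x_nm, y_nm = lat$y_nm, z_nm = ax$z_nm,
                    peak_rho = ax$peak_rho, branch = ax$branch,
                    segment = ax$segment, confidence = lat$confidence)
  attr(out, "axial") <- ax
  out
}
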