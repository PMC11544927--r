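#' Lateral localization of every frame of a video
#'
#' Runs [rvt_localize()] frame by frame. From the second frame on, the search
#' is restricted to a window around the previous detection, which both speeds
#' up the transform and enforces temporal continuity. Missing detections are
#' linearly interpolated across gaps of at most `max_gap` frames; longer gaps
#' leave NA centers (those frames are dropped from profile extraction).
#'
#' @param video a `contrast_video` of contrast frames
#' @param r_min,r_max RVT ring radii (px)
#' @param search_halfwidth search window half-width (px) around the previous
#'   center; NULL searches the full frame every time
#' @param start_guess optional (x, y) 0-based px prior for frame 1
#' @param confidence_floor see [rvt_localize()]
#' @param max_gap longest detection gap (frames) bridged by interpolation
#' @return a `lateral_track` data frame: `frame`, `x_px`, `y_px`, `x_nm`,
#'   `y_nm`, `confidence`, `detected`
#' @export
track_lateral <- function(video, r_min = 2L, r_max = 25L,
                          search_halfwidth = 6, start_guess = NULL,
                          confidence_floor = 0, max_gap = 5L) {
  stopifnot(inherits(video, "contrast_video"))
  n <- .video_nframes(video)
  px <- video$pixel_size
  d <- dim(video$frames)
  r_max <- min(r_max, floor(min(d[1], d[2]) / 2) - 1L) # rings must fit the frame
  out <- data.frame(frame = seq_len(n), x_px = NA_real_, y_px = NA_real_,
                    confidence = NA_real_, detected = FALSE)
  guess <- start_guess
  for (i in seq_len(n)) {
    loc <- rvt_localize(video$frames[, , i], r_min, r_max,
                        center_guess = guess,
                        search_halfwidth = if (is.null(guess)) NULL else search_halfwidth,
                        confidence_floor = confidence_floor)
    out$confidence[i] <- loc$confidence
    if (loc$ok) {
      out$x_px[i] <- loc$x; out$y_px[i] <- loc$y
      out$detected[i] <- TRUE
      guess <- c(loc$x, loc$y)
    }
  }
  miss <- which(!out$detected)
  if (length(miss) > 0 && any(out$detected)) {
    runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
    ok <- which(out$detected)
    for (g in runs) {
      if (length(g) <= max_gap && min(g) > 1 && max(g) < n) {
        out$x_px[g] <- approx(ok, out$x_px[ok], xout = g)$y
        out$y_px[g] <- approx(ok, out$y_px[ok], xout = g)$y
      }
    }
  }
  out$x_nm <- out$x_px * px
  out$y_nm <- out$y_px * px
  structure(out, pixel_size = px, class = c("lateral_track", "data.frame"))
}

#' Extract per-frame radial iPSF profiles along a lateral track
#'
#' Row i is the azimuthal average of frame i about its sub-pixel center. All
#' rows share the same radial grid; when a center sits too close to the image
#' edge for `r_max`, the affected outer bins of that frame are NA and the
#' effective radius is recorded.
#'
#' @param video a `contrast_video`
#' @param track a `lateral_track` (or data frame with `x_px`, `y_px`)
#' @param n_bins number of radial bins
#' @param r_max outer radius (nm); default `n_bins` pixels
#' @return a `radial_profile_series`: list with `profiles` (frames x bins),
#'   `radii` (nm), `effective_r_max` per frame, `track`
#' @export
extract_profiles <- function(video, track, n_bins = 40L, r_max = NULL) {
  stopifnot(inherits(video, "contrast_video"))
  n <- .video_nframes(video)
  .assert(nrow(track) == n, "track must cover all frames")
  px <- video$pixel_size
  if (is.null(r_max)) r_max <- n_bins * px
  d <- dim(video$frames)
  width <- r_max / n_bins
  radii <- (seq_len(n_bins) - 0.5) * width
  prof <- matrix(NA_real_, n, n_bins)
  eff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cx <- track$x_px[i]; cy <- track$y_px[i]
    if (!is.finite(cx) || !is.finite(cy)) next
    edge <- (min(cx, d[2] - 1 - cx, cy, d[1] - 1 - cy) + 0.5) * px
    rm_i <- min(r_max, edge)
    eff[i] <- rm_i
    nb_i <- floor(rm_i / width)
    if (nb_i < 2) next
    rp <- radial_average(video$frames[, , i], center = c(cx, cy),
                         n_bins = nb_i, r_max = nb_i * width, pixel_size = px)
    prof[i, seq_len(nb_i)] <- .recenter_profile(rp$mean_radii, rp$values,
                                                rp$radii)
  }
  structure(list(profiles = prof, radii = radii, effective_r_max = eff,
                 track = track, frame_interval = video$frame_interval),
            class = "radial_profile_series")
}

#' @export
print.radial_profile_series <- function(x, ...) {
  cat(sprintf("<radial_profile_series> %d frames x %d radii (r <= %.0f nm)\n",
              nrow(x$profiles), length(x$radii), max(x$radii)))
  invisible(x)
}
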