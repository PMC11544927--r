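#' Normalize each frame to its total power
#'
#' Divides every frame by the sum of its pixel values and rescales by the
#' median frame sum, removing global illumination-power fluctuations while
#' keeping pixel values at their original scale. Scale-invariant: multiplying
#' a frame by a positive constant leaves its normalized version unchanged
#' (the median reference sum is insensitive to single-frame fluctuations).
#'
#' @param video a `contrast_video` of raw counts (provenance `"raw"`)
#' @return a `contrast_video` with provenance `"normalized"`
#' @export
normalize_frame_power <- function(video) {
  stopifnot(inherits(video, "contrast_video"))
  n <- .video_nframes(video)
  sums <- apply(video$frames, 3, sum)
  zero <- which(sums <= 0)
  if (length(zero) > 0)
    stop(sprintf("frame %d has nonpositive total counts", zero[1]), call. = FALSE)
  out <- sweep(video$frames, 3, sums / median(sums), "/")
  contrast_video(out, video$frame_interval, "normalized", video$pixel_size)
}

#' Temporal median background correction
#'
#' For every pixel, subtracts the rolling temporal median over `window` frames
#' and divides by it, converting a normalized intensity video into contrast
#' C = (I - I_ref) / I_ref. Edge frames use truncated windows. With
#' `window = "all"` a single full-video median per pixel is used -- appropriate
#' for synthetic videos with a stationary background.
#'
#' @param video a `contrast_video` (raw or normalized intensities)
#' @param window odd window length >= 3, or `"all"`
#' @return a `contrast_video` with provenance `"background_corrected"`
#' @export
temporal_median_background <- function(video, window = 101L) {
  stopifnot(inherits(video, "contrast_video"))
  d <- dim(video$frames)
  n <- d[3]
  flat <- matrix(video$frames, d[1] * d[2], n)
  if (identical(window, "all")) {
    med <- matrix(apply(flat, 1, median), d[1] * d[2], n)
  } else {
    window <- as.integer(window)
    .assert(window %% 2 == 1 && window >= 3 && window <= n,
            "window must be odd, >= 3 and <= the frame count")
    med <- t(apply(flat, 1, .runmed_truncated, k = window))
  }
  if (any(med <= 0))
    stop("nonpositive temporal median encountered: invalid reference level",
         call. = FALSE)
  out <- array((flat - med) / med, dim = d)
  contrast_video(out, video$frame_interval, "background_corrected", video$pixel_size)
}

# rolling median with truncated windows at the edges
.runmed_truncated <- function(x, k) {
  n <- length(x)
  if (k >= n) return(rep(median(x), n))
  m <- stats::runmed(x, k, endrule = "keep")
  h <- (k - 1L) %/% 2L
  for (i in seq_len(h)) {
    m[i] <- median(x[1:(i + h)])
    m[n - i + 1L] <- median(x[(n - i + 1L - h):n])
  }
  m
}
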