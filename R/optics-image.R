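# Image-domain iPSF evaluation and radial profiles.
#
# Image coordinates are 0-based; pixel (i, j) sits at (x, y) = (j, i) * pixel
# in sample-plane nm (x = column, y = row). For odd image sizes the center
# pixel is (floor(W/2), floor(H/2)).

# pixel-center coordinates (nm) for an H x W image
.pixel_xy <- function(image_size, pixel) {
  n <- image_size
  list(x = (0:(n - 1)) * pixel, y = (0:(n - 1)) * pixel)
}

#' Compute a model iPSF contrast image
#'
#' Renders the circularly symmetric contrast image of a point scatterer at
#' height `particle_z`, laterally displaced by `lateral_offset` (nm) from the
#' image center pixel. The field is evaluated exactly on the set of distinct
#' pixel radii (or via a dense radial spline when `method = "spline"`, accurate
#' to ~1e-7 relative).
#'
#' @param config an [optical_config()]
#' @param particle_z particle height above the interface (nm, >= 0)
#' @param lateral_offset length-2 (x, y) offset from the center pixel (nm)
#' @param scatterer complex scatterer amplitude
#' @param image_size odd image side length (px)
#' @param focal_z focal-plane position (nm); default from config
#' @param method `"exact"` for per-radius Bessel evaluation, `"spline"` for
#'   the fast dense-grid interpolation used by the video renderer
#' @return a `contrast_image`: a matrix of contrast values with attributes
#'   `center` (x, y in px, 0-based) and `pixel_size`
#' @export
compute_ipsf_image <- function(config, particle_z, lateral_offset = c(0, 0),
                               scatterer = scatterer_amplitude(config),
                               image_size = 81L,
                               focal_z = config$focal_plane_z,
                               method = c("exact", "spline")) {
  stopifnot(inherits(config, "optical_config"))
  method <- match.arg(method)
  .assert(particle_z >= 0, "particle_z must be >= 0")
  .assert(image_size %% 2 == 1, "image_size must be odd so a center pixel exists")
  n <- as.integer(image_size)
  px <- config$pixel_size
  c0 <- floor(n / 2)
  cx <- c0 * px + lateral_offset[1]
  cy <- c0 * px + lateral_offset[2]
  xy <- .pixel_xy(n, px)
  # distance of each pixel center from the particle's lateral position
  dx2 <- (xy$x - cx)^2
  dy2 <- (xy$y - cy)^2
  rmat <- sqrt(outer(dy2, dx2, "+")) # rows = y, cols = x
  p <- .pupil(config)
  if (method == "exact") {
    rr <- round(rmat, 6)
    ur <- sort(unique(as.vector(rr)))
    E <- ipsf_field_radial(config, ur, particle_z, focal_z, scatterer)
    Emat <- matrix(E[match(as.vector(rr), ur)], n, n)
  } else {
    fine <- .field_fine(config, particle_z, focal_z, scatterer, max(rmat))
    Emat <- matrix(.field_interp(fine, as.vector(rmat)), n, n)
  }
  img <- .contrast_of(p, Emat)
  structure(img, center = c(cx, cy) / px, pixel_size = px,
            class = c("contrast_image", class(img)))
}

#' Azimuthal average of an image about a sub-pixel center
#'
#' Bins pixels by their center distance from `center` into `n_bins` annuli of
#' equal width `r_max / n_bins` and averages the pixel values in each annulus.
#' Empty bins are filled by linear interpolation from neighboring bins and
#' flagged in the `empty_bins` attribute.
#'
#' @param image numeric matrix (rows = y, cols = x)
#' @param center length-2 sub-pixel center (x, y) in 0-based pixel units;
#'   defaults to the image's `center` attribute or the central pixel
#' @param n_bins number of radial bins
#' @param r_max outer radius (nm); must not exceed the distance from the
#'   center to the nearest image edge
#' @param pixel_size nm per pixel (taken from the image attribute if present)
#' @return a `radial_profile`: list with `radii` (bin centers, nm), `values`
#'   (plain bin means), `counts` (pixels per bin) and `mean_radii` (mean pixel
#'   distance per bin; for sub-pixel centers the effective sampling radius of
#'   a bin deviates from its nominal center, and profile consumers re-sample
#'   onto the nominal grid to stay comparable with model profiles)
#' @export
radial_average <- function(image, center = NULL, n_bins = 40L, r_max = NULL,
                           pixel_size = attr(image, "pixel_size") %||% 1) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(center)) center <- attr(image, "center") %||% c(floor(nc / 2), floor(nr / 2))
  .assert(center[1] >= 0 && center[1] <= nc - 1 && center[2] >= 0 && center[2] <= nr - 1,
          "center must lie inside the image")
  edge_px <- min(center[1], nc - 1 - center[1], center[2], nr - 1 - center[2])
  if (is.null(r_max)) r_max <- edge_px * pixel_size
  if (r_max > (edge_px + 0.5) * pixel_size)
    stop("r_max exceeds the distance from the center to the nearest image edge",
         call. = FALSE)
  dx2 <- ((0:(nc - 1)) - center[1])^2
  dy2 <- ((0:(nr - 1)) - center[2])^2
  rmat <- sqrt(outer(dy2, dx2, "+")) * pixel_size
  width <- r_max / n_bins
  bin <- floor(as.vector(rmat) / width) + 1L
  keep <- bin >= 1L & bin <= n_bins
  sums <- rep(0, n_bins); cnts <- rep(0L, n_bins); rsum <- rep(0, n_bins)
  t1 <- tapply(as.vector(image)[keep], bin[keep], sum)
  idx <- as.integer(names(t1))
  sums[idx] <- t1
  rsum[idx] <- tapply(as.vector(rmat)[keep], bin[keep], sum)
  cnts[idx] <- tabulate(bin[keep], nbins = n_bins)[idx]
  centers <- (seq_len(n_bins) - 0.5) * width
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
  mean_r <- ifelse(cnts > 0, rsum / pmax(cnts, 1L), centers)
  empty <- which(cnts == 0L)
  if (length(empty) > 0 && length(empty) < n_bins) {
    ok <- which(cnts > 0L)
    vals[empty] <- approx(ok, vals[ok], xout = empty, rule = 2)$y
  }
  structure(list(radii = centers, values = vals, counts = cnts,
                 mean_radii = mean_r),
            empty_bins = empty, class = "radial_profile")
}

# radial bin weights for a centered odd image: maps the vector of distinct
# pixel radii to n_bins annulus means with pixel multiplicities. Shared by
# build_model_stack so model rows equal radial_average(compute_ipsf_image())
# bit-for-bit in exact arithmetic.
.center_binning <- function(image_size, pixel, n_bins, r_max) {
  n <- as.integer(image_size)
  c0 <- floor(n / 2)
  d2 <- ((0:(n - 1)) - c0)^2
  rmat <- sqrt(outer(d2, d2, "+")) * pixel
  rr <- round(rmat, 6)
  ur <- sort(unique(as.vector(rr)))
  pix_of <- match(as.vector(rr), ur)
  width <- r_max / n_bins
  bin <- floor(as.vector(rmat) / width) + 1L
  keep <- bin >= 1L & bin <= n_bins
  # weight matrix W: length(ur) x n_bins, column b = multiplicity/count
  cnt <- tabulate(bin[keep], nbins = n_bins)
  W <- matrix(0, length(ur), n_bins)
  tab <- table(pix_of[keep], bin[keep])
  W[cbind(as.integer(rownames(tab))[row(tab)], as.integer(colnames(tab))[col(tab)])] <-
    as.vector(tab)
  W <- sweep(W, 2, pmax(cnt, 1L), "/")
  centers <- (seq_len(n_bins) - 0.5) * width
  mean_r <- as.vector(ur %*% W)
  mean_r[cnt == 0] <- centers[cnt == 0]
  list(unique_radii = ur, W = W, counts = cnt, radii = centers,
       mean_radii = mean_r)
}

# re-sample a binned profile from its effective (mean pixel distance) radii
# onto the nominal bin centers; removes the center-fraction-dependent radial
# shift of annulus binning
.recenter_profile <- function(mean_r, values, centers) {
  approx(mean_r, values, xout = centers, rule = 2)$y
}
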