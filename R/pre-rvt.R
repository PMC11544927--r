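# Radial variance transform (RVT) lateral localization.
#
# For each candidate center c the transform takes the azimuthal mean mu_r(c)
# of the image on rings of integer radius r in [r_min, r_max], and computes
#
#   V(c) = Var_r[ mu_r(c) ] - mean_r[ azimuthal variance at r ]
#
# V peaks at centers of radially symmetric patterns such as the iPSF: the
# first term rewards strong radial structure, the second penalizes azimuthal
# asymmetry. Rings are sets of integer pixel offsets with round(|offset|) = r;
# pixels outside the image count as zeros (zero-padding convention). The
# implementation evaluates all ring means by FFT cross-correlation.

.ring_offsets <- function(r) {
  s <- -(r + 1):(r + 1)
  g <- expand.grid(dy = s, dx = s)
  g[round(sqrt(g$dx^2 + g$dy^2)) == r, , drop = FALSE]
}

.rvt_kernels <- function(nr, nc, r_min, r_max) {
  key <- sprintf("rvt_%d_%d_%d_%d", nr, nc, r_min, r_max)
  hit <- .ispt_cache[[key]]
  if (!is.null(hit)) return(hit)
  P1 <- nextn(nr + 2 * r_max + 1)
  P2 <- nextn(nc + 2 * r_max + 1)
  radii <- r_min:r_max
  Fk <- vector("list", length(radii))
  counts <- integer(length(radii))
  Ksum <- matrix(0, P1, P2)
  for (ii in seq_along(radii)) {
    off <- .ring_offsets(radii[ii])
    K <- matrix(0, P1, P2)
    K[cbind(off$dy %% P1 + 1L, off$dx %% P2 + 1L)] <- 1
    counts[ii] <- nrow(off)
    Fk[[ii]] <- Conj(fft(K))
    Ksum <- Ksum + K / counts[ii]
  }
  out <- list(P1 = P1, P2 = P2, radii = radii, counts = counts,
              Fk = Fk, FkSum = Conj(fft(Ksum)))
  .ispt_cache[[key]] <- out
  out
}

#' Radial variance transform of a frame
#'
#' @param frame numeric matrix
#' @param r_min,r_max inner and outer ring radii (px), `r_min < r_max` and
#'   `r_max` less than half the image size
#' @return matrix of transform values, same shape as `frame`
#' @export
rvt_map <- function(frame, r_min = 2L, r_max = 25L) {
  nr <- nrow(frame); nc <- ncol(frame)
  .assert(r_min < r_max, "r_min must be smaller than r_max")
  .assert(r_max < min(nr, nc) / 2, "r_max must be below half the image size")
  kn <- .rvt_kernels(nr, nc, as.integer(r_min), as.integer(r_max))
  Ipad <- matrix(0, kn$P1, kn$P2)
  Ipad[1:nr, 1:nc] <- frame
  FI <- fft(Ipad)
  FI2 <- fft(Ipad^2)
  np <- kn$P1 * kn$P2
  S1 <- matrix(0, nr, nc); S2 <- matrix(0, nr, nc)
  for (ii in seq_along(kn$radii)) {
    mu <- Re(fft(FI * kn$Fk[[ii]], inverse = TRUE))[1:nr, 1:nc] / (np * kn$counts[ii])
    S1 <- S1 + mu
    S2 <- S2 + mu^2
  }
  S3 <- Re(fft(FI2 * kn$FkSum, inverse = TRUE))[1:nr, 1:nc] / np
  Nr <- length(kn$radii)
  (2 * S2 - S3) / Nr - (S1 / Nr)^2
}

#' Sub-pixel lateral localization via the radial variance transform
#'
#' Finds the peak of [rvt_map()] and refines it by quadratic interpolation of
#' the 3x3 neighborhood. Optionally restricts the peak search to a window
#' around a prior center estimate (e.g. the previous frame), which also crops
#' the transform input for speed.
#'
#' @param frame numeric matrix (a contrast frame)
#' @param r_min,r_max ring radii (px)
#' @param center_guess optional (x, y) prior center, 0-based px
#' @param search_halfwidth half-width of the peak search window (px) around
#'   `center_guess`
#' @param confidence_floor minimal peak z-score; below it the frame is flagged
#'   as a non-detection (`ok = FALSE`, coordinates NA)
#' @return list with `x`, `y` (0-based sub-pixel), `confidence`, `ok`
#' @export
rvt_localize <- function(frame, r_min = 2L, r_max = 25L, center_guess = NULL,
                         search_halfwidth = NULL, confidence_floor = 0) {
  nr <- nrow(frame); nc <- ncol(frame)
  x0 <- 0L; y0 <- 0L
  if (!is.null(center_guess) && !is.null(search_halfwidth)) {
    m <- as.integer(ceiling(search_halfwidth + r_max + 2))
    x0 <- max(0L, as.integer(round(center_guess[1])) - m)
    y0 <- max(0L, as.integer(round(center_guess[2])) - m)
    x1 <- min(nc - 1L, as.integer(round(center_guess[1])) + m)
    y1 <- min(nr - 1L, as.integer(round(center_guess[2])) + m)
    frame <- frame[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
    nr <- nrow(frame); nc <- ncol(frame)
  }
  V <- rvt_map(frame, r_min, r_max)
  if (!is.null(center_guess) && !is.null(search_halfwidth)) {
    gx <- center_guess[1] - x0; gy <- center_guess[2] - y0
    xr <- pmax(1, pmin(nc, round(gx + 1 + c(-1, 1) * search_halfwidth)))
    yr <- pmax(1, pmin(nr, round(gy + 1 + c(-1, 1) * search_halfwidth)))
    Vs <- V[yr[1]:yr[2], xr[1]:xr[2], drop = FALSE]
    pk <- which(Vs == max(Vs), arr.ind = TRUE)[1, ]
    pk <- c(pk[1] + yr[1] - 1L, pk[2] + xr[1] - 1L)
  } else {
    pk <- which(V == max(V), arr.ind = TRUE)[1, ]
  }
  conf <- (V[pk[1], pk[2]] - mean(V)) / sd(V)
  if (!is.finite(conf) || conf < confidence_floor)
    return(list(x = NA_real_, y = NA_real_, confidence = conf, ok = FALSE))
  # quadratic 3x3 sub-pixel refinement
  iy <- pk[1]; ix <- pk[2]
  sub <- c(0, 0)
  if (iy > 1 && iy < nr) {
    den <- V[iy - 1, ix] - 2 * V[iy, ix] + V[iy + 1, ix]
    if (den < 0) sub[2] <- 0.5 * (V[iy - 1, ix] - V[iy + 1, ix]) / den
  }
  if (ix > 1 && ix < nc) {
    den <- V[iy, ix - 1] - 2 * V[iy, ix] + V[iy, ix + 1]
    if (den < 0) sub[1] <- 0.5 * (V[iy, ix - 1] - V[iy, ix + 1]) / den
  }
  sub[!is.finite(sub)] <- 0
  sub <- pmax(-0.5, pmin(0.5, sub))
  list(x = ix - 1 + sub[1] + x0, y = iy - 1 + sub[2] + y0,
       confidence = conf, ok = TRUE)
}
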