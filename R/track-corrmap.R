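#' Correlation map between measured profiles and the model stack
#'
#' rho(i, z_p): Pearson correlation over radius between the radial profile of
#' frame i and the model profile at height z_p. The map is the central object
#' of axial tracking: the interferometric carrier makes it oscillate along z_p
#' with period lambda/(2 n_m), producing the characteristic striped pattern,
#' with near-mirror ambiguity about the focal plane broken by spherical
#' aberration and by the path search.
#'
#' Frames whose profile has zero variance (or no data) are flagged and carry
#' rho = 0 across all heights.
#'
#' A residual lateral localization error delta displaces the center of the
#' azimuthal average and low-pass filters the measured profile (each radius r
#' samples the pattern over sqrt(r^2 + delta^2 + 2 r delta cos(theta))). To
#' keep the height assignment robust against this known nuisance, the model
#' rows are additionally correlated in identically blurred variants
#' (`blur_offsets`, up to roughly the diffraction limit) and each map cell
#' keeps the best variant. An unblurred mirror-side profile can then no longer
#' outscore the blurred true side.
#'
#' @param profiles a `radial_profile_series` (or plain frames x radii matrix)
#' @param model a `radial_model_stack`
#' @param blur_offsets lateral-offset blur radii (nm) of the model variants;
#'   `0` disables the augmentation
#' @param weights optional per-radius weights for the correlation (NULL =
#'   uniform averaging over r). Weighting by the annulus pixel count
#'   (`model$bin_counts`) corresponds to correlating the azimuthally
#'   symmetrized images pixel by pixel and is matched to shot noise, whose
#'   bin variance scales as 1/count; [track_axial()] uses that weighting
#' @return a `correlation_map`: list with `rho` (frames x heights), `z_grid`,
#'   `flagged_frames`
#' @export
correlation_map <- function(profiles, model, blur_offsets = c(0, 75, 150),
                            weights = NULL) {
  stopifnot(inherits(model, "radial_model_stack"))
  P <- if (inherits(profiles, "radial_profile_series")) profiles$profiles else as.matrix(profiles)
  radii <- if (inherits(profiles, "radial_profile_series")) profiles$radii else model$radii
  M <- model$profiles
  if (length(radii) != length(model$radii) ||
      max(abs(radii - model$radii)) > 1e-6) {
    if (min(radii) < min(model$radii) - 1e-9 || max(radii) > max(model$radii) + 1e-9)
      stop("profile radii extend beyond the model stack's radial range", call. = FALSE)
    M <- t(apply(M, 1, function(v) approx(model$radii, v, xout = radii)$y))
  }
  n <- nrow(P)
  complete <- !apply(P, 1, anyNA)
  rho <- matrix(-1, n, nrow(M))
  flagged <- logical(n)
  w_full <- weights %||% rep(1, ncol(M))
  variants <- lapply(blur_offsets, function(d) {
    if (d <= 0) M else M %*% .blur_weight_matrix(radii, d)
  })
  for (Mv in variants) {
    sw <- sum(w_full)
    Ms <- Mv - as.vector(Mv %*% w_full) / sw
    Msd <- sqrt(as.vector((Ms * Ms) %*% w_full))
    if (any(complete)) {
      Pc <- P[complete, , drop = FALSE]
      Ps <- Pc - as.vector(Pc %*% w_full) / sw
      Psd <- sqrt(as.vector((Ps * Ps) %*% w_full))
      zerovar <- Psd == 0
      Psd[zerovar] <- 1
      rv <- (Ps %*% t(Ms * rep(w_full, each = nrow(Ms)))) / (Psd %o% Msd)
      rv[zerovar, ] <- 0
      flagged[which(complete)[zerovar]] <- TRUE
      rho[complete, ] <- pmax(rho[complete, , drop = FALSE], rv)
    }
    # frames with NA bins: correlation over the complete bins only
    for (i in which(!complete)) {
      ok <- !is.na(P[i, ])
      if (sum(ok) < 3) { flagged[i] <- TRUE; next }
      v <- P[i, ok]
      if (sd(v) == 0) { flagged[i] <- TRUE; next }
      w <- w_full[ok]
      v <- v - sum(w * v) / sum(w)
      Mi <- Mv[, ok, drop = FALSE]
      Mis <- Mi - as.vector(Mi %*% w) / sum(w)
      ri <- (Mis %*% (w * v)) /
        (sqrt(as.vector((Mis * Mis) %*% w)) * sqrt(sum(w * v^2)))
      rho[i, ] <- pmax(rho[i, ], as.vector(ri))
    }
  }
  rho[flagged, ] <- 0
  rho[!is.finite(rho)] <- 0
  structure(list(rho = rho, z_grid = model$z_grid, flagged_frames = which(flagged)),
            class = "correlation_map")
}

# linear operator approximating the lateral-offset blur of a radial profile:
# row k of the result samples the profile at sqrt(r_k^2 + d^2 + 2 r_k d cos t)
# averaged over t, expressed as interpolation weights on the radii grid
.blur_weight_matrix <- function(radii, delta, n_theta = 24L) {
  nb <- length(radii)
  W <- matrix(0, nb, nb)
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta # half circle by symmetry
  for (k in seq_len(nb)) {
    rp <- sqrt(radii[k]^2 + delta^2 + 2 * radii[k] * delta * cos(th))
    rp <- pmin(pmax(rp, radii[1]), radii[nb])
    j <- findInterval(rp, radii, rightmost.closed = TRUE)
    j <- pmin(j, nb - 1L)
    w2 <- (rp - radii[j]) / (radii[j + 1L] - radii[j])
    for (q in seq_len(n_theta)) {
      W[j[q], k] <- W[j[q], k] + (1 - w2[q]) / n_theta
      W[j[q] + 1L, k] <- W[j[q] + 1L, k] + w2[q] / n_theta
    }
  }
  W
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d frames x %d heights, rho in [%.3f, %.3f]\n",
              nrow(x$rho), ncol(x$rho), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Label connected regions of the correlation map
#'
#' Thresholds the map (at zero by default), labels 8-connected components of
#' the suprathreshold set, scores each region R_j by
#' S_j = sum over frames of the per-frame maximum of rho inside R_j, and
#' selects the region with the highest score. Ties are broken by larger pixel
#' count, then by smaller label.
#'
#' @param map a `correlation_map`
#' @param threshold global threshold (default 0)
#' @return a `region_labeling`: list with `labels` (frames x heights integer
#'   matrix, 0 = below threshold), `scores`, `sizes`, `n_regions`,
#'   `selected` (label of R_max), `mask` (logical matrix of R_max)
#' @export
label_regions <- function(map, threshold = 0) {
  stopifnot(inherits(map, "correlation_map"))
  res <- .label_regions_cpp(map$rho, threshold)
  if (res$n_regions == 0)
    stop("no region above threshold in the correlation map", call. = FALSE)
  ord <- order(-res$scores, -res$sizes, seq_along(res$scores))
  sel <- ord[1]
  structure(list(labels = res$labels, scores = res$scores, sizes = res$sizes,
                 n_regions = res$n_regions, selected = sel,
                 mask = res$labels == sel),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  cat(sprintf("<region_labeling> %d regions; selected #%d (score %.1f over %d px)\n",
              x$n_regions, x$selected, x$scores[x$selected], x$sizes[x$selected]))
  invisible(x)
}
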