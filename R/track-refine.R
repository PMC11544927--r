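#' Sub-grid axial refinement by adaptive polynomial fitting
#'
#' Fits a polynomial to the correlation values around the peak of a (branch-
#' restricted) correlation column and returns the location of its maximum,
#' constrained to the fit window. The polynomial degree adapts to the height
#' sampling: up to quartic for fine grids (step <= 5 nm), quadratic otherwise,
#' always capped at points - 1.
#'
#' @param rho correlation values versus height (single frame)
#' @param z_grid heights (nm), same length, uniformly spaced
#' @param window half-width of the fit window in grid points around the peak
#' @return list with `z` (refined height, nm), `degree`, `flag`
#'   (`"ok"`, `"unrefined"` for single-point input, `"degenerate"` for a flat
#'   column)
#' @export
refine_axial <- function(rho, z_grid, window = 10L) {
  n <- length(rho)
  .assert(n == length(z_grid), "rho and z_grid lengths differ")
  .assert(n >= 1, "winning branch must contain at least one grid point")
  if (n == 1L) return(list(z = z_grid[1], degree = 0L, flag = "unrefined"))
  if (max(rho) - min(rho) == 0) {
    mid <- (n + 1L) %/% 2L
    return(list(z = z_grid[mid], degree = 0L, flag = "degenerate"))
  }
  pk <- which.max(rho)
  sel <- max(1L, pk - window):min(n, pk + window)
  z_step <- z_grid[2] - z_grid[1]
  deg <- if (z_step <= 5) min(4L, length(sel) - 1L) else min(2L, length(sel) - 1L)
  # centered/scaled abscissa for conditioning
  u <- (z_grid[sel] - z_grid[pk]) / z_step
  co <- coef(lm(rho[sel] ~ poly(u, degree = deg, raw = TRUE)))
  co[is.na(co)] <- 0
  # stationary points of the fitted polynomial
  dcoef <- co[-1] * seq_len(deg)
  cand <- numeric(0)
  if (any(dcoef != 0)) {
    rts <- polyroot(dcoef)
    cand <- Re(rts)[abs(Im(rts)) < 1e-8]
  }
  lo <- min(u); hi <- max(u)
  cand <- c(cand[cand > lo & cand < hi], lo, hi)
  val <- vapply(cand, function(x) sum(co * x^(0:deg)), numeric(1))
  best <- cand[val >= max(val) - 1e-15]
  ustar <- min(best)  # deterministic: prefer the lower height on exact ties
  list(z = z_grid[pk] + ustar * z_step, degree = deg, flag = "ok")
}

#' Single-frame axial localization against a model stack
#'
#' Frame-wise estimator: Pearson-correlates one radial profile with every
#' model row, takes the global argmax and refines it with [refine_axial()].
#' Used by the localization-error studies; full trajectories should use
#' [track_axial()], which resolves stripe and focal-side ambiguities that
#' frame-wise assignment cannot.
#'
#' @param profile radial profile values (length = model radii)
#' @param model a `radial_model_stack`
#' @param window refinement window (grid points)
#' @param weights per-radius correlation weights; defaults to the annulus
#'   pixel counts (shot-noise matched), NULL for uniform
#' @return list with `z` (nm), `rho_max`, `flag`
#' @export
localize_profile <- function(profile, model, window = 10L,
                             weights = model$bin_counts) {
  M <- model$profiles
  w <- weights %||% rep(1, ncol(M))
  sw <- sum(w)
  v <- profile - sum(w * profile) / sw
  sv <- sqrt(sum(w * v^2))
  if (sv == 0) return(list(z = NA_real_, rho_max = NA_real_, flag = "degenerate"))
  Ms <- M - as.vector(M %*% w) / sw
  rho <- as.vector(Ms %*% (w * v)) / (sqrt(as.vector((Ms * Ms) %*% w)) * sv)
  pk <- which.max(rho)
  sel <- max(1L, pk - window):min(length(rho), pk + window)
  r <- refine_axial(rho[sel], model$z_grid[sel], window = window)
  list(z = r$z, rho_max = rho[pk], flag = r$flag)
}

#' Full axial tracking of a radial-profile series
#'
#' Composition of the tracker: correlation map, connected-region labeling and
#' selection, branch-graph construction, Dijkstra debranching, and per-frame
#' polynomial refinement inside the winning branch. Frames outside the
#' selected region (or flagged) carry NA and segment boundaries are reported.
#'
#' @param profiles a `radial_profile_series`
#' @param model a `radial_model_stack`
#' @param threshold correlation-map threshold for region labeling
#' @param window refinement window (grid points)
#' @param weights per-radius correlation weights; defaults to the annulus
#'   pixel counts (shot-noise matched), NULL for uniform (plain Pearson)
#' @param blur_offsets see [correlation_map()]
#' @return an `axial_track` data frame: `frame`, `z_nm`, `peak_rho`,
#'   `branch`, `segment`, `refine_flag`, with the `correlation_map` and
#'   `region_labeling` attached as attributes `map` and `labeling`
#' @export
track_axial <- function(profiles, model, threshold = 0, window = 10L,
                        weights = model$bin_counts,
                        blur_offsets = c(0, 75, 150)) {
  map <- correlation_map(profiles, model, blur_offsets = blur_offsets,
                         weights = weights)
  lab <- label_regions(map, threshold)
  gr <- build_branch_graph(map, lab)
  deb <- shortest_path_debranch(gr)
  n <- nrow(map$rho)
  out <- data.frame(frame = seq_len(n), z_nm = NA_real_, peak_rho = NA_real_,
                    branch = NA_integer_, segment = NA_integer_,
                    refine_flag = NA_character_)
  asn <- deb$assignment
  for (q in seq_len(nrow(asn))) {
    i <- asn$frame[q]
    sel <- asn$lo[q]:asn$hi[q]
    r <- refine_axial(map$rho[i, sel], map$z_grid[sel], window = window)
    out$z_nm[i] <- r$z
    out$peak_rho[i] <- asn$maxrho[q]
    out$branch[i] <- asn$branch[q]
    out$segment[i] <- asn$segment[q]
    out$refine_flag[i] <- r$flag
  }
  structure(out, map = map, labeling = lab, graph = gr,
            class = c("axial_track", "data.frame"))
}
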