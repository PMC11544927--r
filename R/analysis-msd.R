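#' Time-averaged mean squared displacement
#'
#' MSD(tau) per axis and in 3D for a uniformly sampled trajectory, averaged
#' over all start frames at each lag.
#'
#' @param traj a `trajectory3d` (or data frame with `x`, `y`, `z` in nm and
#'   uniform frame interval `dt` attribute or argument)
#' @param max_lag largest lag in frames; clipped (with a warning) to the
#'   trajectory length minus one
#' @param dt frame interval (s); defaults to the trajectory attribute
#' @return an `msd_curve`: data frame with `lag`, `tau` (s), `msd_x`, `msd_y`,
#'   `msd_z`, `msd_3d` (um^2) and `n_pairs`
#' @export
msd <- function(traj, max_lag = 100L, dt = attr(traj, "dt")) {
  n <- nrow(traj)
  .assert(n >= 10, "need at least 10 frames")
  .assert(!is.null(dt), "frame interval dt is required")
  if (max_lag >= n) {
    warning("max_lag clipped to trajectory length - 1", call. = FALSE)
    max_lag <- n - 1L
  }
  P <- as.matrix(traj[, c("x", "y", "z")]) / 1e3 # um
  lags <- seq_len(max_lag)
  res <- t(vapply(lags, function(L) {
    d <- P[(1 + L):n, , drop = FALSE] - P[1:(n - L), , drop = FALSE]
    m <- colMeans(d^2)
    c(m, sum(m), n - L)
  }, numeric(5)))
  out <- data.frame(lag = lags, tau = lags * dt,
                    msd_x = res[, 1], msd_y = res[, 2], msd_z = res[, 3],
                    msd_3d = res[, 4], n_pairs = as.integer(res[, 5]))
  structure(out, dt = dt, class = c("msd_curve", "data.frame"))
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Least-squares line through the first `n_fit_points` lags. In 3D the slope
#' equals 6 D and the intercept 2 * (sigma_x^2 + sigma_y^2 + sigma_z^2), the
#' static localization-error offset; per axis the slope equals 2 D and the
#' intercept 2 sigma^2.
#'
#' @param msd_curve an [msd()] result
#' @param n_fit_points number of initial lags to fit (>= 2)
#' @param axis `"3d"`, `"x"`, `"y"` or `"z"`
#' @return list with `D` (um^2/s), `intercept` (um^2), `sigma_loc` (nm,
#'   per-axis localization error implied by the intercept; NA when negative),
#'   `flag`
#' @export
fit_diffusion <- function(msd_curve, n_fit_points = 10L, axis = c("3d", "x", "y", "z")) {
  axis <- match.arg(axis)
  .assert(n_fit_points >= 2, "need at least two fit points")
  k <- min(n_fit_points, nrow(msd_curve))
  y <- msd_curve[seq_len(k), paste0("msd_", axis)]
  tau <- msd_curve$tau[seq_len(k)]
  fit <- lm(y ~ tau)
  slope <- coef(fit)[2]
  icpt <- coef(fit)[1]
  denom <- if (axis == "3d") 6 else 2
  flag <- "ok"
  D <- slope / denom
  if (slope < 0) { D <- 0; flag <- "negative_slope"; warning("negative MSD slope; D set to 0", call. = FALSE) }
  n_ax <- if (axis == "3d") 3 else 1
  sig2 <- icpt / (2 * n_ax)                  # um^2 per axis
  sigma_loc <- if (sig2 > 0) sqrt(sig2) * 1e3 else NA_real_
  list(D = unname(D), intercept = unname(icpt), sigma_loc = unname(sigma_loc),
       flag = flag)
}

#' Step-size statistics of a trajectory
#'
#' Per-axis standard deviation of displacements over a given interval, the
#' Gaussian fit (mean, sd) and a Kolmogorov--Smirnov p-value against the
#' fitted normal.
#'
#' @param traj a `trajectory3d`
#' @param interval step interval in frames
#' @return data frame with one row per axis: `axis`, `sd_nm`, `mean_nm`,
#'   `ks_p`
#' @export
step_statistics <- function(traj, interval = 1L) {
  .assert(interval >= 1 && interval == round(interval),
          "interval must be a positive whole number of frames")
  P <- as.matrix(traj[, c("x", "y", "z")])
  n <- nrow(P)
  d <- P[(1 + interval):n, , drop = FALSE] - P[1:(n - interval), , drop = FALSE]
  res <- lapply(1:3, function(a) {
    s <- sd(d[, a]); m <- mean(d[, a])
    p <- if (s > 0) suppressWarnings(ks.test(d[, a], "pnorm", m, s)$p.value) else NA_real_
    data.frame(axis = c("x", "y", "z")[a], sd_nm = s, mean_nm = m, ks_p = p)
  })
  do.call(rbind, res)
}
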