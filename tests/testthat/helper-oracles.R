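# Shared fixtures and brute-force oracles. Oracles are deliberately naive
# (nested loops, direct formulas) and independent of the package's vectorized
# implementations.

test_config <- function(...) optical_config(focal_plane_z = 3200, ...)

# plain Pearson by the textbook formula
bf_pearson <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# per-pixel radial binning by explicit loop
bf_radial_average <- function(image, center, n_bins, r_max, px) {
  width <- r_max / n_bins
  sums <- rep(0, n_bins); cnts <- rep(0L, n_bins)
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    r <- sqrt(((j - 1) - center[1])^2 + ((i - 1) - center[2])^2) * px
    k <- floor(r / width) + 1
    if (k >= 1 && k <= n_bins) {
      sums[k] <- sums[k] + image[i, j]
      cnts[k] <- cnts[k] + 1L
    }
  }
  list(values = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_), counts = cnts)
}

# radial variance transform by direct per-center loops (zero-padding
# convention identical to the FFT implementation)
bf_rvt <- function(frame, r_min, r_max) {
  nr <- nrow(frame); nc <- ncol(frame)
  radii <- r_min:r_max
  rings <- lapply(radii, function(r) {
    s <- -(r + 1):(r + 1)
    g <- expand.grid(dy = s, dx = s)
    g[round(sqrt(g$dx^2 + g$dy^2)) == r, ]
  })
  V <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    mus <- numeric(length(radii)); varaz <- numeric(length(radii))
    for (q in seq_along(radii)) {
      off <- rings[[q]]
      vals <- numeric(nrow(off))
      for (t in seq_len(nrow(off))) {
        ii <- i + off$dy[t]; jj <- j + off$dx[t]
        vals[t] <- if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) frame[ii, jj] else 0
      }
      mus[q] <- mean(vals)
      varaz[q] <- mean(vals^2) - mus[q]^2
    }
    V[i, j] <- mean(mus^2) - mean(mus)^2 - mean(varaz)
  }
  V
}

# frames x heights Pearson by nested loops
bf_corrmap <- function(P, M) {
  out <- matrix(0, nrow(P), nrow(M))
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(M)))
    out[i, j] <- bf_pearson(P[i, ], M[j, ])
  out
}

# all source-to-sink path costs of a branch graph segment, by exhaustive DFS
bf_all_paths <- function(graph, segment = 1) {
  g <- graph$graph
  src <- graph$segments$source[segment]
  snk <- graph$segments$sink[segment]
  paths <- igraph::all_simple_paths(g, from = src, to = snk, mode = "out")
  vapply(paths, function(p) {
    ids <- igraph::get_edge_ids(g, rep(p$name, each = 2)[-c(1, 2 * length(p))])
    sum(igraph::E(g)$weight[ids])
  }, numeric(1))
}

# oscillation period from interpolated zero crossings of a detrended signal
estimate_period <- function(z, y, k = 195) {
  d <- y - stats::filter(y, rep(1 / k, k), sides = 2)
  ok <- !is.na(d)
  zz <- z[ok]; d <- d[ok]
  ix <- which(diff(sign(d)) != 0)
  zc <- zz[ix] - d[ix] * (zz[ix + 1] - zz[ix]) / (d[ix + 1] - d[ix])
  2 * (zc[length(zc)] - zc[1]) / (length(zc) - 1)
}

# render a single noiseless frame of a static particle
render_static_frame <- function(cfg, z, center_px = c(64, 64), image_size = 128L,
                                diameter = 40) {
  px <- cfg$pixel_size
  traj <- simulate_trajectory(0, 1e-5, 2,
                              start = c(center_px[1] * px, center_px[2] * px, z),
                              diameter = diameter)
  render_video(traj, cfg, camera = NULL, image_size = image_size)$frames[, , 1]
}

# synthetic mask with k independent two-branch episodes: a single band that
# repeatedly splits into two touching sub-branches and remerges
toggle_mask <- function(k, ep_len = 3L, gap = 2L, nz = 30L) {
  n <- (k + 1) * gap + k * ep_len
  m <- matrix(FALSE, n, nz)
  m[, 10:16] <- TRUE
  f <- gap
  for (q in seq_len(k)) {
    m[(f + 1):(f + ep_len), 13] <- FALSE # split: runs 10:12 and 14:16
    f <- f + ep_len + gap
  }
  m
}

rho_for_mask <- function(mask, hi = 0.9) {
  rho <- matrix(-0.5, nrow(mask), ncol(mask))
  rho[mask] <- hi
  structure(list(rho = rho, z_grid = seq_len(ncol(mask)),
                 flagged_frames = integer(0)),
            class = "correlation_map")
}
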