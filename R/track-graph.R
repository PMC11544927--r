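# Branch-graph construction and debranching.
#
# Inside the selected region the suprathreshold set of a frame consists of one
# or more contiguous z-runs ("branches"). The region is divided into sections
# over which the branch count and identity are constant; sections become edges
# of a directed acyclic graph ordered forward in time, with distance
# b_m = sum over the section's frames of (1 - max rho in the branch). The
# minimum-distance source-to-sink path therefore carries the largest summed
# per-frame correlation, and Dijkstra's algorithm finds it efficiently.

# 8-connectivity between z-index intervals of consecutive frames
.runs_touch <- function(lo1, hi1, lo2, hi2) (lo1 <= hi2 + 1L) & (hi1 >= lo2 - 1L)

# contiguous TRUE-runs of a logical vector -> matrix [lo, hi] (may be 0-row)
.mask_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(lo = starts[r$values], hi = ends[r$values])
}

#' Build the branch graph of a selected correlation region
#'
#' Decomposes the selected region mask into branches (chains of per-frame
#' z-runs linked 8-connectedly across frames) and sections of constant branch
#' structure, and assembles the directed acyclic graph whose minimum-distance
#' path selects the physically consistent height sequence. Frames where the
#' region is empty split the trajectory into independently solved segments.
#'
#' A deterministic tie-break (an infinitesimal preference for lower heights)
#' is folded into the edge distances so that exactly tied alternatives resolve
#' reproducibly.
#'
#' @param map a `correlation_map`
#' @param labeling a `region_labeling` (its `mask` is used), or a logical mask
#'   matrix of the same shape as `map$rho`
#' @return a `branch_graph`: list with `graph` (igraph), `branches` (data
#'   frame: id, segment, first_frame, last_frame, cost, mean_z), `runs` (list
#'   of per-branch matrices frame/lo/hi/argmax/maxrho), `segments` (data frame
#'   with per-segment source/sink vertex names and frame span)
#' @export
build_branch_graph <- function(map, labeling) {
  stopifnot(inherits(map, "correlation_map"))
  mask <- if (inherits(labeling, "region_labeling")) labeling$mask else labeling
  rho <- map$rho
  .assert(all(dim(mask) == dim(rho)), "mask shape must match the map")
  n <- nrow(rho)
  nz <- ncol(rho)

  branches <- list()   # each: list(first, last, runs = list of c(frame, lo, hi, argmax, maxrho))
  links <- list()      # integer pairs c(from_branch, to_branch)
  seg_of <- integer(0)
  new_branch <- function(seg) {
    branches[[length(branches) + 1L]] <<- list(first = NA_integer_, last = NA_integer_,
                                               rows = list())
    seg_of[length(branches)] <<- seg
    length(branches)
  }
  extend <- function(b, i, lo, hi) {
    row <- rho[i, lo:hi]
    am <- which.max(row)
    branches[[b]]$rows[[length(branches[[b]]$rows) + 1L]] <<-
      c(i, lo, hi, lo + am - 1L, row[am])
    if (is.na(branches[[b]]$first)) branches[[b]]$first <<- i
    branches[[b]]$last <<- i
  }

  active <- integer(0)     # branch ids open at the previous frame
  prev_runs <- NULL        # their runs at the previous frame (matrix lo, hi)
  segment <- 0L
  in_segment <- FALSE

  for (i in seq_len(n)) {
    cur <- .mask_runs(mask[i, ])
    k <- nrow(cur)
    if (k == 0L) {
      active <- integer(0); prev_runs <- NULL; in_segment <- FALSE
      next
    }
    if (!in_segment) {
      segment <- segment + 1L
      in_segment <- TRUE
      active <- vapply(seq_len(k), function(q) new_branch(segment), integer(1))
      for (q in seq_len(k)) extend(active[q], i, cur[q, 1], cur[q, 2])
      prev_runs <- cur
      next
    }
    m <- length(active)
    adj <- outer(seq_len(m), seq_len(k), function(p, c)
      .runs_touch(prev_runs[p, 1], prev_runs[p, 2], cur[c, 1], cur[c, 2]))
    one_to_one <- m == k && all(rowSums(adj) == 1) && all(colSums(adj) == 1)
    if (one_to_one) {
      match_c <- apply(adj, 1, which)
      for (p in seq_len(m)) extend(active[p], i, cur[match_c[p], 1], cur[match_c[p], 2])
      prev_runs <- cur[match_c, , drop = FALSE]
    } else {
      nb <- vapply(seq_len(k), function(q) new_branch(segment), integer(1))
      for (q in seq_len(k)) extend(nb[q], i, cur[q, 1], cur[q, 2])
      for (p in seq_len(m)) for (q in seq_len(k)) if (adj[p, q])
        links[[length(links) + 1L]] <- c(active[p], nb[q])
      # a new run with no ancestor starts fresh from the segment source;
      # a vanished run simply ends (its branch connects to the sink)
      active <- nb
      prev_runs <- cur
    }
  }

  nb <- length(branches)
  .assert(nb > 0, "selected region mask is empty")
  first <- vapply(branches, function(b) b$first, integer(1))
  last <- vapply(branches, function(b) b$last, integer(1))
  runs <- lapply(branches, function(b) {
    m <- do.call(rbind, b$rows)
    colnames(m) <- c("frame", "lo", "hi", "argmax", "maxrho")
    m
  })
  cost <- vapply(runs, function(m) sum(1 - m[, "maxrho"]), numeric(1))
  mean_z <- vapply(runs, function(m) mean(m[, "argmax"]), numeric(1))
  tie_eps <- 1e-9 * mean_z / nz

  bdf <- data.frame(id = seq_len(nb), segment = seg_of, first_frame = first,
                    last_frame = last, cost = cost, mean_z = mean_z)

  # assemble the igraph: branch vertices plus per-segment source/sink
  segs <- sort(unique(seg_of))
  vnames <- c(paste0("b", seq_len(nb)), paste0("src", segs), paste0("snk", segs))
  lmat <- if (length(links)) do.call(rbind, links) else matrix(integer(0), 0, 2)
  e_from <- character(0); e_to <- character(0); e_w <- numeric(0)
  if (nrow(lmat) > 0) {
    e_from <- paste0("b", lmat[, 1])
    e_to <- paste0("b", lmat[, 2])
    e_w <- cost[lmat[, 2]] + tie_eps[lmat[, 2]]
  }
  # only branches spanning a segment boundary touch its source/sink: a path
  # must cover every frame of the segment (skipping frames would otherwise
  # always be cheaper, since each frame contributes a nonnegative distance)
  seg_first <- stats::ave(first, seg_of, FUN = min)
  seg_last <- stats::ave(last, seg_of, FUN = max)
  for (b in which(first == seg_first)) {
    e_from <- c(e_from, paste0("src", seg_of[b]))
    e_to <- c(e_to, paste0("b", b))
    e_w <- c(e_w, cost[b] + tie_eps[b])
  }
  for (b in which(last == seg_last)) {
    e_from <- c(e_from, paste0("b", b))
    e_to <- c(e_to, paste0("snk", seg_of[b]))
    e_w <- c(e_w, 0)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = e_from, to = e_to, weight = e_w),
    directed = TRUE,
    vertices = data.frame(name = vnames))
  seg_frames <- t(vapply(segs, function(s) {
    idx <- seg_of == s
    c(min(first[idx]), max(last[idx]))
  }, numeric(2)))
  structure(list(graph = g,
                 branches = bdf,
                 runs = runs,
                 segments = data.frame(segment = segs,
                                       source = paste0("src", segs),
                                       sink = paste0("snk", segs),
                                       first_frame = seg_frames[, 1],
                                       last_frame = seg_frames[, 2]),
                 dim = dim(rho)),
            class = "branch_graph")
}

#' @export
print.branch_graph <- function(x, ...) {
  cat(sprintf("<branch_graph> %d branches, %d segment(s), %d edges\n",
              nrow(x$branches), nrow(x$segments), igraph::ecount(x$graph)))
  invisible(x)
}

#' Count distinct source-to-sink paths of a branch graph
#'
#' Dynamic programming over the topological order of the DAG. With k
#' independent two-branch episodes the count is 2^k, which is why exhaustive
#' path enumeration is not viable for long trajectories and a shortest-path
#' search is used instead.
#'
#' @param graph a `branch_graph`
#' @return numeric vector of path counts, one per trajectory segment
#' @export
count_paths <- function(graph) {
  stopifnot(inherits(graph, "branch_graph"))
  g <- graph$graph
  topo <- igraph::topo_sort(g, mode = "out")
  cnt <- stats::setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  cnt[graph$segments$source] <- 1
  for (v in topo$name) {
    if (cnt[v] == 0) next
    nxt <- igraph::neighbors(g, v, mode = "out")$name
    for (u in nxt) cnt[u] <- cnt[u] + cnt[v]
  }
  unname(cnt[graph$segments$sink])
}

#' Debranch a selected region via Dijkstra's shortest path
#'
#' Finds, per trajectory segment, the minimum-distance source-to-sink path of
#' the branch graph; the union of the path's branches contains exactly one
#' z-run per frame. Equivalently (all edge distances being nonnegative sums of
#' 1 - rho), the selected path maximizes the summed per-frame maximum
#' correlation over all alternative paths.
#'
#' @param graph a `branch_graph`
#' @return a `debranched_map`: list with `assignment` (data frame: frame,
#'   segment, branch, lo, hi, argmax, maxrho) and `mask` (logical matrix with
#'   one run per covered frame)
#' @export
shortest_path_debranch <- function(graph) {
  stopifnot(inherits(graph, "branch_graph"))
  g <- graph$graph
  rows <- list()
  mask <- matrix(FALSE, graph$dim[1], graph$dim[2])
  for (s in seq_len(nrow(graph$segments))) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = graph$segments$source[s],
                             to = graph$segments$sink[s],
                             weights = igraph::E(g)$weight,
                             output = "vpath", algorithm = "dijkstra"))
    vp <- sp$vpath[[1]]$name
    bids <- as.integer(sub("^b", "", vp[grepl("^b", vp)]))
    if (length(bids) == 0) {
      # no boundary-to-boundary path (pathological connectivity): fall back
      # to the best-correlated run per frame among this segment's branches
      warning(sprintf("segment %d: no spanning path; using per-frame maxima",
                      graph$segments$segment[s]), call. = FALSE)
      in_seg <- which(graph$branches$segment == graph$segments$segment[s])
      allruns <- do.call(rbind, lapply(in_seg, function(b)
        cbind(graph$runs[[b]], branch = b)))
      best <- tapply(seq_len(nrow(allruns)), allruns[, "frame"], function(ii)
        ii[which.max(allruns[ii, "maxrho"])])
      for (q in as.integer(best)) {
        rr <- allruns[q, ]
        rows[[length(rows) + 1L]] <-
          data.frame(frame = rr[["frame"]], segment = graph$segments$segment[s],
                     branch = rr[["branch"]], lo = rr[["lo"]], hi = rr[["hi"]],
                     argmax = rr[["argmax"]], maxrho = rr[["maxrho"]])
        mask[rr[["frame"]], rr[["lo"]]:rr[["hi"]]] <- TRUE
      }
      next
    }
    for (b in bids) {
      m <- graph$runs[[b]]
      rows[[length(rows) + 1L]] <-
        data.frame(frame = m[, "frame"], segment = graph$segments$segment[s],
                   branch = b, lo = m[, "lo"], hi = m[, "hi"],
                   argmax = m[, "argmax"], maxrho = m[, "maxrho"])
      for (q in seq_len(nrow(m)))
        mask[m[q, "frame"], m[q, "lo"]:m[q, "hi"]] <- TRUE
    }
  }
  asn <- do.call(rbind, rows)
  asn <- asn[order(asn$frame), ]
  rownames(asn) <- NULL
  structure(list(assignment = asn, mask = mask), class = "debranched_map")
}
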