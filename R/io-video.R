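# Video containers. Two on-disk formats, both with a YAML sidecar carrying
# shape, dtype, frame rate, pixel size and (for TIFF) the affine rescaling:
#  - "raw": float64 little-endian binary, lossless round trip;
#  - "tiff": multi-page 32-bit float TIFF; values are affinely mapped to
#    [0, 1] on write (scale/offset recorded in the sidecar) because the TIFF
#    writer clamps values outside that range.

.sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a video to disk
#'
#' @param video a `contrast_video`
#' @param path output file path (`.raw` or `.tif` suggested)
#' @param format `"raw"` (lossless float64 binary) or `"tiff"` (32-bit float
#'   multi-page TIFF, affinely rescaled)
#' @return `path`, invisibly
#' @export
write_video <- function(video, path, format = c("raw", "tiff")) {
  stopifnot(inherits(video, "contrast_video"))
  format <- match.arg(format)
  d <- dim(video$frames)
  meta <- list(width = d[2], height = d[1], frames = d[3], dtype = "float64",
               frame_interval = video$frame_interval,
               pixel_size = video$pixel_size, provenance = video$provenance,
               format = format, package_version = as.character(packageVersion("ispt3d")))
  if (format == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(video$frames), con, size = 8, endian = "little")
  } else {
    lo <- min(video$frames); hi <- max(video$frames)
    scale <- if (hi > lo) hi - lo else 1
    meta$dtype <- "float32"
    meta$offset <- lo
    meta$scale <- scale
    pages <- lapply(seq_len(d[3]), function(i) (video$frames[, , i] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

#' Read a video from disk
#'
#' Reads a multi-page TIFF or raw binary written by [write_video()] (or any
#' file with a compatible YAML sidecar). Metadata found in both the sidecar
#' and `config_meta` is taken from `config_meta`, with a warning on conflict.
#'
#' @param path file path (sidecar expected at `<path>.yaml`)
#' @param config_meta optional named list overriding sidecar metadata
#'   (`frame_interval`, `pixel_size`)
#' @return a `contrast_video`
#' @export
read_video <- function(path, config_meta = NULL) {
  sp <- .sidecar_path(path)
  .assert(file.exists(sp), paste0("missing sidecar metadata file: ", sp))
  meta <- yaml::read_yaml(sp)
  for (f in c("width", "height", "frames"))
    .assert(!is.null(meta[[f]]), paste0("sidecar lacks required field: ", f))
  n_expect <- meta$width * meta$height * meta$frames
  if (identical(meta$format, "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != meta$frames)
      stop(sprintf("truncated video: expected %d frames, found %d",
                   meta$frames, length(pages)), call. = FALSE)
    arr <- array(0, dim = c(meta$height, meta$width, meta$frames))
    for (i in seq_along(pages))
      arr[, , i] <- pages[[i]] * (meta$scale %||% 1) + (meta$offset %||% 0)
  } else {
    sz <- file.info(path)$size
    n_found <- sz / 8
    if (n_found != n_expect)
      stop(sprintf("truncated video: expected %d frames, found %.2f",
                   meta$frames, n_found / (meta$width * meta$height)), call. = FALSE)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
    arr <- array(v, dim = c(meta$height, meta$width, meta$frames))
  }
  for (f in c("frame_interval", "pixel_size")) {
    if (!is.null(config_meta[[f]])) {
      if (!is.null(meta[[f]]) && !isTRUE(all.equal(meta[[f]], config_meta[[f]])))
        warning(sprintf("%s: config value %g overrides sidecar value %g",
                        f, config_meta[[f]], meta[[f]]), call. = FALSE)
      meta[[f]] <- config_meta[[f]]
    }
  }
  contrast_video(arr, frame_interval = meta$frame_interval %||% NA_real_,
                 provenance = meta$provenance %||% "raw",
                 pixel_size = meta$pixel_size %||% NA_real_)
}

#' Write a trajectory to delimited text
#'
#' CSV with a `#`-prefixed header block (units, config hash, column spec) and
#' full float precision, losslessly round-trippable with
#' [read_trajectory()]. Lengths are stored in nm and times in seconds.
#'
#' @param track data frame (e.g. `trajectory3d`, `axial_track`, or a merged
#'   3D track); written as-is
#' @param path output path
#' @param config_hash optional provenance hash stamped into the header
#' @return `path`, invisibly
#' @export
write_trajectory <- function(track, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# ispt3d trajectory v1 (package %s)", packageVersion("ispt3d")),
    "# units: lengths nm, times s",
    sprintf("# config_hash: %s", config_hash %||% "none"),
    sprintf("# columns: %s", paste(names(track), collapse = ","))), con)
  write.csv(format(as.data.frame(track), digits = 17, trim = TRUE,
                   scientific = FALSE), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path input path
#' @param required_columns columns that must be present; a missing one raises
#'   a schema error
#' @return data frame with the stored columns
#' @export
read_trajectory <- function(path, required_columns = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) stop("malformed trajectory file: ", conditionMessage(e),
                             call. = FALSE))
  nf <- which(!grepl("^#", lines))[1]
  bad <- which(!complete.cases(df[, intersect(c("frame", "t"), names(df)), drop = FALSE]))
  if (length(bad) > 0)
    stop(sprintf("malformed row at line %d", nf + bad[1]), call. = FALSE)
  for (cn in required_columns)
    if (!cn %in% names(df))
      stop(sprintf("trajectory file lacks required column '%s'", cn), call. = FALSE)
  df
}
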