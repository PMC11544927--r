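#' Read a run configuration file
#'
#' YAML with optional sections `optics`, `camera`, `particle`, `tracking` and
#' `paths`. Unknown keys raise an error; recognized keys override the package
#' defaults of [optical_config()] and [camera_config()]. Lengths are in nm
#' unless the key carries a `_um` suffix (converted on load).
#'
#' @param path YAML file path
#' @return a `run_config`: list with `optics` (optical_config), `camera`
#'   (camera_config), `particle`, `tracking`, `paths` and `hash`
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("optics", "camera", "particle", "tracking", "paths")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config section(s): ", paste(extra, collapse = ", "), call. = FALSE)
  um_to_nm <- function(lst) {
    # YAML may deliver numerics like "1.0e5" as strings; coerce when numeric
    for (nm in names(lst)) {
      if (is.character(lst[[nm]]) && length(lst[[nm]]) == 1 &&
          !is.na(suppressWarnings(as.numeric(lst[[nm]]))))
        lst[[nm]] <- as.numeric(lst[[nm]])
    }
    for (nm in grep("_um$", names(lst), value = TRUE)) {
      lst[[sub("_um$", "", nm)]] <- lst[[nm]] * 1e3
      lst[[nm]] <- NULL
    }
    lst
  }
  opt <- um_to_nm(raw$optics %||% list())
  bad <- setdiff(names(opt), names(formals(optical_config)))
  if (length(bad) > 0)
    stop("unknown optics key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cam <- um_to_nm(raw$camera %||% list())
  bad <- setdiff(names(cam), names(formals(camera_config)))
  if (length(bad) > 0)
    stop("unknown camera key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- list(optics = do.call(optical_config, opt),
              camera = do.call(camera_config, cam),
              particle = um_to_nm(raw$particle %||% list()),
              tracking = um_to_nm(raw$tracking %||% list()),
              paths = raw$paths %||% list())
  cfg$hash <- config_hash(cfg[c("optics", "camera", "particle", "tracking")])
  class(cfg) <- "run_config"
  cfg
}

#' Write the resolved configuration next to run outputs
#'
#' @param run_config a `run_config`
#' @param dir output directory
#' @return the file path, invisibly
#' @export
write_resolved_config <- function(run_config, dir) {
  path <- file.path(dir, "resolved_config.yaml")
  sanitize <- function(lst) lapply(lst, function(v) if (is.complex(v)) {
    paste0(Re(v), ifelse(Im(v) >= 0, "+", "-"), abs(Im(v)), "i")
  } else v)
  out <- list(optics = sanitize(unclass(run_config$optics)),
              camera = unclass(run_config$camera),
              particle = run_config$particle,
              tracking = run_config$tracking,
              hash = run_config$hash,
              package_version = as.character(packageVersion("ispt3d")))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build or load a cached model stack
#'
#' Model stacks are the expensive reusable object of the pipeline. This keyed
#' single-file cache stores each stack under a hash of the optical
#' configuration and grid parameters.
#'
#' @param config an [optical_config()]
#' @param z_min,z_max,z_step grid (nm), as in [build_model_stack()]
#' @param cache_dir cache directory (created if needed); NULL disables caching
#' @param ... further arguments to [build_model_stack()]
#' @return a `radial_model_stack`
#' @export
model_stack_cached <- function(config, z_min, z_max, z_step = 1,
                               cache_dir = file.path(tempdir(), "ispt3d_cache"),
                               ...) {
  if (is.null(cache_dir))
    return(build_model_stack(config, z_min, z_max, z_step, ...))
  key <- config_hash(list(config, z_min, z_max, z_step, list(...)))
  path <- file.path(cache_dir, paste0("stack_", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  stack <- build_model_stack(config, z_min, z_max, z_step, ...)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(stack, path)
  stack
}
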