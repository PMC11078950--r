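# Configuration-driven workflow: simulate (optional) -> reconstruct ->
# analyze, with a run manifest sufficient to regenerate every output.

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(block)
}

optics_from_config <- function(cfg) {
  check_keys(cfg, c("wavelength_em", "wavelength_ex", "numerical_aperture",
                    "magnification", "refractive_index", "pixel_pitch",
                    "psf_model"), "optics")
  do.call(optics_config, cfg)
}

params_from_config <- function(cfg) {
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg, c("window_size", "subpixels", "alpha", "threshold_mode",
                    "threshold_value", "stride", "mean_subtract"),
             "reconstruct")
  do.call(musical_params, cfg)
}

#' Run the simulate / reconstruct / analyze pipeline
#'
#' Executes the stages named in the configuration and writes all outputs
#' plus a run manifest (config snapshot, package version, output checksums,
#' per-stage timings, collected warnings) to the output directory. The run
#' is fully determined by the configuration and its seed.
#'
#' Configuration blocks (YAML file or nested list):
#' \describe{
#'   \item{`optics`}{[optics_config()] fields; required.}
#'   \item{`seed`}{integer; required when simulating.}
#'   \item{`out_dir`}{output directory; required.}
#'   \item{`simulate`}{optional phantom block: `field_size`, `n_fibrils`,
#'     `waviness`, `dense_fraction`, `fibril_width`, `raster_pitch`,
#'     `linear_density`, `jitter_sd`, `mean_brightness`, `frames`,
#'     `fluctuation` ([fluctuation_model()] fields), `camera`
#'     ([camera_model()] fields).}
#'   \item{`stack`}{optional path to an input TIFF stack (used when not
#'     simulating).}
#'   \item{`reconstruct`}{optional [musical_params()] fields; present by
#'     default whenever a stack is available.}
#'   \item{`analyze`}{optional: `scales` (um ladder for
#'     [multiscale_variance()]).}
#' }
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, c("optics", "seed", "out_dir", "simulate", "stack",
                       "reconstruct", "analyze"), "config")
  if (is.null(config$optics)) stop("config needs an `optics` block", call. = FALSE)
  if (is.null(config$out_dir)) stop("config needs an `out_dir`", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  optics <- optics_from_config(config$optics)
  warnings_log <- character(0)
  timings <- list()
  outputs <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  stack <- NULL
  if (!is.null(config$simulate)) {
    if (is.null(config$seed)) stop("simulation requires a seed", call. = FALSE)
    sim <- config$simulate
    check_keys(sim, c("field_size", "n_fibrils", "waviness", "dense_fraction",
                      "fibril_width", "raster_pitch", "linear_density",
                      "jitter_sd", "mean_brightness", "frames", "fluctuation",
                      "camera"), "simulate")
    t0 <- proc.time()[["elapsed"]]
    seed <- as.integer(config$seed)
    phantom <- collect(generate_fibrils(
      field_size = unlist(sim$field_size),
      n_fibrils = sim$n_fibrils,
      waviness = sim$waviness %||% 0.4,
      dense_fraction = sim$dense_fraction %||% 0.8,
      seed = seed,
      fibril_width = sim$fibril_width %||% 0.1,
      raster_pitch = sim$raster_pitch %||% 0.3225))
    phantom <- collect(place_emitters(
      phantom, linear_density = sim$linear_density %||% 10,
      jitter_sd = sim$jitter_sd,
      mean_brightness = sim$mean_brightness %||% 100, seed = seed + 1L))
    fluct <- do.call(fluctuation_model, as.list(sim$fluctuation))
    cam <- do.call(camera_model, as.list(sim$camera))
    bmat <- collect(simulate_fluctuations(phantom$emitters, fluct,
                                          K = sim$frames %||% 200L,
                                          seed = seed + 2L))
    stack <- collect(render_stack(phantom, bmat, optics, cam, seed = seed + 3L))
    write_phantom(phantom, file.path(out_dir, "phantom"))
    write_stack(stack, file.path(out_dir, "stack.tif"))
    outputs <- c(outputs, file.path(out_dir, "stack.tif"),
                 file.path(out_dir, "phantom", "emitters.csv"),
                 file.path(out_dir, "phantom", "density.tif"))
    timings$simulate <- proc.time()[["elapsed"]] - t0
  } else if (!is.null(config$stack)) {
    stack <- collect(read_stack(config$stack,
                                pixel_pitch_object = object_pixel_pitch(optics)))
  }

  map <- NULL
  if (!is.null(stack) &&
      (!is.null(config$reconstruct) || is.null(config$analyze))) {
    t0 <- proc.time()[["elapsed"]]
    params <- params_from_config(config$reconstruct)
    map <- collect(reconstruct(stack, params, optics))
    write_map(map, file.path(out_dir, "map.tif"))
    outputs <- c(outputs, file.path(out_dir, "map.tif"))
    timings$reconstruct <- proc.time()[["elapsed"]] - t0
  }

  if (!is.null(config$analyze) && !is.null(map)) {
    check_keys(config$analyze, c("scales"), "analyze")
    t0 <- proc.time()[["elapsed"]]
    scales <- unlist(config$analyze$scales %||% c(90, 45, 25, 10, 5))
    report <- collect(multiscale_variance(map, window_sizes = scales))
    rows <- do.call(rbind, lapply(report$per_size, function(p)
      data.frame(window_size_um = p$window_size_um,
                 window_size_px = p$window_size_px,
                 n_windows = p$n_windows,
                 mean_within_var = mean(p$within_var),
                 between_var = p$between_var)))
    utils::write.csv(rows, file.path(out_dir, "multiscale.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, file.path(out_dir, "multiscale.csv"))
    timings$analyze <- proc.time()[["elapsed"]] - t0
  }

  manifest <- list(
    package = "musicalr",
    version = as.character(utils::packageVersion("musicalr")),
    config = config,
    outputs = as.list(tools::md5sum(outputs)),
    timings = timings,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
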