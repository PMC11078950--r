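# TIFF stack and map input/output. Stacks are read from plain multi-page or
# OME-TIFF files; pixel-size metadata embedded in an OME image description
# takes precedence over caller-supplied values. Written files use
# uncompressed TIFF plus a JSON sidecar carrying metadata the TIFF tags
# cannot (the tiff writer stores samples normalized to [0, 1]).

sidecar_path <- function(path) paste0(path, ".json")

# Parse PhysicalSizeX (um) from an OME-XML image description, if any.
ome_pixel_size <- function(description) {
  if (is.null(description) || !nzchar(description)) return(NULL)
  m <- regmatches(description,
                  regexpr('PhysicalSizeX="([0-9.eE+-]+)"', description))
  if (length(m) == 0) return(NULL)
  as.numeric(sub('PhysicalSizeX="([0-9.eE+-]+)"', "\\1", m))
}

#' Read a fluctuation stack from a TIFF file
#'
#' Reads a single-channel multi-page TIFF (or OME-TIFF) into an
#' [image_stack()]. Integer samples are returned as counts. The object-space
#' pixel size is taken, in order of precedence, from (1) OME metadata in the
#' file's image description, (2) a JSON sidecar written by [write_stack()],
#' (3) the `pixel_pitch_object` argument; a message notes which source won.
#'
#' @param path TIFF file path.
#' @param pixel_pitch_object Fallback object-space pixel size in
#'   micrometres.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_pitch_object = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e)
                      stop("failed to parse TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("multi-channel TIFF: select a single channel before reading",
         call. = FALSE)
  desc <- attr(pages[[1]], "description")
  meta <- list()
  side <- sidecar_path(path)
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pitch_ome <- ome_pixel_size(desc)
  pitch <- if (!is.null(pitch_ome)) {
    message("pixel size taken from OME metadata (", pitch_ome, " um)")
    pitch_ome
  } else if (!is.null(meta$pixel_pitch_object)) {
    meta$pixel_pitch_object
  } else if (!is.null(pixel_pitch_object)) {
    message("pixel size not present in file metadata; using configured value")
    pixel_pitch_object
  } else {
    stop("pixel size is neither in the file metadata nor supplied", call. = FALSE)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(unlist(pages), dim = c(h, w, length(pages)))
  image_stack(frames * 1.0, pixel_pitch_object = pitch,
              frame_interval = meta$frame_interval,
              metadata = list(path = path, description = desc))
}

#' Write a fluctuation stack to a 16-bit TIFF file
#'
#' Frames are rounded to integers and stored uncompressed at 16 bits per
#' sample (value-exact round trip for counts up to 65535). Pixel pitch and
#' frame interval go into a JSON sidecar next to the file.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- 65535
  if (max(stack$frames) > mx)
    stop("stack intensities exceed the 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(k) round(stack$frames[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(pixel_pitch_object = stack$pixel_pitch_object,
         frame_interval = stack$frame_interval,
         n_frames = dim(stack$frames)[3]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write an indicator map to TIFF with a JSON sidecar
#'
#' The map is stored as 32-bit samples normalized to `[0, 1]`; the scale
#' factor, mask convention, reconstruction parameters and optics go into
#' the sidecar so [read_map()] can restore values exactly (up to float32
#' precision).
#'
#' @param map An `indicator_map` from [reconstruct()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "indicator_map"))
  v <- map$values
  scale <- max(v, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  v[is.na(v)] <- 0
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  o <- map$optics
  jsonlite::write_json(
    list(scale = scale, pixel_pitch = map$pixel_pitch,
         window_size = map$window_size,
         n_degenerate = map$n_degenerate,
         params = unclass(map$params),
         optics = unclass(o)[!vapply(unclass(o), is.null, logical(1))],
         valid_rows = range(which(apply(map$valid_mask, 1, any))),
         valid_cols = range(which(apply(map$valid_mask, 2, any)))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an indicator map written by [write_map()]
#'
#' @param path TIFF path with its JSON sidecar present.
#' @return A list with `values` (rescaled matrix, `NA` outside the valid
#'   interior) and the sidecar metadata.
#' @export
read_map <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * meta$scale
  vr <- meta$valid_rows; vc <- meta$valid_cols
  mask <- matrix(TRUE, nrow(v), ncol(v))
  mask[seq_len(nrow(v)) < vr[1] | seq_len(nrow(v)) > vr[2], ] <- FALSE
  mask[, seq_len(ncol(v)) < vc[1] | seq_len(ncol(v)) > vc[2]] <- FALSE
  v[!mask] <- NA_real_
  c(list(values = v), meta[setdiff(names(meta), "scale")])
}

#' Write phantom ground truth to plain-text and TIFF files
#'
#' Emitter table as CSV (`x_um`, `y_um`, `brightness`), density raster as a
#' normalized 32-bit TIFF with sidecar, and the phantom configuration as
#' JSON.
#'
#' @param phantom A [fibril_phantom].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "fibril_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(x_um = phantom$emitters$x, y_um = phantom$emitters$y,
               brightness = phantom$emitters$brightness),
    file.path(dir, "emitters.csv"), row.names = FALSE)
  r <- phantom$density_raster
  scale <- max(r, 1)
  tiff::writeTIFF(r / scale, file.path(dir, "density.tif"),
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, raster_pitch = phantom$raster_pitch,
         field_size = phantom$field_size, seed = phantom$seed,
         n_fibrils = length(phantom$centerlines),
         n_emitters = nrow(phantom$emitters),
         fibril_width = phantom$fibril_width),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
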