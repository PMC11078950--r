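# Microscope optics model: configuration, depth of field, field of view,
# resolution limit and point-spread-function kernels. All object-space
# lengths are in micrometres; the camera pixel pitch is divided by the
# magnification to obtain object-space sampling.

#' Microscope optics configuration
#'
#' Bundles the acquisition parameters that drive the point spread function,
#' depth of field and field of view: emission wavelength, numerical aperture,
#' magnification, medium refractive index and camera pixel pitch.
#'
#' @param wavelength_em Emission wavelength in micrometres (e.g. 0.460 for
#'   blue autofluorescence emission).
#' @param numerical_aperture Objective numerical aperture (NA).
#' @param magnification Total lateral magnification M (>= 1).
#' @param pixel_pitch Physical camera pixel size e in micrometres.
#' @param refractive_index Refractive index of the imaging medium (default 1,
#'   air). Must be >= the numerical aperture.
#' @param wavelength_ex Optional excitation wavelength in micrometres
#'   (metadata only; not used in any computation).
#' @param psf_model PSF parameterization: `"gaussian"` (default; sigma =
#'   0.21 lambda / NA) or `"airy"` (Airy-disk intensity with first zero at
#'   0.61 lambda / NA).
#'
#' @return An object of class `optics_config`.
#' @examples
#' opt <- optics_config(wavelength_em = 0.460, numerical_aperture = 0.80,
#'                      magnification = 20, pixel_pitch = 6.45)
#' depth_of_field(opt)
#' @export
optics_config <- function(wavelength_em, numerical_aperture, magnification,
                          pixel_pitch, refractive_index = 1,
                          wavelength_ex = NULL,
                          psf_model = c("gaussian", "airy")) {
  psf_model <- match.arg(psf_model)
  num <- c(wavelength_em = wavelength_em,
           numerical_aperture = numerical_aperture,
           magnification = magnification,
           pixel_pitch = pixel_pitch,
           refractive_index = refractive_index)
  if (!all(is.finite(num)) || any(num <= 0))
    stop("invalid optics config: all parameters must be finite and positive",
         call. = FALSE)
  if (numerical_aperture > refractive_index)
    stop("invalid optics config: numerical aperture cannot exceed the ",
         "refractive index of the medium", call. = FALSE)
  if (magnification < 1)
    stop("invalid optics config: magnification must be >= 1", call. = FALSE)
  if (!is.null(wavelength_ex) && (!is.finite(wavelength_ex) || wavelength_ex <= 0))
    stop("invalid optics config: wavelength_ex must be positive", call. = FALSE)
  structure(
    list(wavelength_em = wavelength_em,
         wavelength_ex = wavelength_ex,
         numerical_aperture = numerical_aperture,
         magnification = magnification,
         refractive_index = refractive_index,
         pixel_pitch = pixel_pitch,
         psf_model = psf_model),
    class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("Optics configuration\n")
  cat(sprintf("  emission wavelength : %.4g um\n", x$wavelength_em))
  if (!is.null(x$wavelength_ex))
    cat(sprintf("  excitation wavelength: %.4g um\n", x$wavelength_ex))
  cat(sprintf("  numerical aperture  : %.3g\n", x$numerical_aperture))
  cat(sprintf("  magnification       : %gx\n", x$magnification))
  cat(sprintf("  refractive index    : %.3g\n", x$refractive_index))
  cat(sprintf("  camera pixel pitch  : %.4g um (%.4g um in object space)\n",
              x$pixel_pitch, object_pixel_pitch(x)))
  cat(sprintf("  PSF model           : %s\n", x$psf_model))
  cat(sprintf("  depth of field      : %.3g um\n", depth_of_field(x)))
  cat(sprintf("  Rayleigh limit      : %.3g um\n", rayleigh_limit(x)))
  invisible(x)
}

stopifnot_optics <- function(optics) {
  if (!inherits(optics, "optics_config"))
    stop("expected an `optics_config` object", call. = FALSE)
  invisible(optics)
}

#' Object-space sampling pitch
#'
#' The size of one camera pixel projected into object space: `pixel_pitch /
#' magnification`, in micrometres.
#'
#' @param optics An [optics_config()].
#' @return Length in micrometres.
#' @export
object_pixel_pitch <- function(optics) {
  stopifnot_optics(optics)
  optics$pixel_pitch / optics$magnification
}

#' Depth of field
#'
#' Wide-field depth of field combining the wave-optical term
#' `lambda * mu / NA^2` with the geometric (pixel-limited) term
#' `mu * e / (M * NA)`, where mu is the medium refractive index, e the camera
#' pixel pitch and M the magnification.
#'
#' @param optics An [optics_config()].
#' @return Depth of field in micrometres.
#' @examples
#' # 20x / 0.80 NA with a 6.45 um camera pixel: ~1.2 um
#' depth_of_field(optics_config(0.460, 0.80, 20, 6.45))
#' @export
depth_of_field <- function(optics) {
  stopifnot_optics(optics)
  lam <- optics$wavelength_em
  mu <- optics$refractive_index
  na <- optics$numerical_aperture
  lam * mu / na^2 + mu * optics$pixel_pitch / (optics$magnification * na)
}

#' Field of view
#'
#' Lateral extent of the imaged object region for a given sensor size:
#' each axis is `pixel_count * e / M` micrometres.
#'
#' @param optics An [optics_config()].
#' @param sensor_pixels Integer vector of length 2, sensor size in pixels
#'   (width, height) or any axis order; the result follows the input order.
#' @return Numeric vector of length 2, micrometres per axis.
#' @examples
#' field_of_view(optics_config(0.460, 0.80, 20, 6.45), c(1388, 1040))
#' @export
field_of_view <- function(optics, sensor_pixels) {
  stopifnot_optics(optics)
  if (length(sensor_pixels) != 2 || any(!is.finite(sensor_pixels)) ||
      any(sensor_pixels < 1) || any(sensor_pixels != round(sensor_pixels)))
    stop("sensor_pixels must be two positive integers", call. = FALSE)
  as.numeric(sensor_pixels) * object_pixel_pitch(optics)
}

#' Rayleigh resolution limit
#'
#' Classical lateral resolution bound `0.61 * lambda / NA` of a
#' diffraction-limited microscope.
#'
#' @param optics An [optics_config()].
#' @return Length in micrometres.
#' @export
rayleigh_limit <- function(optics) {
  stopifnot_optics(optics)
  0.61 * optics$wavelength_em / optics$numerical_aperture
}

# Gaussian PSF sigma (um) for the standard paraxial approximation of the
# Airy intensity pattern.
psf_sigma <- function(optics) 0.21 * optics$wavelength_em / optics$numerical_aperture

# Radial PSF intensity profile (unnormalized) at radii r (um).
psf_radial <- function(optics, r) {
  if (optics$psf_model == "gaussian") {
    s <- psf_sigma(optics)
    exp(-r^2 / (2 * s^2))
  } else {
    # Airy intensity (2 J1(v)/v)^2 with its first zero placed at the
    # Rayleigh radius 0.61 lambda / NA, i.e. v = j11 * r / r0 where j11 is
    # the first zero of the Bessel function J1.
    j11 <- 3.8317059702075125
    v <- j11 * r / rayleigh_limit(optics)
    out <- v
    out[] <- 1                      # limit value at v = 0
    nz <- v != 0
    out[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
    out
  }
}

#' Sampled point-spread-function kernel
#'
#' Samples the configured PSF model on a square grid centred on the origin
#' and normalizes it to unit sum so it can be used as a sampling /
#' convolution kernel. The grid always has an odd number of points per side
#' so the centre falls on a grid node.
#'
#' @param optics An [optics_config()].
#' @param grid_spacing Grid step in object-space micrometres.
#' @param support_radius Half-width of the kernel support in micrometres.
#'   Should cover at least ~3x the PSF half-width; a kernel capturing less
#'   than 99% of the PSF mass triggers a warning.
#' @return An object of class `psf_kernel`: a list with `values` (square
#'   matrix summing to 1), `grid_spacing` (um) and `center` (row/col index of
#'   the central node).
#' @examples
#' k <- make_psf(optics_config(0.460, 0.80, 20, 6.45), grid_spacing = 0.05,
#'               support_radius = 0.6)
#' sum(k$values)
#' @export
make_psf <- function(optics, grid_spacing, support_radius) {
  stopifnot_optics(optics)
  if (!is.finite(grid_spacing) || grid_spacing <= 0)
    stop("grid_spacing must be positive", call. = FALSE)
  if (!is.finite(support_radius) || support_radius <= 0)
    stop("support_radius must be positive", call. = FALSE)
  h <- ceiling(support_radius / grid_spacing)
  ax <- (-h:h) * grid_spacing
  r <- sqrt(outer(ax^2, ax^2, `+`))
  v <- psf_radial(optics, r)
  total <- sum(v)
  # Mass check against a much larger support at the same spacing.
  hbig <- 3L * h
  axb <- (-hbig:hbig) * grid_spacing
  rb <- sqrt(outer(axb^2, axb^2, `+`))
  big <- sum(psf_radial(optics, rb))
  if (total < 0.99 * big)
    warning(sprintf("PSF support captures only %.1f%% of the kernel mass; increase support_radius",
                    100 * total / big), call. = FALSE)
  structure(
    list(values = v / total, grid_spacing = grid_spacing, center = h + 1L),
    class = "psf_kernel")
}

#' @export
print.psf_kernel <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("PSF kernel: %d x %d grid, spacing %.4g um, sum %.6f\n",
              n, n, x$grid_spacing, sum(x$values)))
  invisible(x)
}
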