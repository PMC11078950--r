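# Synthetic fibril phantoms: curvilinear fibril networks with dense and
# sparse regions, point emitters along the fibrils, per-frame brightness
# fluctuations, optical blur and a camera noise model. Every generator takes
# an explicit seed and is bit-reproducible.

#' Fluctuation model for emitter brightness
#'
#' @param kind `"two_state_blinking"`: each emitter follows an on/off Markov
#'   chain with stationary on-probability `p_on` and lag-1 persistence
#'   `on_off_correlation`; its on-frame brightness is the emitter's mean
#'   brightness, optionally modulated by lognormal noise of coefficient of
#'   variation `brightness_cv`. `"lognormal_brightness"`: always on,
#'   independent lognormal brightness per frame with the given CV.
#' @param p_on Stationary per-frame on probability in `[0, 1]`.
#' @param on_off_correlation Lag-1 autocorrelation of the on/off chain in
#'   `[0, 1)` (0 = independent frames).
#' @param brightness_cv Coefficient of variation of multiplicative
#'   brightness noise (>= 0).
#' @return An object of class `fluctuation_model`.
#' @export
fluctuation_model <- function(kind = c("two_state_blinking", "lognormal_brightness"),
                              p_on = 0.7, on_off_correlation = 0.3,
                              brightness_cv = 0) {
  kind <- match.arg(kind)
  if (p_on < 0 || p_on > 1) stop("p_on must be in [0, 1]", call. = FALSE)
  if (on_off_correlation < 0 || on_off_correlation >= 1)
    stop("on_off_correlation must be in [0, 1)", call. = FALSE)
  if (brightness_cv < 0) stop("brightness_cv must be >= 0", call. = FALSE)
  structure(list(kind = kind, p_on = p_on,
                 on_off_correlation = on_off_correlation,
                 brightness_cv = brightness_cv),
            class = "fluctuation_model")
}

#' Camera noise model
#'
#' Photon counts are Poisson-distributed, scaled by `gain`, then Gaussian
#' read noise and a constant offset are added and the result is clipped to
#' the sensor bit depth.
#'
#' @param gain Counts per photon (> 0).
#' @param read_noise_sd Read noise standard deviation in counts (>= 0).
#' @param offset Dark offset in counts.
#' @param bit_depth Sensor bit depth (default 16).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(gain = 1, read_noise_sd = 2, offset = 100,
                         bit_depth = 16L) {
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0", call. = FALSE)
  if (bit_depth < 1 || bit_depth > 32) stop("bit_depth out of range", call. = FALSE)
  structure(list(gain = gain, read_noise_sd = read_noise_sd, offset = offset,
                 bit_depth = as.integer(bit_depth)),
            class = "camera_model")
}

#' Generate a fibril phantom skeleton
#'
#' Draws smooth random fibril centerlines (random-walk control points,
#' spline-resampled) in a rectangular object-space field. The right half of
#' the field is the designated dense region: it receives `dense_fraction` of
#' the fibrils, the left half the remainder, emulating tissue fields with
#' both densely and sparsely fibrous zones.
#'
#' @param field_size Field extent in micrometres: `c(width, height)` or a
#'   scalar for a square field.
#' @param n_fibrils Number of fibril centerlines (>= 0).
#' @param waviness Direction-change standard deviation per control-point
#'   step, in radians (default 0.4; 0 gives straight fibrils).
#' @param dense_fraction Fraction of fibrils assigned to the dense (right)
#'   half (default 0.8).
#' @param seed Integer RNG seed (required; generation is deterministic).
#' @param fibril_width Nominal ground-truth fibril width in micrometres
#'   (metadata used by downstream defaults; default 0.1).
#' @param raster_pitch Grid step of the ground-truth density raster in
#'   micrometres (default 0.3225, one 20x camera pixel).
#' @return An object of class `fibril_phantom` with empty `emitters` and an
#'   all-zero `density_raster`.
#' @export
generate_fibrils <- function(field_size, n_fibrils, waviness = 0.4,
                             dense_fraction = 0.8, seed,
                             fibril_width = 0.1, raster_pitch = 0.3225) {
  if (length(field_size) == 1) field_size <- c(field_size, field_size)
  if (any(!is.finite(field_size)) || any(field_size <= 0))
    stop("field_size must be positive", call. = FALSE)
  if (n_fibrils < 0 || n_fibrils != round(n_fibrils))
    stop("n_fibrils must be a nonnegative integer", call. = FALSE)
  if (dense_fraction < 0 || dense_fraction > 1)
    stop("dense_fraction must be in [0, 1]", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  area <- prod(field_size)
  if (n_fibrils > area)  # less than ~1 um^2 of field per fibril
    stop("field too small for the requested fibril count", call. = FALSE)

  w <- field_size[1]; h <- field_size[2]
  n_dense <- round(dense_fraction * n_fibrils)
  # region boxes: c(xmin, xmax)
  dense_box <- c(w / 2, w); sparse_box <- c(0, w / 2)

  centerlines <- withr::with_seed(seed, {
    draw_one <- function(box) {
      bw <- box[2] - box[1]
      n_ctrl <- 8L
      # fibril length ~ 60% of the region's characteristic size
      step <- 0.6 * sqrt(bw * h) / (n_ctrl - 1) * stats::runif(1, 0.7, 1.3)
      x <- numeric(n_ctrl); y <- numeric(n_ctrl)
      x[1] <- stats::runif(1, box[1], box[2]); y[1] <- stats::runif(1, 0, h)
      theta <- stats::runif(1, 0, 2 * pi)
      for (i in 2:n_ctrl) {
        theta <- theta + stats::rnorm(1, sd = waviness)
        x[i] <- x[i - 1] + step * cos(theta)
        y[i] <- y[i - 1] + step * sin(theta)
      }
      # spline-resample to a smooth dense polyline, then confine to the box
      t0 <- seq_len(n_ctrl)
      tt <- seq(1, n_ctrl, length.out = 12L * n_ctrl)
      sx <- stats::spline(t0, x, xout = tt)$y
      sy <- stats::spline(t0, y, xout = tt)$y
      eps <- 1e-9
      cl <- cbind(x = pmin(pmax(sx, box[1] + eps), box[2] - eps),
                  y = pmin(pmax(sy, eps), h - eps))
      # clamping can collapse consecutive vertices; drop the duplicates
      cl[c(TRUE, rowSums(abs(diff(cl))) > 0), , drop = FALSE]
    }
    c(lapply(seq_len(n_dense), function(i) draw_one(dense_box)),
      lapply(seq_len(n_fibrils - n_dense), function(i) draw_one(sparse_box)))
  })

  raster_dim <- c(max(1L, round(h / raster_pitch)), max(1L, round(w / raster_pitch)))
  structure(
    list(field_size = field_size, centerlines = centerlines,
         fibril_width = fibril_width,
         emitters = data.frame(x = numeric(0), y = numeric(0),
                               brightness = numeric(0)),
         density_raster = matrix(0, raster_dim[1], raster_dim[2]),
         raster_pitch = raster_pitch, dense_box = dense_box, seed = seed),
    class = "fibril_phantom")
}

#' @export
print.fibril_phantom <- function(x, ...) {
  cat(sprintf("Fibril phantom: %g x %g um field, %d fibrils, %d emitters\n",
              x$field_size[1], x$field_size[2], length(x$centerlines),
              nrow(x$emitters)))
  invisible(x)
}

# Sum of polyline arc lengths, optionally restricted to segments whose
# midpoints fall in an x-interval box c(xmin, xmax).
fibril_length <- function(phantom, box = NULL) {
  total <- 0
  for (cl in phantom$centerlines) {
    dx <- diff(cl[, 1]); dy <- diff(cl[, 2])
    len <- sqrt(dx^2 + dy^2)
    if (!is.null(box)) {
      mx <- (cl[-1, 1] + cl[-nrow(cl), 1]) / 2
      len <- len[mx >= box[1] & mx < box[2]]
    }
    total <- total + sum(len)
  }
  total
}

#' Dense / sparse / background region labels on the phantom raster
#'
#' @param phantom A [fibril_phantom].
#' @return Character matrix with entries `"dense"` and `"sparse"`, aligned
#'   to the phantom's `density_raster`.
#' @export
region_labels <- function(phantom) {
  stopifnot(inherits(phantom, "fibril_phantom"))
  r <- phantom$density_raster
  xc <- (seq_len(ncol(r)) - 0.5) * phantom$raster_pitch
  lab <- matrix("sparse", nrow(r), ncol(r))
  lab[, xc >= phantom$dense_box[1] & xc < phantom$dense_box[2]] <- "dense"
  lab
}

#' Place fluctuating emitters along the fibrils
#'
#' Emitters are dropped along each centerline as a Poisson process of the
#' given linear density, then displaced perpendicular to the local fibril
#' direction by Gaussian jitter, emulating the transverse extent of a
#' fibril. The ground-truth density raster is rebuilt as the per-cell
#' emitter count.
#'
#' @param phantom A [fibril_phantom].
#' @param linear_density Mean emitters per micrometre of fibril length (> 0).
#' @param jitter_sd Transverse jitter standard deviation in micrometres
#'   (default `phantom$fibril_width / 2.3548`, so the fibril's emitter
#'   profile has FWHM equal to the nominal width).
#' @param mean_brightness Mean emitter brightness in photons per frame
#'   (default 100).
#' @param seed Integer RNG seed.
#' @return The phantom with `emitters` and `density_raster` filled in.
#' @export
place_emitters <- function(phantom, linear_density, jitter_sd = NULL,
                           mean_brightness = 100, seed) {
  stopifnot(inherits(phantom, "fibril_phantom"))
  if (linear_density <= 0) stop("linear_density must be positive", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(jitter_sd)) jitter_sd <- phantom$fibril_width / 2.3548
  w <- phantom$field_size[1]; h <- phantom$field_size[2]

  pts <- withr::with_seed(seed, {
    out <- list()
    for (cl in phantom$centerlines) {
      # drop duplicate consecutive vertices (produced by boundary clamping)
      keep <- c(TRUE, rowSums(abs(diff(cl))) > 0)
      cl <- cl[keep, , drop = FALSE]
      if (nrow(cl) < 2) next
      dx <- diff(cl[, 1]); dy <- diff(cl[, 2])
      seg <- sqrt(dx^2 + dy^2)
      total <- sum(seg)
      if (total <= 0) next
      n <- stats::rpois(1, total * linear_density)
      if (n == 0) next
      u <- stats::runif(n) * total
      cum <- c(0, cumsum(seg))
      i <- findInterval(u, cum, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), length(seg))
      frac <- (u - cum[i]) / seg[i]
      px <- cl[i, 1] + frac * dx[i]
      py <- cl[i, 2] + frac * dy[i]
      # unit normal to the local segment
      nx <- -dy[i] / seg[i]; ny <- dx[i] / seg[i]
      off <- if (jitter_sd > 0) stats::rnorm(n, sd = jitter_sd) else numeric(n)
      out[[length(out) + 1L]] <- cbind(px + off * nx, py + off * ny)
    }
    if (length(out)) do.call(rbind, out) else matrix(0, 0, 2)
  })
  eps <- 1e-9
  x <- pmin(pmax(pts[, 1], eps), w - eps)
  y <- pmin(pmax(pts[, 2], eps), h - eps)
  phantom$emitters <- data.frame(x = x, y = y,
                                 brightness = rep(mean_brightness, length(x)))
  phantom$density_raster <- bin_emitters(x, y, dim(phantom$density_raster),
                                         phantom$raster_pitch)
  phantom
}

bin_emitters <- function(x, y, raster_dim, pitch) {
  r <- matrix(0, raster_dim[1], raster_dim[2])
  if (length(x) == 0) return(r)
  ri <- pmin(pmax(ceiling(y / pitch), 1L), raster_dim[1])
  ci <- pmin(pmax(ceiling(x / pitch), 1L), raster_dim[2])
  for (k in seq_along(ri)) r[ri[k], ci[k]] <- r[ri[k], ci[k]] + 1
  r
}

#' Simulate per-frame emitter brightness
#'
#' @param emitters Data frame with a `brightness` column (mean photons per
#'   frame), e.g. `phantom$emitters`.
#' @param model A [fluctuation_model()].
#' @param K Number of frames (>= 1).
#' @param seed Integer RNG seed.
#' @return Emitters x K nonnegative matrix of per-frame brightness; rows are
#'   statistically independent across emitters.
#' @export
simulate_fluctuations <- function(emitters, model, K, seed) {
  stopifnot(inherits(model, "fluctuation_model"))
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- nrow(emitters)
  b <- emitters$brightness
  withr::with_seed(seed, {
    if (model$kind == "two_state_blinking") {
      p <- model$p_on; rho <- model$on_off_correlation
      states <- matrix(0L, n, K)
      if (n > 0) {
        states[, 1] <- stats::rbinom(n, 1, p)
        if (K > 1) {
          p_stay <- p + rho * (1 - p)    # P(on -> on)
          p_rise <- (1 - rho) * p        # P(off -> on)
          for (k in 2:K) {
            u <- stats::runif(n)
            states[, k] <- ifelse(states[, k - 1] == 1L,
                                  as.integer(u < p_stay),
                                  as.integer(u < p_rise))
          }
        }
      }
      m <- states * b
      if (model$brightness_cv > 0 && n > 0) {
        sdl <- sqrt(log(1 + model$brightness_cv^2))
        m <- m * matrix(stats::rlnorm(n * K, -sdl^2 / 2, sdl), n, K)
      }
      m
    } else {
      if (n == 0) return(matrix(0, 0, K))
      if (model$brightness_cv > 0) {
        sdl <- sqrt(log(1 + model$brightness_cv^2))
        b * matrix(stats::rlnorm(n * K, -sdl^2 / 2, sdl), n, K)
      } else {
        matrix(rep(b, K), n, K)
      }
    }
  })
}

# Pixels x emitters matrix of expected photon fractions: the optics PSF
# centred on each emitter, integrated over every camera pixel footprint
# (analytic for the Gaussian model). Row-major pixel order is not needed
# here; pixels are indexed (row, col) column-major as in R matrices.
emitter_pixel_matrix <- function(x, y, optics, H, W) {
  pitch <- object_pixel_pitch(optics)
  n <- length(x)
  e <- matrix(0, H * W, n)
  if (n == 0) return(e)
  if (optics$psf_model != "gaussian")
    stop("rendering supports the gaussian PSF model", call. = FALSE)
  s <- psf_sigma(optics)
  edges_r <- (0:H) * pitch
  edges_c <- (0:W) * pitch
  for (j in seq_len(n)) {
    iy <- stats::pnorm((edges_r[-1] - y[j]) / s) -
          stats::pnorm((edges_r[-(H + 1)] - y[j]) / s)
    ix <- stats::pnorm((edges_c[-1] - x[j]) / s) -
          stats::pnorm((edges_c[-(W + 1)] - x[j]) / s)
    e[, j] <- as.vector(outer(iy, ix))
  }
  e
}

#' Expected (noise-free) photon image
#'
#' The PSF-blurred, pixel-integrated emitter field for one vector of
#' emitter brightnesses, in expected photons per pixel: the noise-free
#' diffraction-limited image of the phantom.
#'
#' @param phantom A [fibril_phantom] with emitters placed.
#' @param brightness Per-emitter brightness vector (photons/frame); defaults
#'   to the emitters' mean brightness.
#' @param optics An [optics_config()].
#' @return H x W matrix of expected photons, where H and W cover the
#'   phantom field at the optics' object-space pixel pitch.
#' @export
render_expected <- function(phantom, brightness = NULL, optics) {
  stopifnot(inherits(phantom, "fibril_phantom"))
  pitch <- object_pixel_pitch(optics)
  H <- max(1L, round(phantom$field_size[2] / pitch))
  W <- max(1L, round(phantom$field_size[1] / pitch))
  if (is.null(brightness)) brightness <- phantom$emitters$brightness
  e <- emitter_pixel_matrix(phantom$emitters$x, phantom$emitters$y, optics, H, W)
  matrix(e %*% brightness, H, W)
}

#' Render a noisy fluctuation stack from a phantom
#'
#' Per frame: each emitter's continuous image (the optics PSF integrated
#' over camera pixel footprints) is scaled by that frame's brightness; the
#' summed expected photon image is corrupted by Poisson shot noise, scaled
#' by the camera gain, then Gaussian read noise and the dark offset are
#' added and the frame is clipped to the sensor bit depth.
#'
#' @param phantom A [fibril_phantom] with emitters placed.
#' @param brightness_matrix Emitters x K matrix from
#'   [simulate_fluctuations()].
#' @param optics An [optics_config()].
#' @param camera A [camera_model()].
#' @param seed Integer RNG seed.
#' @param background Expected background photons per pixel per frame, as a
#'   scalar or an H x W matrix (e.g. a defocused out-of-focus fibril layer
#'   from [blur_density()]); Poisson shot noise is applied per frame.
#'   Default 0 (no background).
#' @return An [image_stack()]; a warning is raised if more than 1% of pixels
#'   saturate.
#' @export
render_stack <- function(phantom, brightness_matrix, optics, camera, seed,
                         background = 0) {
  stopifnot(inherits(phantom, "fibril_phantom"))
  stopifnot(inherits(camera, "camera_model"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- nrow(phantom$emitters)
  if (!is.matrix(brightness_matrix) || nrow(brightness_matrix) != n)
    stop("brightness_matrix rows must match the phantom emitter count",
         call. = FALSE)
  K <- ncol(brightness_matrix)
  pitch <- object_pixel_pitch(optics)
  H <- max(1L, round(phantom$field_size[2] / pitch))
  W <- max(1L, round(phantom$field_size[1] / pitch))
  e <- emitter_pixel_matrix(phantom$emitters$x, phantom$emitters$y, optics, H, W)
  lambda <- e %*% brightness_matrix           # expected photons, (H*W) x K
  if (is.matrix(background)) {
    if (!all(dim(background) == c(H, W)))
      stop("background matrix must match the rendered frame size", call. = FALSE)
    lambda <- lambda + as.vector(background)
  } else if (background[1] != 0) {
    lambda <- lambda + background[1]
  }
  maxcount <- 2^camera$bit_depth - 1
  frames <- withr::with_seed(seed, {
    photons <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda), K)
    counts <- camera$gain * photons + camera$offset +
      matrix(stats::rnorm(length(lambda), sd = camera$read_noise_sd),
             nrow(lambda), K)
    counts
  })
  sat <- mean(frames > maxcount)
  if (sat > 0.01)
    warning(sprintf("%.1f%% of pixels saturate the %d-bit sensor",
                    100 * sat, camera$bit_depth), call. = FALSE)
  frames <- pmin(pmax(frames, 0), maxcount)
  image_stack(array(frames, dim = c(H, W, K)), pixel_pitch_object = pitch,
              metadata = list(phantom_seed = phantom$seed, render_seed = seed))
}

#' Simulate a complete tissue-like fluctuation stack
#'
#' Bundles the full study conditions into one reproducible generator: an
#' in-focus fibril phantom with dense and sparse halves, independently
#' blinking emitters, and an out-of-focus background layer — a second,
#' statistically identical fibril layer defocus-blurred and scaled relative
#' to the mean in-focus signal — rendered through the optics and camera
#' models. The background emulates the fibril mass of a thick section lying
#' outside the depth of field (a 5 um section imaged at ~1.2 um depth of
#' field carries several times more out-of-focus than in-focus material),
#' and sets the signal-to-background ratio at fibrils near the lower end of
#' the method's working range.
#'
#' @param seed Integer seed controlling every random draw.
#' @param optics An [optics_config()]; default the 20x / 0.80 NA
#'   configuration (460 nm emission, 6.45 um camera pixel).
#' @param field_pixels Field size in camera pixels (square; default 64).
#' @param n_fibrils In-focus fibril count (default 12).
#' @param dense_fraction Fraction of fibrils in the dense half (default 0.7).
#' @param linear_density Emitters per micrometre of fibril (default 5).
#' @param mean_brightness Mean emitter brightness, photons/frame
#'   (default 80).
#' @param frames Stack length K (default 500).
#' @param fluctuation A [fluctuation_model()]; default blinking with
#'   `p_on = 0.7`, persistence 0.3, brightness CV 0.3.
#' @param camera A [camera_model()]; default gain 1, read noise 2, offset
#'   100, 16 bit.
#' @param background_ratio Out-of-focus background level as a multiple of
#'   the mean in-focus signal (default 2.5; 0 disables the background).
#' @param background_sigma Defocus blur sigma of the background layer in
#'   micrometres (default 0.8).
#' @param subpixels Ground-truth raster resolution, sub-pixels per camera
#'   pixel (default 10, matching the default reconstruction grid).
#' @return A list with `phantom` (ground truth), `stack` (the rendered
#'   [image_stack()]), `background` (expected background photons per pixel),
#'   and `optics`.
#' @export
simulate_fibril_stack <- function(seed,
                                  optics = optics_config(0.460, 0.80, 20, 6.45),
                                  field_pixels = 64L,
                                  n_fibrils = 12L,
                                  dense_fraction = 0.7,
                                  linear_density = 5,
                                  mean_brightness = 80,
                                  frames = 500L,
                                  fluctuation = fluctuation_model(
                                    p_on = 0.7, on_off_correlation = 0.3,
                                    brightness_cv = 0.3),
                                  camera = camera_model(gain = 1,
                                                        read_noise_sd = 2,
                                                        offset = 100),
                                  background_ratio = 2.5,
                                  background_sigma = 0.8,
                                  subpixels = 10L) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  pitch <- object_pixel_pitch(optics)
  fs <- field_pixels * pitch
  phantom <- generate_fibrils(field_size = fs, n_fibrils = n_fibrils,
                              waviness = 0.4, dense_fraction = dense_fraction,
                              seed = seed, raster_pitch = pitch / subpixels)
  phantom <- place_emitters(phantom, linear_density, jitter_sd = 0.03,
                            mean_brightness = mean_brightness, seed = seed + 1L)
  bmat <- simulate_fluctuations(phantom$emitters, fluctuation, K = frames,
                                seed = seed + 2L)
  background <- 0
  if (background_ratio > 0) {
    oof <- generate_fibrils(field_size = fs, n_fibrils = n_fibrils,
                            waviness = 0.4, dense_fraction = dense_fraction,
                            seed = seed + 7L, raster_pitch = pitch)
    oof <- place_emitters(oof, linear_density, jitter_sd = 0.03,
                          mean_brightness = 1, seed = seed + 8L)
    haze <- blur_density(oof$density_raster, background_sigma,
                         pixel_size = pitch)
    # scale so the mean background equals background_ratio x the mean
    # in-focus photon signal per pixel
    infocus_mean <- sum(phantom$emitters$brightness) * fluctuation$p_on /
      (field_pixels^2)
    if (mean(haze) > 0)
      background <- haze * (background_ratio * infocus_mean / mean(haze))
  }
  stack <- render_stack(phantom, bmat, optics, camera, seed = seed + 3L,
                        background = background)
  list(phantom = phantom, stack = stack, background = background,
       optics = optics)
}

#' Blur a ground-truth density raster
#'
#' Gaussian blur of the emitter-count raster with reflective boundaries
#' (total intensity conserved). A large sigma emulates a diffraction-limited
#' rendering of the phantom, a small sigma a super-resolved one.
#'
#' @param density_raster Numeric matrix (e.g. `phantom$density_raster`).
#' @param blur_sigma Gaussian sigma. Interpreted in micrometres when
#'   `pixel_size` is given, else in raster pixels.
#' @param pixel_size Optional raster pitch in micrometres.
#' @return Blurred matrix of the same dimensions.
#' @export
blur_density <- function(density_raster, blur_sigma, pixel_size = NULL) {
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (!is.null(pixel_size)) blur_sigma <- blur_sigma / pixel_size
  gaussian_blur(density_raster, blur_sigma)
}
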