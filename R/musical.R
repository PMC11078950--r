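# Reconstruction core: per-window singular value decomposition of the
# fluctuation stack, separation of signal and noise subspaces, evaluation of
# the indicator function (signal/noise)^alpha on a sub-pixel grid, and
# stitching of window results into a full super-resolved map.
#
# Conventions, fixed package-wide:
#   * images are H x W matrices, stacks H x W x K arrays (frames last);
#   * pixel (r, c) (1-based) is centred at ((r-0.5)*pitch, (c-0.5)*pitch)
#     in object-space micrometres, origin at the image corner;
#   * window crops are vectorized row-major: row 1 left-to-right, then
#     row 2, ... so entry (a, b) of an N x N crop lands at (a-1)*N + b.

#' Fluctuation image stack
#'
#' Container for a multi-frame single-channel acquisition: K frames of
#' H x W nonnegative intensities with object-space pixel-pitch metadata.
#'
#' @param frames H x W x K numeric array, or a list of K equally sized
#'   matrices. All intensities must be finite and nonnegative; K >= 2.
#' @param pixel_pitch_object Object-space size of one camera pixel in
#'   micrometres (camera pitch / magnification).
#' @param frame_interval Optional time between frames in seconds (metadata).
#' @param metadata Optional free-form acquisition record (list).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_pitch_object, frame_interval = NULL,
                        metadata = list()) {
  if (is.list(frames) && !is.array(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1)
      stop("all frames must have the same shape", call. = FALSE)
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be an H x W x K array or list of matrices", call. = FALSE)
  if (dim(frames)[3] < 2)
    stop("an image stack needs at least 2 frames", call. = FALSE)
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame intensities must be finite and nonnegative", call. = FALSE)
  if (!is.finite(pixel_pitch_object) || pixel_pitch_object <= 0)
    stop("pixel_pitch_object must be positive", call. = FALSE)
  structure(
    list(frames = frames, pixel_pitch_object = pixel_pitch_object,
         frame_interval = frame_interval, metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d x %d pixels, %d frames, %.4g um/pixel\n",
              d[1], d[2], d[3], x$pixel_pitch_object))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Temporal mean frame
#'
#' Per-pixel mean over frames: the diffraction-limited image a long exposure
#' would record (up to noise).
#'
#' @param stack An [image_stack()].
#' @return H x W matrix.
#' @export
mean_frame <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  rowMeans(stack$frames, dims = 2)
}

#' Reconstruction parameters
#'
#' @param window_size Odd sliding-window side length N in camera pixels, or
#'   `NULL` to derive it from the optics at reconstruction time via
#'   [default_window_size()] (the PSF's spatial spread plus context).
#' @param subpixels Sub-pixelation factor s: each camera pixel is resolved
#'   into an s x s grid of indicator evaluations (default 10).
#' @param alpha Contrast exponent applied to the signal/noise ratio
#'   (default 4).
#' @param threshold_mode `"auto_knee"` (default) picks the signal rank per
#'   window at the knee of the singular-value spectrum; `"manual"` keeps all
#'   singular values at or above `threshold_value`.
#' @param threshold_value Absolute singular-value cutoff, used only in
#'   manual mode.
#' @param stride Window stride in camera pixels (default 1).
#' @param stitch How sliding-window results are combined into the map.
#'   `"average"` (default): every window evaluates the indicator over its
#'   full N x N footprint and each sub-pixel reports the mean over all
#'   windows covering it, which suppresses the window-to-window variance of
#'   individual indicator estimates. `"center"`: each window writes only its
#'   central camera pixel's s x s block (cheaper, higher variance).
#' @param mean_subtract If `TRUE`, subtract the per-pixel temporal mean from
#'   each window matrix before decomposition (default `FALSE`: raw
#'   intensities are decomposed).
#' @return An object of class `musical_params`.
#' @export
musical_params <- function(window_size = NULL, subpixels = 10L, alpha = 4,
                           threshold_mode = c("auto_knee", "manual"),
                           threshold_value = NULL, stride = 1L,
                           stitch = c("average", "center"),
                           mean_subtract = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  stitch <- match.arg(stitch)
  if (!is.null(window_size)) {
    if (window_size < 3 || window_size %% 2 != 1)
      stop("window_size must be an odd integer >= 3", call. = FALSE)
  }
  if (subpixels < 1 || subpixels != round(subpixels))
    stop("subpixels must be a positive integer", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0)
    stop("alpha must be nonnegative", call. = FALSE)
  if (threshold_mode == "manual" &&
      (is.null(threshold_value) || !is.finite(threshold_value) || threshold_value <= 0))
    stop("manual threshold_mode requires a positive threshold_value", call. = FALSE)
  if (stride < 1 || stride != round(stride))
    stop("stride must be a positive integer", call. = FALSE)
  structure(
    list(window_size = if (is.null(window_size)) NULL else as.integer(window_size),
         subpixels = as.integer(subpixels), alpha = alpha,
         threshold_mode = threshold_mode, threshold_value = threshold_value,
         stride = as.integer(stride), stitch = stitch,
         mean_subtract = isTRUE(mean_subtract)),
    class = "musical_params")
}

#' Default window size for an optics configuration
#'
#' Smallest odd integer of camera pixels covering two Rayleigh radii on
#' either side of the central pixel (four Rayleigh radii in total), so one
#' window spans the PSF's central lobe plus enough surrounding context to
#' sample the noise subspace well: with an N x N window the decomposition
#' lives in an N^2-dimensional pixel space, and a window that barely covers
#' the PSF leaves too few dimensions above the typical signal rank of a
#' dense field for a stable signal/noise split.
#'
#' @param optics An [optics_config()].
#' @return Odd integer >= 3.
#' @export
default_window_size <- function(optics) {
  pitch <- object_pixel_pitch(optics)
  n <- ceiling(4 * rayleigh_limit(optics) / pitch + 1)
  n <- max(3L, as.integer(n))
  if (n %% 2 == 0) n <- n + 1L
  n
}

#' Extract a window matrix from a stack
#'
#' Crops the N x N window centred on a camera pixel from every frame and
#' vectorizes each crop row-major into a column, giving the N^2 x K matrix
#' that the subspace decomposition operates on.
#'
#' @param stack An [image_stack()].
#' @param center Integer vector `c(row, col)` of the central camera pixel.
#' @param N Odd window size in camera pixels.
#' @return N^2 x K numeric matrix; column j is frame j's crop.
#' @export
extract_window <- function(stack, center, N) {
  stopifnot(inherits(stack, "image_stack"))
  if (N < 1 || N %% 2 != 1) stop("N must be odd and positive", call. = FALSE)
  d <- dim(stack$frames)
  h <- (N - 1L) %/% 2L
  r0 <- center[1] - h; r1 <- center[1] + h
  c0 <- center[2] - h; c1 <- center[2] + h
  if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2])
    stop("window extends outside the image; borders must be masked by the caller",
         call. = FALSE)
  crop <- stack$frames[r0:r1, c0:c1, , drop = FALSE]
  # row-major vectorization: transpose each frame's crop before flattening
  out <- matrix(aperm(crop, c(2, 1, 3)), nrow = N * N, ncol = d[3])
  out
}

#' Subspace decomposition of a window matrix
#'
#' Thin singular value decomposition of the N^2 x K window matrix. The left
#' singular vectors ("eigenimages") ordered by nonincreasing singular value
#' form an orthonormal basis in which the leading vectors capture correlated
#' emitter structure and the trailing ones noise.
#'
#' @param window_matrix N^2 x K numeric matrix (columns are frames).
#' @return An object of class `subspace_basis` with `eigenimages`
#'   (N^2 x min(N^2, K) orthonormal columns), `singular_values`
#'   (nonincreasing), and `signal_rank` (`NA` until thresholded).
#' @export
decompose_window <- function(window_matrix) {
  if (!is.matrix(window_matrix) || any(!is.finite(window_matrix)))
    stop("window matrix must be a finite numeric matrix", call. = FALSE)
  k <- min(dim(window_matrix))
  sv <- svd(window_matrix, nu = k, nv = 0)
  structure(
    list(eigenimages = sv$u, singular_values = sv$d[seq_len(k)],
         signal_rank = NA_integer_),
    class = "subspace_basis")
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat(sprintf("Subspace basis: %d eigenimages of length %d, signal rank %s\n",
              ncol(x$eigenimages), nrow(x$eigenimages),
              ifelse(is.na(x$signal_rank), "unset", x$signal_rank)))
  invisible(x)
}

#' Knee-of-spectrum signal rank
#'
#' Chooses the number of signal eigenimages as the knee of the
#' singular-value spectrum: the index at maximum perpendicular distance
#' between the log10 singular-value curve and the straight chord joining
#' its endpoints. Values are clamped to a floor of `1e-12 * max` before
#' taking logs so trailing numerical zeros cannot dominate.
#'
#' @param singular_values Nonincreasing nonnegative vector, length >= 3.
#' @return Integer signal rank r >= 1. A flat or log-linear spectrum has no
#'   knee; r = 1 is returned with a degenerate-spectrum warning.
#' @export
knee_threshold <- function(singular_values) {
  sv <- singular_values
  if (length(sv) < 3) stop("need at least 3 singular values", call. = FALSE)
  if (any(!is.finite(sv)) || any(sv < 0))
    stop("singular values must be finite and nonnegative", call. = FALSE)
  mx <- max(sv)
  if (mx <= 0) {
    warning("degenerate spectrum: all singular values are zero", call. = FALSE)
    return(1L)
  }
  floor_val <- 1e-12 * mx
  n <- max(which(sv > floor_val))   # trailing numerical zeros carry no knee
  if (n < 3) {
    warning("degenerate spectrum: fewer than 3 values above the numerical floor",
            call. = FALSE)
    return(1L)
  }
  y <- log10(sv[seq_len(n)])
  x <- seq_len(n)
  # perpendicular distance from (x, y) to the chord (1, y1) -- (n, yn)
  dx <- n - 1; dy <- y[n] - y[1]
  dist <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-9) {
    warning("degenerate spectrum: no knee (flat or log-linear); using rank 1",
            call. = FALSE)
    return(1L)
  }
  # first index attaining the maximum within round-off (ties -> smaller rank)
  as.integer(which(dist >= max(dist) * (1 - 1e-12))[1])
}

#' Set the signal rank of a subspace basis
#'
#' @param basis A [decompose_window()] result.
#' @param rank Integer in `[0, n_eigenimages]`, or `"auto"` to apply
#'   [knee_threshold()] to the basis' singular values.
#' @return The basis with `signal_rank` set.
#' @export
set_signal_rank <- function(basis, rank = "auto") {
  stopifnot(inherits(basis, "subspace_basis"))
  if (identical(rank, "auto")) rank <- knee_threshold(basis$singular_values)
  if (rank < 0 || rank > ncol(basis$eigenimages))
    stop("signal rank out of range", call. = FALSE)
  basis$signal_rank <- as.integer(rank)
  basis
}

#' PSF steering vector for a window
#'
#' The unit-norm vectorized image a point emitter at `test_point` would cast
#' on the window's camera pixels: the PSF centred at the test point,
#' integrated over each of the N^2 pixel footprints, vectorized row-major
#' (the [extract_window()] order) and normalized to unit Euclidean norm.
#'
#' The Gaussian model integrates analytically (separable error functions);
#' the Airy model uses oversampled midpoint quadrature per pixel.
#'
#' @param optics An [optics_config()] providing the PSF model.
#' @param test_point Numeric `c(x, y)` in object-space micrometres relative
#'   to the centre of the window's central pixel.
#' @param N Odd window size in camera pixels.
#' @param pitch Object-space pixel pitch in micrometres.
#' @param oversample Quadrature points per pixel side for the Airy model
#'   (default 16).
#' @return Unit-norm numeric vector of length N^2.
#' @export
psf_vector <- function(optics, test_point, N, pitch, oversample = 16L) {
  stopifnot_optics(optics)
  if (N < 1 || N %% 2 != 1) stop("N must be odd", call. = FALSE)
  h <- (N - 1) / 2
  half <- (h + 0.5) * pitch
  if (abs(test_point[1]) > half || abs(test_point[2]) > half)
    stop("test point lies outside the window footprint", call. = FALSE)
  offs <- (-h:h) * pitch
  if (optics$psf_model == "gaussian") {
    s <- psf_sigma(optics)
    ix <- stats::pnorm((offs + 0.5 * pitch - test_point[1]) / s) -
          stats::pnorm((offs - 0.5 * pitch - test_point[1]) / s)
    iy <- stats::pnorm((offs + 0.5 * pitch - test_point[2]) / s) -
          stats::pnorm((offs - 0.5 * pitch - test_point[2]) / s)
    m <- outer(iy, ix)             # rows a (y), cols b (x)
  } else {
    q <- as.integer(oversample)
    sub <- ((seq_len(q) - 0.5) / q - 0.5) * pitch
    m <- matrix(0, N, N)
    for (a in seq_len(N)) {
      for (b in seq_len(N)) {
        px <- offs[b] + sub - test_point[1]
        py <- offs[a] + sub - test_point[2]
        r <- sqrt(outer(py^2, px^2, `+`))
        m[a, b] <- mean(psf_radial(optics, r)) * pitch^2
      }
    }
  }
  v <- as.vector(t(m))  # row-major
  nrm <- sqrt(sum(v^2))
  if (nrm < .Machine$double.eps)
    stop("degenerate test point: PSF has no support on the window", call. = FALSE)
  v / nrm
}

#' Indicator function value at a test point
#'
#' Projects the PSF steering vector onto the signal and noise subspaces of a
#' window basis and returns `(|P_S g| / |P_N g|)^alpha`, the super-resolution
#' score: large where the PSF at the test point is explained by correlated
#' (signal) structure, small where it falls into the noise subspace.
#'
#' @param basis A [subspace_basis] with `signal_rank` set (see
#'   [set_signal_rank()]).
#' @param psf_vec Unit-norm steering vector from [psf_vector()].
#' @param alpha Contrast exponent (>= 0).
#' @param noise_floor Lower bound applied to the noise norm to keep the
#'   ratio finite (default 1e-12).
#' @return Nonnegative scalar.
#' @export
indicator <- function(basis, psf_vec, alpha = 4, noise_floor = 1e-12) {
  stopifnot(inherits(basis, "subspace_basis"))
  r <- basis$signal_rank
  n <- ncol(basis$eigenimages)
  if (is.na(r)) stop("signal_rank is unset; call set_signal_rank()", call. = FALSE)
  if (r == 0) stop("signal rank 0: signal subspace is empty", call. = FALSE)
  if (r >= n) stop("signal rank equals the basis size: noise subspace is empty",
                   call. = FALSE)
  p <- drop(crossprod(basis$eigenimages, psf_vec))
  signal <- sqrt(sum(p[seq_len(r)]^2))
  noise <- sqrt(sum(p[(r + 1):n]^2))
  (signal / max(noise, noise_floor))^alpha
}

# Precompute the N^2 x n_pts matrix of steering vectors for the sub-pixel
# test points of a window: either the s x s grid of the central camera
# pixel, or the (N*s) x (N*s) grid of the full window footprint. Column
# order is row-major over the test-point grid: (u, v) -> (u-1)*ncol + v.
steering_matrix <- function(optics, N, pitch, s,
                            footprint = c("center", "window")) {
  footprint <- match.arg(footprint)
  span <- if (footprint == "center") s else N * s
  shift <- if (footprint == "center") 0.5 else N / 2
  offsets <- ((seq_len(span) - 0.5) / s - shift) * pitch
  g <- matrix(0, N * N, span * span)
  for (u in seq_len(span)) {
    for (v in seq_len(span)) {
      g[, (u - 1L) * span + v] <-
        psf_vector(optics, c(offsets[v], offsets[u]), N, pitch)
    }
  }
  g
}

#' Super-resolved indicator map reconstruction
#'
#' Slides an N x N window across the stack; for each window position,
#' decomposes the N^2 x K window matrix, separates signal from noise
#' subspaces per `threshold_mode`, evaluates the indicator function on the
#' s x s sub-pixel grid of the window's central camera pixel, and stitches
#' the central-pixel blocks into an (s*H) x (s*W) map. A border of
#' (N-1)/2 camera pixels cannot host a full window and is masked invalid,
#' as are degenerate windows (numerical rank <= 1, or an empty signal or
#' noise subspace).
#'
#' The result is deterministic given its inputs, and exactly invariant to
#' positive rescaling of the stack under auto-knee thresholding.
#'
#' @param stack An [image_stack()].
#' @param params A [musical_params()]; a `NULL` `window_size` is derived
#'   from the optics via [default_window_size()].
#' @param optics An [optics_config()].
#' @return An object of class `indicator_map`: `values` ((s*H) x (s*W),
#'   `NA` where invalid), `valid_mask`, `pixel_pitch` (map pixel size, um),
#'   `params`, `optics`, `n_degenerate` (masked interior windows) and
#'   `signal_ranks` (per-window rank matrix, `NA` at masked positions).
#' @export
reconstruct <- function(stack, params = musical_params(), optics) {
  stopifnot(inherits(stack, "image_stack"))
  stopifnot(inherits(params, "musical_params"))
  stopifnot_optics(optics)
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; K <- d[3]
  N <- if (is.null(params$window_size)) default_window_size(optics) else params$window_size
  if (H <= N || W <= N)
    stop("stack must be larger than the window in both dimensions", call. = FALSE)
  if (K < N * N)
    warning(sprintf("only %d frames for a %d-pixel window (K < N^2); noise subspace is truncated",
                    K, N * N), call. = FALSE)
  pitch_stack <- stack$pixel_pitch_object
  pitch_optics <- object_pixel_pitch(optics)
  if (abs(pitch_stack - pitch_optics) > 1e-6 * pitch_optics)
    warning(sprintf("stack pixel pitch (%.4g um) differs from optics (%.4g um); using the stack's",
                    pitch_stack, pitch_optics), call. = FALSE)
  pitch <- pitch_stack
  s <- params$subpixels
  averaging <- params$stitch == "average"
  g <- steering_matrix(optics, N, pitch, s,
                       footprint = if (averaging) "window" else "center")
  span <- if (averaging) N * s else s

  values <- matrix(NA_real_, s * H, s * W)
  if (averaging) {
    acc <- matrix(0, s * H, s * W)
    cnt <- matrix(0L, s * H, s * W)
  }
  ranks <- matrix(NA_integer_, H, W)
  h <- (N - 1L) %/% 2L
  centers_r <- seq.int(h + 1L, H - h, by = params$stride)
  centers_c <- seq.int(h + 1L, W - h, by = params$stride)
  n_degenerate <- 0L

  for (rc in centers_r) {
    for (cc in centers_c) {
      m <- extract_window(stack, c(rc, cc), N)
      if (params$mean_subtract) m <- m - rowMeans(m)
      k <- min(dim(m))
      sv <- svd(m, nu = k, nv = 0)
      d_sv <- sv$d[seq_len(k)]
      numrank <- sum(d_sv > 1e-10 * max(d_sv, .Machine$double.xmin))
      r <- if (numrank <= 1L) {
        0L  # no noise-subspace mass: degenerate
      } else if (params$threshold_mode == "manual") {
        sum(d_sv >= params$threshold_value)
      } else {
        withCallingHandlers(knee_threshold(d_sv),
                            warning = function(w) invokeRestart("muffleWarning"))
      }
      if (r < 1L || r >= k) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      ranks[rc, cc] <- r
      p <- crossprod(sv$u, g)                       # k x span^2
      sig <- sqrt(.colSums(p[seq_len(r), , drop = FALSE]^2, r, span * span))
      noi <- sqrt(.colSums(p[(r + 1):k, , drop = FALSE]^2, k - r, span * span))
      vals <- (sig / pmax(noi, 1e-12))^params$alpha
      block <- matrix(vals, span, span, byrow = TRUE)  # rows u (y), cols v (x)
      if (averaging) {
        rows <- ((rc - h - 1L) * s + 1L):((rc + h) * s)
        cols <- ((cc - h - 1L) * s + 1L):((cc + h) * s)
        acc[rows, cols] <- acc[rows, cols] + block
        cnt[rows, cols] <- cnt[rows, cols] + 1L
      } else {
        values[((rc - 1L) * s + 1L):(rc * s), ((cc - 1L) * s + 1L):(cc * s)] <- block
      }
    }
  }
  if (averaging) {
    hit <- cnt > 0L
    values[hit] <- acc[hit] / cnt[hit]
    # the border of h camera pixels never hosts a full window; mask it
    border_r <- c(seq_len(h * s), (s * H - h * s + 1L):(s * H))
    border_c <- c(seq_len(h * s), (s * W - h * s + 1L):(s * W))
    values[border_r, ] <- NA_real_
    values[, border_c] <- NA_real_
  }
  if (n_degenerate > 0)
    warning(sprintf("%d degenerate window(s) masked (empty signal or noise subspace)",
                    n_degenerate), call. = FALSE)
  structure(
    list(values = values, valid_mask = !is.na(values),
         pixel_pitch = pitch / s, params = params, optics = optics,
         window_size = N, n_degenerate = n_degenerate, signal_ranks = ranks),
    class = "indicator_map")
}

#' @export
print.indicator_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Indicator map: %d x %d sub-pixels (%.4g um each), window N = %d, alpha = %g\n",
              d[1], d[2], x$pixel_pitch, x$window_size, x$params$alpha))
  cat(sprintf("  valid: %.1f%%; degenerate windows: %d\n",
              100 * mean(x$valid_mask), x$n_degenerate))
  invisible(x)
}
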