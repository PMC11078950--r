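# Small numerical helpers shared across modules.

# Reflect (symmetric, half-sample) 1-based indices into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(i < n, i + 1L, period - i)
}

# Dense 1-D Gaussian convolution operator with reflective (symmetric)
# boundary; rows sum to 1 and, by kernel symmetry, mass is conserved.
gaussian_conv_matrix <- function(n, sigma) {
  radius <- max(1L, ceiling(6 * sigma))   # <1e-9 of the mass truncated
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  cm <- matrix(0, n, n)
  for (o in seq_along(k)) {
    src <- reflect_index(seq_len(n) + (o - radius - 1L), n)
    cm[cbind(seq_len(n), src)] <- cm[cbind(seq_len(n), src)] + k[o]
  }
  cm
}

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution with reflective (symmetric) boundary
#' handling, which conserves total intensity. `sigma = 0` returns the input
#' unchanged.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be a nonnegative number", call. = FALSE)
  if (sigma == 0) return(image)
  cy <- gaussian_conv_matrix(nrow(image), sigma)
  cx <- gaussian_conv_matrix(ncol(image), sigma)
  cy %*% image %*% t(cx)
}

# Bilinear interpolation of `image` (pixel (r,c) centred at
# ((r-0.5)*pitch, (c-0.5)*pitch)) at object-space points (x um along
# columns, y um along rows). Points outside the grid are clamped to the
# border pixel centres.
bilinear_interp <- function(image, x, y, pitch) {
  h <- nrow(image); w <- ncol(image)
  fr <- pmin(pmax(y / pitch + 0.5, 1), h)
  fc <- pmin(pmax(x / pitch + 0.5, 1), w)
  r0 <- pmin(floor(fr), h - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(fc), w - 1L); c0 <- pmax(c0, 1L)
  dr <- fr - r0; dc <- fc - c0
  image[cbind(r0, c0)] * (1 - dr) * (1 - dc) +
    image[cbind(r0 + 1L, c0)] * dr * (1 - dc) +
    image[cbind(r0, c0 + 1L)] * (1 - dr) * dc +
    image[cbind(r0 + 1L, c0 + 1L)] * dr * dc
}

# Nearest-neighbour (block replication) upsampling by an integer factor.
# Preserves region means over blocks aligned to the coarse grid.
upsample_nearest <- function(image, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(image)
  image[rep(seq_len(nrow(image)), each = factor),
        rep(seq_len(ncol(image)), each = factor), drop = FALSE]
}
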