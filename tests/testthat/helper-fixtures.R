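# Shared fixtures and small oracles, built in code at test time.

default_optics <- function(...) {
  optics_config(wavelength_em = 0.460, numerical_aperture = 0.80,
                magnification = 20, pixel_pitch = 6.45, ...)
}

# Stack with a single static emitter of fluctuating brightness at a known
# continuous position (um), on a field_px x field_px grid.
single_emitter_stack <- function(position, brightness = 30, K = 200,
                                 field_px = 13, seed = 1,
                                 optics = default_optics(),
                                 camera = camera_model(gain = 1,
                                                       read_noise_sd = 2,
                                                       offset = 100)) {
  pitch <- object_pixel_pitch(optics)
  ph <- generate_fibrils(field_size = field_px * pitch, n_fibrils = 0,
                         seed = seed)
  ph$emitters <- data.frame(x = position[1], y = position[2],
                            brightness = brightness)
  fl <- fluctuation_model(p_on = 0.5, on_off_correlation = 0)
  b <- simulate_fluctuations(ph$emitters, fl, K = K, seed = seed + 1)
  render_stack(ph, b, optics, camera, seed = seed + 2)
}

# Brute-force window gather: naive double loop over pixels, row-major order.
gather_window_naive <- function(frames, center, N) {
  h <- (N - 1) / 2
  K <- dim(frames)[3]
  out <- matrix(0, N * N, K)
  for (k in seq_len(K)) {
    i <- 0
    for (a in (center[1] - h):(center[1] + h)) {
      for (b in (center[2] - h):(center[2] + h)) {
        i <- i + 1
        out[i, k] <- frames[a, b, k]
      }
    }
  }
  out
}

# Independent subspace oracle: eigen-decomposition of the Gram matrix
# M M^T, naive projections of a unit vector onto signal/noise eigenvectors.
gram_subspace_oracle <- function(m, g, r) {
  ev <- eigen(m %*% t(m), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  k <- min(dim(m))
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  proj <- as.numeric(t(u) %*% g)
  list(singular_values = sqrt(vals[seq_len(k)]),
       signal = sqrt(sum(proj[seq_len(r)]^2)),
       noise = sqrt(sum(proj[(r + 1):k]^2)))
}

# Brute-force knee: drop trailing numerical zeros, then evaluate the
# perpendicular distance of every log10 point to the endpoint chord from
# the explicit point-to-line formula; first index within round-off of the
# maximum wins.
knee_oracle <- function(sv) {
  n <- max(which(sv > 1e-12 * max(sv)))
  y <- log10(sv[seq_len(n)])
  x1 <- 1; y1 <- y[1]; x2 <- n; y2 <- y[n]
  d <- vapply(seq_len(n), function(i) {
    abs((y2 - y1) * i - (x2 - x1) * y[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }, numeric(1))
  which(d >= max(d) * (1 - 1e-12))[1]
}

# Count prominent local maxima of a 1-D profile after baseline subtraction:
# strict local maxima whose height exceeds `frac` of the profile range.
count_peaks <- function(v, frac = 0.25) {
  v <- v[is.finite(v)]
  rng <- max(v) - min(v)
  if (rng <= 0) return(0L)
  rel <- (v - min(v)) / rng
  idx <- which(diff(sign(diff(rel))) == -2) + 1L
  sum(rel[idx] >= frac)
}
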