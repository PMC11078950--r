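test_that("extract_window matches a naive double-loop gather", {
  set.seed(42)
  frames <- array(runif(5 * 5 * 4), dim = c(5, 5, 4))
  st <- image_stack(frames, pixel_pitch_object = 0.3)
  got <- extract_window(st, c(3, 3), 3)
  expect_equal(got, gather_window_naive(frames, c(3, 3), 3))
  # round trip: devectorizing column j reproduces the crop (row-major)
  crop2 <- matrix(got[, 2], 3, 3, byrow = TRUE)
  expect_identical(crop2, frames[2:4, 2:4, 2])
  # constant stack gives a constant matrix
  stc <- image_stack(array(7, dim = c(5, 5, 3)), pixel_pitch_object = 0.3)
  expect_true(all(extract_window(stc, c(3, 3), 3) == 7))
  expect_error(extract_window(st, c(1, 3), 3), "border")
})

test_that("decompose_window agrees with an independent Gram-matrix oracle", {
  set.seed(7)
  m <- matrix(rexp(9 * 4), 9, 4)
  basis <- decompose_window(m)
  oracle <- gram_subspace_oracle(m, rep(1 / 3, 9), r = 2)
  expect_equal(basis$singular_values, oracle$singular_values,
               tolerance = 1e-10)
  # eigenimages orthonormal
  gram <- crossprod(basis$eigenimages)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # SVD homogeneity: scaling the data scales singular values only
  b2 <- decompose_window(3 * m)
  expect_equal(b2$singular_values, 3 * basis$singular_values,
               tolerance = 1e-10)
  expect_equal(abs(crossprod(b2$eigenimages, basis$eigenimages)),
               diag(ncol(basis$eigenimages)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-1 stacks have a single nonzero singular value", {
  base <- runif(9)
  m <- outer(base, c(1, 2, 0.5, 3))
  sv <- decompose_window(m)$singular_values
  expect_gt(sv[1], 0)
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("knee_threshold finds the max-distance index of the log spectrum", {
  sv <- c(100, 90, 80, 1, 0.9, 0.8)
  expect_identical(knee_threshold(sv), knee_oracle(sv))
  expect_identical(knee_threshold(sv), 3L)
  # random spectra agree with the oracle
  set.seed(11)
  for (i in 1:25) {
    s <- sort(rexp(sample(5:40, 1), rate = 0.2), decreasing = TRUE)
    expect_identical(knee_threshold(s), as.integer(knee_oracle(s)))
  }
  # appending values below the clamping floor does not move the knee
  padded <- c(sv, 1e-15 * max(sv), 1e-18 * max(sv))
  expect_identical(knee_threshold(padded), as.integer(knee_oracle(padded)))
  expect_identical(knee_threshold(padded), 3L)
})

test_that("flat and log-linear spectra degrade to rank 1 with a warning", {
  expect_warning(r <- knee_threshold(rep(5, 6)), "degenerate")
  expect_identical(r, 1L)
  expect_warning(r2 <- knee_threshold(10^-(0:6)), "degenerate")
  expect_identical(r2, 1L)
})

test_that("psf steering vectors are unit-norm, symmetric and quadrature-accurate", {
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  # unit norm anywhere in the window
  set.seed(3)
  for (i in 1:10) {
    p <- runif(2, -1.4, 1.4) * pitch
    expect_equal(sum(psf_vector(opt, p, 7, pitch)^2), 1, tolerance = 1e-12)
  }
  # centre point: symmetric under window reflection
  g <- psf_vector(opt, c(0, 0), 5, pitch)
  m <- matrix(g, 5, 5, byrow = TRUE)
  expect_lt(max(abs(m - m[5:1, ])), 1e-9)
  expect_lt(max(abs(m - t(m))), 1e-9)
  # analytic Gaussian pixel integration vs 64x midpoint quadrature
  p <- c(0.3, -0.2) * pitch
  analytic <- psf_vector(opt, p, 5, pitch)
  q <- 64
  sub <- ((seq_len(q) - 0.5) / q - 0.5) * pitch
  s <- musicalr:::psf_sigma(opt)
  offs <- (-2:2) * pitch
  quad <- matrix(0, 5, 5)
  for (a in 1:5) for (b in 1:5) {
    px <- offs[b] + sub - p[1]; py <- offs[a] + sub - p[2]
    quad[a, b] <- mean(exp(-outer(py^2, px^2, `+`) / (2 * s^2))) * pitch^2
  }
  qv <- as.vector(t(quad)); qv <- qv / sqrt(sum(qv^2))
  expect_lt(max(abs(analytic - qv)), 1e-4)
  expect_error(psf_vector(opt, c(10, 0) * pitch, 5, pitch), "outside")
})

test_that("indicator projects onto signal and noise subspaces as specified", {
  set.seed(5)
  m <- matrix(rnorm(9 * 20), 9, 20)
  basis <- set_signal_rank(decompose_window(m), 3)
  # a vector inside the noise subspace scores zero
  noise_vec <- basis$eigenimages[, 5]
  expect_equal(indicator(basis, noise_vec, alpha = 4), 0)
  # alpha = 0 collapses the score to one
  g <- rep(1 / 3, 9)
  expect_equal(indicator(basis, g, alpha = 0), 1)
  # agreement with the Gram oracle
  o <- gram_subspace_oracle(m, g, 3)
  expect_equal(indicator(basis, g, alpha = 4), (o$signal / o$noise)^4,
               tolerance = 1e-10)
  # degenerate ranks are rejected
  expect_error(indicator(set_signal_rank(basis, 0), g), "signal")
  expect_error(indicator(set_signal_rank(basis, 9), g), "noise")
})

test_that("indicator contrast between two points is nondecreasing in alpha", {
  set.seed(6)
  m <- matrix(rnorm(25 * 30), 25, 30)
  basis <- set_signal_rank(decompose_window(m), 4)
  g1 <- basis$eigenimages[, 1] * 0.9 + basis$eigenimages[, 6] * sqrt(1 - 0.81)
  g2 <- basis$eigenimages[, 2] * 0.7 + basis$eigenimages[, 7] * sqrt(1 - 0.49)
  alphas <- c(0.5, 1, 2, 4, 8)
  ratio <- vapply(alphas, function(a)
    indicator(basis, g1, a) / indicator(basis, g2, a), numeric(1))
  expect_true(all(diff(ratio) >= 0))
})

test_that("full reconstruction matches brute-force window computations", {
  set.seed(8)
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  frames <- array(rexp(9 * 9 * 20, rate = 0.05), dim = c(9, 9, 20))
  st <- image_stack(frames, pixel_pitch_object = pitch)
  params <- musical_params(window_size = 5, subpixels = 2, stitch = "center")
  expect_warning(map <- reconstruct(st, params, opt), "K < N")
  # oracle: per-window Gram decomposition and naive projections
  g <- musicalr:::steering_matrix(opt, 5, pitch, 2, footprint = "center")
  for (rc in c(3, 5, 7)) {
    for (cc in c(3, 6)) {
      m <- gather_window_naive(frames, c(rc, cc), 5)
      sv <- svd(m)$d
      r <- knee_threshold(sv)
      for (j in 1:4) {
        o <- gram_subspace_oracle(m, g[, j], r)
        expected <- (o$signal / max(o$noise, 1e-12))^4
        u <- ((j - 1) %/% 2) + 1; v <- ((j - 1) %% 2) + 1
        got <- map$values[(rc - 1) * 2 + u, (cc - 1) * 2 + v]
        expect_equal(got, expected, tolerance = 1e-8)
      }
    }
  }
})

test_that("map geometry: shape contract, masked border, degenerate handling", {
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  set.seed(9)
  frames <- array(rexp(8 * 10 * 30), dim = c(8, 10, 30))
  st <- image_stack(frames, pixel_pitch_object = pitch)
  for (stitch in c("center", "average")) {
    map <- suppressWarnings(reconstruct(
      st, musical_params(window_size = 5, subpixels = 3, stitch = stitch), opt))
    expect_identical(dim(map$values), c(3L * 8L, 3L * 10L))
    expect_true(all(is.na(map$values[1:6, ])))    # 2-pixel border
    expect_true(all(is.na(map$values[, 1:6])))
    expect_true(all(map$values[map$valid_mask] >= 0))
  }
  # constant noiseless stack: every window is rank-1, all masked (also
  # warns that K < N^2 for this short stack)
  stc <- image_stack(array(5, dim = c(8, 8, 12)), pixel_pitch_object = pitch)
  w <- capture_warnings(
    mc <- reconstruct(stc, musical_params(window_size = 5, subpixels = 2), opt))
  expect_match(w, "degenerate", all = FALSE)
  expect_true(all(is.na(mc$values)))
  expect_identical(mc$n_degenerate, 16L)
})

test_that("reconstruction is exactly invariant to positive rescaling", {
  set.seed(10)
  sim <- simulate_fibril_stack(31, field_pixels = 16, n_fibrils = 3,
                               frames = 60, background_ratio = 1)
  params <- musical_params(window_size = 5, subpixels = 4)
  base <- suppressWarnings(reconstruct(sim$stack, params, sim$optics))
  for (c_scale in c(0.1, 10)) {
    scaled <- sim$stack
    scaled$frames <- scaled$frames * c_scale
    m2 <- suppressWarnings(reconstruct(scaled, params, sim$optics))
    expect_equal(m2$values, base$values, tolerance = 1e-10)
  }
})

test_that("single-emitter argmax lands within one sub-pixel of the truth", {
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  true_pos <- c(6.5 * pitch + 0.13, 6.5 * pitch - 0.07)
  st <- single_emitter_stack(true_pos, brightness = 30, K = 200, seed = 21)
  map <- reconstruct(st, musical_params(window_size = 7), opt)
  idx <- which(map$values == max(map$values, na.rm = TRUE), arr.ind = TRUE)
  est <- c((idx[1, 2] - 0.5), (idx[1, 1] - 0.5)) * map$pixel_pitch
  expect_lt(sqrt(sum((est - true_pos)^2)) / map$pixel_pitch, 1)
})

test_that("background without structure is strongly suppressed", {
  # left half pure noise, right half fibrils: mean indicator left < 5% right
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  npx <- 24
  ph <- generate_fibrils(field_size = npx * pitch, n_fibrils = 5,
                         dense_fraction = 1, seed = 13)   # all fibrils right
  ph <- place_emitters(ph, 5, jitter_sd = 0.03, mean_brightness = 80,
                       seed = 14)
  b <- simulate_fluctuations(ph$emitters, fluctuation_model(), 200, seed = 15)
  st <- render_stack(ph, b, opt, camera_model(), seed = 16, background = 5)
  map <- suppressWarnings(reconstruct(st, musical_params(window_size = 5),
                                      opt))
  s <- map$params$subpixels
  left <- map$values[, seq_len(npx * s / 2)]
  right <- map$values[, (npx * s / 2 + 1):(npx * s)]
  expect_lt(mean(left, na.rm = TRUE), 0.05 * mean(right, na.rm = TRUE))
})
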