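test_that("ROI mean density equals the naive double-loop mean", {
  set.seed(21)
  img <- matrix(runif(40 * 40), 40, 40)
  roi <- roi_spec(c(5, 8), c(10, 12))
  naive <- 0
  for (r in 5:14) for (cc in 8:19) naive <- naive + img[r, cc]
  expect_equal(roi_mean_density(img, roi), naive / 120)
  expect_equal(roi_mean_density(matrix(3, 10, 10), roi_spec(c(1, 1), c(4, 4))), 3)
  checker <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  expect_equal(roi_mean_density(checker, roi_spec(c(1, 1), c(4, 4))), 0.5)
  expect_error(roi_mean_density(img, roi_spec(c(38, 1), c(10, 4))), "outside")
  masked <- img; masked[1:30, ] <- NA
  expect_error(roi_mean_density(masked, roi_spec(c(21, 1), c(12, 5))),
               "valid")
})

test_that("camera-grid ROIs scale onto indicator maps by the sub-pixelation", {
  sim <- simulate_fibril_stack(41, field_pixels = 14, n_fibrils = 2,
                               frames = 60, background_ratio = 1,
                               subpixels = 4)
  map <- suppressWarnings(reconstruct(
    sim$stack, musical_params(window_size = 5, subpixels = 4), sim$optics))
  cam_roi <- roi_spec(c(4, 4), c(6, 6), frame_of_reference = "camera_grid")
  sub_roi <- roi_spec(c(13, 13), c(24, 24))
  expect_equal(roi_mean_density(map, cam_roi), roi_mean_density(map, sub_roi))
})

test_that("layer ratios are scale-free relative densities", {
  set.seed(22)
  img <- matrix(runif(30 * 30, 1, 2), 30, 30)
  upper <- layer_mask("E", row(img) <= 15)
  lower <- layer_mask("SE", row(img) > 15)
  expect_equal(layer_ratio(img, upper, upper), 1)
  two_tone <- img
  two_tone[upper$mask] <- 0.5
  two_tone[lower$mask] <- 1.0
  expect_equal(layer_ratio(two_tone, lower, upper), 2)
  # invariance to positive rescaling
  r1 <- layer_ratio(img, lower, upper)
  expect_equal(layer_ratio(7.3 * img, lower, upper), r1)
  expect_error(layer_ratio(img * 0, lower, upper), "degenerate")
})

test_that("two-layer phantom recovers the programmed density ratio", {
  # upper layer carries twice the fibril coverage of the lower layer
  # (4 vs 2 fibrils of equal length); the reconstructed-map layer ratio
  # should centre near 2. Single-image ratios carry the indicator's
  # peak-height variance, so the claim is made on the geometric mean over
  # seeds, as ratios are averaged over many measurements in practice.
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  npx <- 40
  fs <- npx * pitch
  ratios <- vapply(1:10, function(i) {
    seed <- 500 + i * 31
    ph <- generate_fibrils(c(fs, fs), 0, seed = seed)
    xs <- seq(0.4, fs - 0.4, length.out = 50)
    ph$centerlines <- lapply(fs * c(0.10, 0.22, 0.34, 0.46, 0.64, 0.86),
                             function(y) cbind(x = xs, y = rep(y, 50)))
    ph <- place_emitters(ph, 2, jitter_sd = 0.03, mean_brightness = 120,
                         seed = seed + 1)
    b <- simulate_fluctuations(ph$emitters, fluctuation_model(), 250,
                               seed = seed + 2)
    st <- render_stack(ph, b, opt, camera_model(), seed = seed + 3,
                       background = 5)
    map <- suppressWarnings(reconstruct(st, musical_params(subpixels = 5),
                                        opt))
    half <- nrow(map$values) / 2
    layer_ratio(map, layer_mask("upper", row(map$values) <= half),
                layer_mask("lower", row(map$values) > half))
  }, numeric(1))
  gm <- exp(mean(log(ratios)))
  expect_gte(gm, 1.5)
  expect_lte(gm, 2.5)
  expect_gte(mean(ratios > 1), 0.7)
})

test_that("multiscale variance ladder behaves on constant and noise images", {
  const <- matrix(4, 120, 120)
  rep_const <- multiscale_variance(const, c(20, 10, 5), pixel_size = 1)
  for (p in rep_const$per_size) {
    expect_true(all(p$within_var == 0))
    expect_equal(p$between_var, 0)
  }
  # i.i.d. noise: variance of window means shrinks as window area grows
  set.seed(23)
  decreasing <- replicate(20, {
    noise <- matrix(rnorm(120 * 120), 120, 120)
    rep_n <- multiscale_variance(noise, c(40, 20, 10, 5), pixel_size = 1)
    b <- vapply(rep_n$per_size, `[[`, numeric(1), "between_var")
    all(diff(b) > 0)   # sizes are decreasing, so between-var increases
  })
  expect_gte(mean(decreasing), 0.9)
  # within-window variance equals the naive two-pass computation
  set.seed(24)
  img <- matrix(runif(30 * 30), 30, 30)
  rep1 <- multiscale_variance(img, c(10), pixel_size = 1)
  w <- img[1:10, 1:10]
  expect_equal(rep1$per_size[[1]]$within_var[1],
               sum((w - mean(w))^2) / (length(w) - 1))
  expect_error(multiscale_variance(img, c(50), pixel_size = 1), "exceeds")
  expect_error(multiscale_variance(img, c(10, 10), pixel_size = 1),
               "decreasing")
})

test_that("fibrosis series ordering: variance falls as heterogeneity is lost", {
  # programmed decreasing density heterogeneity across five stages (the
  # dense/sparse split relaxing towards uniform); the between-window
  # variance at the three coarsest scales, averaged over replicate fields
  # per stage as group measurements are in practice, must be monotone
  # across the series
  pitch <- 0.645
  stage_variance <- function(dense_fraction, seed) {
    ph <- generate_fibrils(c(280, 280), 160, waviness = 0.4,
                           dense_fraction = dense_fraction, seed = seed,
                           raster_pitch = pitch)
    ph <- place_emitters(ph, 3, jitter_sd = 0.1, seed = seed + 1)
    img <- blur_density(ph$density_raster, 2.5, pixel_size = pitch)
    img <- img / mean(img)   # images are normalized between acquisitions
    rep <- multiscale_variance(img, c(90, 45, 25), pixel_size = pitch)
    vapply(rep$per_size, function(p) p$between_var, numeric(1))
  }
  fractions <- c(0.95, 0.85, 0.75, 0.65, 0.55)
  vs <- vapply(seq_along(fractions), function(i) {
    reps <- vapply(0:2, function(r)
      stage_variance(fractions[i], 700 + i * 13 + r * 1000), numeric(3))
    rowMeans(reps)
  }, numeric(3))
  for (scale_i in 1:3) expect_true(all(diff(vs[scale_i, ]) < 0))
})

test_that("FWHM recovers known ridge widths from line profiles", {
  # Gaussian ridge of sigma um: FWHM = 2.3548 sigma within 2%
  px <- 0.05
  xs <- (seq_len(200) - 0.5) * px
  for (sg in c(0.2, 0.5)) {
    img <- matrix(rep(exp(-(xs - 5)^2 / (2 * sg^2)), each = 100), 100, 200)
    got <- fibril_width(img, line = c(2, 2.5, 8, 2.5), n_samples = 256,
                        pixel_size = px)
    expect_equal(got, 2.3548 * sg, tolerance = 0.02)
  }
  # rectangular ridge converges to its width with dense sampling
  rect <- matrix(rep(as.numeric(abs(xs - 5) < 0.4), each = 100), 100, 200)
  got <- fibril_width(rect, c(2, 2.5, 8, 2.5), n_samples = 4096,
                      pixel_size = px)
  expect_equal(got, 0.8, tolerance = 0.05)
  flat <- matrix(1, 50, 50)
  expect_error(fibril_width(flat, c(0.2, 1, 2, 1), pixel_size = px),
               "ridge")
})

test_that("reconstructed fibrils are narrower than their mean-frame image", {
  opt <- default_optics()
  pitch <- object_pixel_pitch(opt)
  npx <- 16
  ph <- generate_fibrils(c(npx, npx) * pitch, 0, seed = 33)
  # one straight horizontal fibril across the field centre
  mid <- npx * pitch / 2 + 0.13
  xs <- seq(0.3, npx * pitch - 0.3, length.out = 60)
  ph$centerlines <- list(cbind(x = xs, y = rep(mid, 60)))
  ph <- place_emitters(ph, 12, jitter_sd = 0.02, mean_brightness = 60,
                       seed = 34)
  b <- simulate_fluctuations(ph$emitters, fluctuation_model(), 300,
                             seed = 35)
  st <- render_stack(ph, b, opt, camera_model(), seed = 36, background = 3)
  map <- suppressWarnings(reconstruct(st, musical_params(), opt))
  line <- c(npx * pitch / 2, mid - 0.8, npx * pitch / 2, mid + 0.8)
  w_map <- fibril_width(map, line)
  w_dl <- fibril_width(mean_frame(st) - 100, line, pixel_size = pitch)
  expect_lt(w_map, w_dl)
})

test_that("ssim matches its definition and a reference implementation", {
  set.seed(99)
  a <- matrix(runif(48 * 40), 48, 40)
  set.seed(100)
  b <- 0.6 * a + 0.4 * matrix(runif(48 * 40), 48, 40)
  # frozen reference: scikit-image structural_similarity with Gaussian
  # weights (sigma 1.5), no sample-covariance correction, data_range =
  # joint dynamic range, on this exact seed-reproducible fixture
  expect_equal(ssim(a, b), 0.7792644697934863, tolerance = 1e-6)
  expect_equal(ssim(a, a), 1)
  # anti-correlated images with (near-)zero local means score non-positive:
  # a checkerboard has vanishing Gaussian-weighted means, so the sign is
  # carried by the covariance term
  z <- outer(1:40, 1:40, function(i, j) (-1)^(i + j))
  expect_lte(ssim(z, -z, dynamic_range = 2), 0)
  expect_error(ssim(a, t(a)), "shape")
})

test_that("density fidelity report behaves on exact and degraded candidates", {
  set.seed(25)
  gt <- gaussian_blur(matrix(rexp(80 * 80), 80, 80), 1.5)
  rois <- list()
  labs <- character(0)
  for (r in seq(1, 71, by = 10)) for (cc in seq(1, 71, by = 10)) {
    rois[[length(rois) + 1]] <- roi_spec(c(r, cc), c(8, 8))
    labs <- c(labs, if (cc <= 40) "sparse" else "dense")
  }
  # ground truth against itself: perfect correlation, zero error
  rep0 <- density_fidelity(gt, list(self = gt), rois, labs)
  expect_true(all(abs(rep0$correlation - 1) < 1e-12))
  expect_true(all(rep0$mae < 1e-12))
  # light blur stays closer to truth than heavy blur, per region
  light <- gaussian_blur(gt, 1)
  heavy <- gaussian_blur(gt, 10)
  rep1 <- density_fidelity(gt, list(light = light, heavy = heavy), rois, labs)
  for (reg in c("dense", "sparse")) {
    sub <- rep1[rep1$region == reg, ]
    expect_gt(sub$correlation[sub$candidate == "light"],
              sub$correlation[sub$candidate == "heavy"])
  }
  # shuffling ROI labels destroys the correlation
  set.seed(26)
  shuffled <- sample(seq_along(rois))
  gt_means <- vapply(rois, function(r) roi_mean_density(gt, r), numeric(1))
  r_shuf <- stats::cor(gt_means, gt_means[shuffled])
  expect_lt(abs(r_shuf), 0.3)
  expect_error(density_fidelity(gt, list(x = gt), rois[1:4],
                                c("dense", "dense", "dense", "sparse")),
               "at least 3")
})

test_that("group comparison wraps the standard tests", {
  set.seed(27)
  vals <- c(rnorm(20, 1), rnorm(20, 1.5), rnorm(20, 3))
  grp <- rep(c("NOM", "OSF", "OSCC"), each = 20)
  res <- compare_groups(vals, grp)
  expect_s3_class(res$anova, "aov")
  expect_s3_class(res$tukey, "TukeyHSD")
  two <- compare_groups(vals[c(1:20, 41:60)], grp[c(1:20, 41:60)])
  expect_s3_class(two, "htest")
  expect_lt(two$p.value, 0.001)
})
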