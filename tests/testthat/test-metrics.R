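# SNR, relative error, SSIM, FSIM (phase congruency, gradient magnitude)

test_that("snr follows its norm-ratio definition", {
  u <- make_phantom("piecewise", 32, 1)
  # reconstruction equal to the reference mean scores 0 dB
  expect_equal(snr(u, matrix(mean(u), 32, 32)), 0, tolerance = 1e-12)
  expect_identical(snr(u, u), Inf)
  # halving the error norm adds 10*log10(2) dB
  e <- random_image(32, seed = 2) - 0.5
  expect_equal(snr(u, u + e / 2) - snr(u, u + e), 10 * log10(2),
               tolerance = 1e-10)
  expect_error(snr(matrix(1, 8, 8), matrix(0, 8, 8)), "constant")
})

test_that("relative error follows its definition", {
  u <- make_phantom("piecewise", 32, 1)
  expect_equal(relative_error(u, u), 0)
  expect_equal(relative_error(u, matrix(0, 32, 32)), 100, tolerance = 1e-12)
  expect_equal(relative_error(u, 1.1 * u), 10, tolerance = 1e-10)
  # SNR/RE consistency: halving RE adds 10*log10(2) dB
  e <- random_image(32, seed = 3) - 0.5
  re_ratio <- relative_error(u, u + e) / relative_error(u, u + e / 2)
  expect_equal(10 * log10(re_ratio),
               snr(u, u + e / 2) - snr(u, u + e), tolerance = 1e-10)
})

test_that("ssim is 1 at identity, symmetric, and matches the constant-image form", {
  x <- 255 * make_phantom("textured", 64, 1)
  y <- 255 * make_phantom("piecewise", 64, 2)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_lte(ssim(x, y), 1)
  # constant images: sigma terms vanish, closed form remains
  p <- ssim_params()
  a <- 120; b <- 90
  C1 <- (p$K1 * p$L)^2
  expect_equal(ssim(matrix(a, 16, 16), matrix(b, 16, 16), p),
               (2 * a * b + C1) / (a^2 + b^2 + C1), tolerance = 1e-12)
  expect_error(ssim(matrix(1, 8, 8), matrix(1, 8, 8)), "window")
})

test_that("gradient magnitude matches direct stencil arithmetic", {
  expect_true(all(gradient_magnitude(matrix(3, 16, 16)) == 0))
  # linear ramp: constant gradient in the interior
  ramp <- matrix(seq_len(16), 16, 16)
  gm <- gradient_magnitude(ramp, "sobel")
  expect_lt(max(abs(gm[2:15, 2:15] - gm[8, 8])), 1e-12)
  expect_gt(gm[8, 8], 0)
  # 5x5 hand check, scharr at the centre pixel
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, byrow = TRUE) / 16
  gm2 <- gradient_magnitude(img, "scharr")
  # centre of a delta image: both directional responses are zero there
  expect_equal(gm2[3, 3], 0, tolerance = 1e-12)
  # at (2,3): convolution of the delta reproduces the flipped stencil entry
  expect_equal(gm2[2, 3], sqrt((10 / 16)^2), tolerance = 1e-12)
  expect_equal(gm2[2, 2], sqrt((3 / 16)^2 + (3 / 16)^2), tolerance = 1e-12)
  expect_error(gradient_magnitude(matrix(1, 8, 8), "roberts"), "arg")
})

test_that("phase congruency is zero on constants, scale-invariant, edge-peaked", {
  const <- matrix(0.5, 48, 48)
  expect_lt(max(phase_congruency(const)), 1e-10)
  # dimensionless: exact invariance under positive affine rescaling
  img <- 255 * make_phantom("shepp_logan", 64)
  pc1 <- phase_congruency(img)
  pc2 <- phase_congruency(3.7 * img + 41)
  expect_equal(pc1, pc2, tolerance = 1e-8)
  expect_true(all(pc1 >= 0 & pc1 <= 1))
  # a vertical step edge peaks on the edge line
  # vertical step edge; under the FFT's circular topology the wrap-around
  # boundary is an edge too, so the check looks at the interior columns
  step <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  pc <- phase_congruency(step)
  interior <- 8:56
  peak_col <- interior[which.max(colMeans(pc)[interior])]
  expect_true(peak_col %in% c(32, 33))
  expect_error(phase_congruency(matrix(1, 16, 16)), "small")
})

test_that("fsim is 1 at identity, symmetric, and pools correctly", {
  x <- 255 * make_phantom("textured", 64, 1)
  y <- 255 * make_phantom("shepp_logan", 64)
  expect_equal(fsim(x, x), 1, tolerance = 1e-12)
  expect_equal(fsim(x, y), fsim(y, x), tolerance = 1e-12)
  expect_lte(fsim(x, y), 1)
  # pooling: a constant similarity map pools to that constant regardless of
  # the phase-congruency weights
  pcm <- phase_congruency(x)
  expect_equal(nltvrecon:::fsim_pool(matrix(0.42, 64, 64), pcm), 0.42,
               tolerance = 1e-12)
})

test_that("evaluate_pair reports all four metrics on the unit scale", {
  u <- make_phantom("textured", 64, 1)
  rec <- u + 0.01 * (random_image(64, seed = 4) - 0.5)
  rep <- evaluate_pair(u, rec)
  expect_named(rep, c("snr_db", "re_pct", "ssim", "fsim"))
  expect_gt(rep$snr_db, 10)
  expect_lt(rep$re_pct, 5)
  expect_gt(rep$ssim, 0.9)
  expect_gt(rep$fsim, 0.9)
})
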