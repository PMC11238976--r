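test_that("SSIM of an image with itself is exactly 1", {
  img <- to_eight_bit(small_phantom(seed = 4))
  expect_equal(ssim(img, img), 1)
  expect_equal(ssim(img, img, ssim_params(gaussian_weighted = TRUE)), 1)
})

test_that("SSIM of two constant images matches the closed form", {
  a <- const_img(100, 32, 32)
  b <- const_img(110, 32, 32)
  C1 <- (0.01 * 255)^2
  expected <- (2 * 100 * 110 + C1) / (100^2 + 110^2 + C1)
  expect_equal(ssim(a, b), expected, tolerance = 1e-12)
})

test_that("SSIM is symmetric and decreases with noise strength", {
  ph <- small_phantom(seed = 4, size = 256)
  ref8 <- to_eight_bit(ph)
  weak <- to_eight_bit(simulate_dose_noise(ph, dose_noise_spec(89.1, 89.1, 4, seed = 1)))
  strong <- to_eight_bit(simulate_dose_noise(ph, dose_noise_spec(89.1, 89.1, 25, seed = 2)))
  expect_equal(ssim(ref8, weak), ssim(weak, ref8), tolerance = 1e-12)
  expect_lt(ssim(ref8, strong), ssim(ref8, weak))
  expect_error(ssim(ref8, const_img(1, 10, 10)), "dimensions")
})

test_that("PSNR closed forms hold", {
  a <- random_img(40, 40, seed = 6)
  expect_identical(psnr(a, a), Inf)
  b <- img8(pmin(a$pixels + 1, 255))
  # ensure exactly +1 everywhere (avoid the clip)
  a2 <- img8(pmin(a$pixels, 254))
  b2 <- img8(a2$pixels + 1)
  expect_equal(psnr(a2, b2), 20 * log10(255), tolerance = 1e-12)
  expect_equal(psnr(a2, b2), psnr(b2, a2))
  expect_error(psnr(a, const_img(0, 3, 3)), "dimensions")
})

test_that("halving the noise sigma raises PSNR by about 6 dB", {
  flat <- const_img(30000, 256, 256, bits = 16L)
  n1 <- simulate_dose_noise(flat, dose_noise_spec(89.1, 89.1, 20, seed = 3))
  n2 <- simulate_dose_noise(flat, dose_noise_spec(89.1, 89.1, 10, seed = 4))
  gain <- psnr(flat, n2) - psnr(flat, n1)
  expect_equal(gain, 20 * log10(2), tolerance = 0.2)
})

test_that("SSIM and PSNR both fall monotonically along a noise series", {
  ph <- small_phantom(seed = 8, size = 256)
  ref8 <- to_eight_bit(ph)
  sig <- c(3, 10, 25)
  vals <- sapply(seq_along(sig), function(i) {
    t8 <- to_eight_bit(simulate_dose_noise(ph, dose_noise_spec(89.1, 89.1, sig[i], seed = i)))
    c(ssim(ref8, t8), psnr(ref8, t8))
  })
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("ssim parameter validation rejects malformed windows", {
  expect_error(ssim_params(window = 4), "odd")
  expect_error(ssim_params(window = 1), "odd")
  expect_error(ssim_params(K1 = 0), "K1")
})
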