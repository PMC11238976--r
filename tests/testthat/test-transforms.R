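test_that("the kernel-size sigma rule reproduces its closed forms", {
  expect_equal(blur_sigma(3), 0.95)
  expect_equal(blur_sigma(5), 1.25)
  expect_equal(blur_sigma(21), 3.65)
  # the library compatibility convention differs
  expect_equal(blur_sigma(3, "opencv"), 0.8)
  expect_error(blur_sigma(4), "odd")
  expect_error(blur_sigma(1), "odd")
})

test_that("gaussian blur preserves constants and matches an impulse oracle", {
  cimg <- const_img(93, 48, 48)
  expect_identical(gaussian_blur(cimg, 7)$pixels, cimg$pixels)

  m <- matrix(0, 21, 21)
  m[11, 11] <- 255
  out <- gaussian_blur(img8(m), 3)
  g <- exp(-((-1:1)^2) / (2 * 0.95^2))
  g <- g / sum(g)
  k2d <- outer(g, g)
  expect_identical(out$pixels[11, 11], floor(255 * k2d[2, 2] + 0.5))
  expect_identical(out$pixels[10, 11], floor(255 * k2d[1, 2] + 0.5))
})

test_that("larger kernels strictly reduce image variance", {
  ref8 <- to_eight_bit(small_phantom(seed = 6))
  v <- sapply(seq(3, 21, by = 2), function(k) var(as.vector(gaussian_blur(ref8, k)$pixels)))
  expect_true(all(diff(v) < 0))
})

test_that("blur conserves the mean of an interior region", {
  ref8 <- to_eight_bit(small_phantom(seed = 6))
  out <- gaussian_blur(ref8, 11)
  inner <- 30:160
  expect_lt(abs(mean(out$pixels[inner, inner]) - mean(ref8$pixels[inner, inner])), 0.5)
})

test_that("identity affine parameters return bit-identical images", {
  img <- to_eight_bit(small_phantom(seed = 7))
  expect_identical(apply_affine(img, affine_spec("translate", dx = 0, dy = 0))$pixels,
                   img$pixels)
  expect_identical(apply_affine(img, affine_spec("rotate", angle = 0))$pixels,
                   img$pixels)
  expect_identical(apply_affine(img, affine_spec("scale", factor = 1))$pixels,
                   img$pixels)
})

test_that("integer translation is a lossless shift of interior pixels", {
  img <- random_img(40, 40, seed = 9)
  out <- apply_affine(img, affine_spec("translate", dx = 4, dy = 0))
  expect_equal(out$pixels[, 5:40], img$pixels[, 1:36], ignore_attr = TRUE)
  expect_true(all(out$pixels[, 1:4] == 0))  # vacated strip takes the border fill
  out2 <- apply_affine(img, affine_spec("translate", dx = 0, dy = -3))
  expect_equal(out2$pixels[1:37, ], img$pixels[4:40, ], ignore_attr = TRUE)
})

test_that("a 90-degree rotation matches an index-permutation oracle", {
  set.seed(12)
  m <- matrix(sample(0:255, 25), 5, 5)
  out <- apply_affine(img8(m), affine_spec("rotate", angle = 90))
  # positive angles rotate displayed content clockwise about the centre:
  # output row i, column j comes from input row 6-j, column i
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) expected[i, j] <- m[6 - j, i]
  expect_identical(out$pixels, expected)
})

test_that("scaling keeps dimensions and fills exposed regions with border", {
  img <- const_img(200, 64, 64)
  out <- apply_affine(img, affine_spec("scale", factor = 0.5))
  expect_identical(dim(out), dim(img))
  expect_identical(out$pixels[1, 1], 0)    # exposed corner
  expect_identical(out$pixels[32, 32], 200)
  expect_error(affine_spec("scale", factor = 0), "factor")
})

test_that("the standard degradation series reproduce the study grids", {
  expect_identical(length(dose_series()), 10L)
  expect_equal(sapply(dose_series(), `[[`, "ctdi"),
               c(2.7, 5.5, 13.7, 21.9, 27.4, 35.6, 41.0, 53.4, 59.4, 74.2),
               ignore_attr = TRUE)
  bs <- blur_series()
  expect_identical(length(bs), 10L)
  expect_equal(sapply(bs, `[[`, "sigma"),
               0.3 * (seq(3, 21, 2) / 2 - 1) + 0.8, ignore_attr = TRUE)
  expect_identical(length(translation_series()), 11L)
  expect_identical(length(rotation_series()), 11L)
  expect_identical(length(reduction_series()), 5L)
  expect_identical(length(enlargement_series()), 5L)
})
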