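test_that("PNG round trip is bit-exact for 8-bit images", {
  p <- withr::local_tempfile(fileext = ".png")
  img <- const_img(7, 16, 20)
  write_image(img, p)
  back <- read_image(p)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$bit_depth, 8L)

  r <- random_img(32, 40, seed = 11)
  write_image(r, p)
  expect_identical(read_image(p)$pixels, r$pixels)
})

test_that("TIFF round trip is bit-exact for 16-bit images", {
  p <- withr::local_tempfile(fileext = ".tif")
  r <- random_img(24, 31, bits = 16L, seed = 7)
  write_image(r, p)
  back <- read_image(p)
  expect_identical(back$bit_depth, 16L)
  expect_equal(back$pixels, r$pixels, ignore_attr = TRUE)
})

test_that("color input and missing files are rejected", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12 * 10 * 3), dim = c(12, 10, 3)), p)
  expect_error(read_image(p), "color")
  expect_error(read_image(file.path(tempdir(), "no-such-file.png")), "exist")
  expect_error(write_image(random_img(8, 8, bits = 16L), "x.png"), "16-bit")
})

test_that("DICOM reading applies the rescale and carries metadata", {
  p <- withr::local_tempfile(fileext = ".dcm")
  px <- matrix(1024L, 12, 10)
  px[3, 4] <- 2024L
  write_minimal_dicom(p, px, slope = 1, intercept = -1024,
                      spacing = c(0.49, 0.49))
  img <- read_image(p)
  expect_identical(dim(img), c(12L, 10L))
  expect_identical(img$bit_depth, 16L)
  # stored 1024 with slope 1, intercept -1024 -> 0 HU
  hu <- as_hu(img)
  expect_identical(hu[1, 1], 0)
  expect_identical(hu[3, 4], 1000)
  expect_equal(img$spacing_mm, c(0.49, 0.49))
})

test_that("unsupported DICOM variants raise unsupported-format errors", {
  p <- withr::local_tempfile(fileext = ".dcm")
  px <- matrix(0L, 8, 8)
  write_minimal_dicom(p, px, photometric = "MONOCHROME1")
  expect_error(read_image(p), "photometric")
  write_minimal_dicom(p, px, frames = 3)
  expect_error(read_image(p), "multi-frame")
})

test_that("windowing maps the window linearly onto [0, 255]", {
  w <- window_spec(center = 40, width = 80)
  ct <- gray_image(matrix(c(40, 0, 80, -500, 500) + 1024, 1, 5),
                   bit_depth = 16L, slope = 1, intercept = -1024)
  out <- to_eight_bit(ct, w)
  expect_identical(out$bit_depth, 8L)
  expect_identical(as.vector(out$pixels), c(128, 0, 255, 0, 255))
})

test_that("windowing is monotone non-decreasing and defaults sensibly", {
  set.seed(3)
  vals <- sort(runif(200, -200, 300))
  ct <- gray_image(matrix(vals + 1024, 1, 200), bit_depth = 16L,
                   slope = 1, intercept = -1024)
  out <- to_eight_bit(ct, window_spec(40, 95))
  expect_true(all(diff(as.vector(out$pixels)) >= 0))

  # default for CT-like input is the brain window; 8-bit input is unchanged
  expect_identical(to_eight_bit(ct)$pixels,
                   to_eight_bit(ct, brain_window())$pixels)
  r8 <- random_img(10, 10)
  expect_identical(to_eight_bit(r8), r8)
  # 16-bit non-CT input: min-max scaling hits both endpoints
  r16 <- random_img(20, 20, bits = 16L, seed = 2)
  mm <- to_eight_bit(r16)
  expect_identical(range(mm$pixels), c(0, 255))
  expect_error(window_spec(0, 0), "width")
})
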