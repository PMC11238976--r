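overlay_fixture <- function() {
  ref <- to_eight_bit(small_phantom(seed = 3))
  tgt <- to_eight_bit(simulate_dose_noise(small_phantom(seed = 3),
                                          dose_noise_spec(27.4, seed = 5)))
  fr <- reference_detect_describe(ref)
  ft <- reference_detect_describe(tgt)
  m <- brute_force_match(fr$descriptors, ft$descriptors)
  list(ref = ref, tgt = tgt, fr = fr, ft = ft, m = m)
}

test_that("the overlay canvas is two panels wide plus the gap", {
  f <- overlay_fixture()
  ov <- render_matches(f$ref, f$tgt, f$fr$keypoints, f$ft$keypoints, f$m,
                       overlay_spec(gap = 10))
  expect_identical(ov$width, ncol(f$ref$pixels) + 10L + ncol(f$tgt$pixels))
  expect_identical(ov$height, nrow(f$ref$pixels))
  ras <- rasterize_overlay(ov)
  expect_identical(dim(ras), c(ov$height, ov$width, 3L))
  expect_true(all(ras >= 0 & ras <= 1))
})

test_that("one line primitive is drawn per matched pair, dots for all keypoints", {
  f <- overlay_fixture()
  ov <- render_matches(f$ref, f$tgt, f$fr$keypoints, f$ft$keypoints, f$m)
  expect_identical(nrow(ov$primitives$lines), f$m$N)
  expect_identical(nrow(ov$primitives$points),
                   nrow(f$fr$keypoints) + nrow(f$ft$keypoints))
})

test_that("matching an image to itself yields horizontal match lines", {
  ref <- to_eight_bit(small_phantom(seed = 3))
  fr <- reference_detect_describe(ref)
  m <- brute_force_match(fr$descriptors, fr$descriptors)
  ov <- render_matches(ref, ref, fr$keypoints, fr$keypoints, m)
  expect_true(all(ov$primitives$lines$y0 == ov$primitives$lines$y1))
})

test_that("an empty match set renders dots only and writes a PNG", {
  ref <- to_eight_bit(small_phantom(seed = 3))
  fr <- reference_detect_describe(ref)
  empty <- brute_force_match(fr$descriptors,
                             reference_detect_describe(const_img(5))$descriptors)
  ov <- render_matches(ref, const_img(5, 192, 192), fr$keypoints,
                       data.frame(x = numeric(0), y = numeric(0)), empty)
  expect_identical(nrow(ov$primitives$lines), 0L)
  expect_gt(nrow(ov$primitives$points), 0)
  p <- withr::local_tempfile(fileext = ".png")
  write_overlay(ov, p)
  expect_true(file.exists(p))
})

test_that("rendering never mutates its input images", {
  f <- overlay_fixture()
  before <- f$ref$pixels
  ov <- render_matches(f$ref, f$tgt, f$fr$keypoints, f$ft$keypoints, f$m)
  invisible(rasterize_overlay(ov))
  expect_identical(f$ref$pixels, before)
})

test_that("inconsistent match indices are rejected", {
  f <- overlay_fixture()
  expect_error(
    render_matches(f$ref, f$tgt, f$fr$keypoints[1:2, ], f$ft$keypoints[1:2, ],
                   f$m),
    "indices")
})
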