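backends <- c("akaze", "brisk", "orb", "ref")

test_that("a constant image yields zero keypoints and an empty descriptor set", {
  img <- const_img(77)
  for (b in backends) {
    res <- detect_and_describe(img, backend_params(b))
    expect_identical(nrow(res$keypoints), 0L)
    expect_identical(n_descriptors(res$descriptors), 0L)
  }
})

test_that("detection is deterministic and index-aligned on real structure", {
  img <- to_eight_bit(small_phantom(seed = 3))
  for (b in backends) {
    r1 <- detect_and_describe(img, backend_params(b))
    r2 <- detect_and_describe(img, backend_params(b))
    expect_identical(r1$keypoints, r2$keypoints)
    expect_identical(r1$descriptors$bytes, r2$descriptors$bytes)
    expect_identical(nrow(r1$keypoints), n_descriptors(r1$descriptors))
    expect_gt(nrow(r1$keypoints), 0)
  }
})

test_that("descriptor bit lengths are fixed per backend", {
  img <- to_eight_bit(small_phantom(seed = 3))
  expected <- c(akaze = 486L, brisk = 512L, orb = 256L, ref = 256L)
  for (b in backends) {
    ds <- detect_and_describe(img, backend_params(b))$descriptors
    expect_identical(ds$L, expected[[b]])
    expect_identical(descriptor_length(b), expected[[b]])
    expect_identical(ncol(descriptor_bits(ds)), expected[[b]])
  }
})

test_that("a high-contrast square produces keypoints at its corners", {
  img <- square_img(100, from = 41, to = 60)
  res <- reference_detect_describe(img)
  kp <- res$keypoints
  expect_gte(nrow(kp), 4)
  corners <- rbind(c(40, 40), c(59, 40), c(40, 59), c(59, 59)) # 0-based x, y
  for (i in 1:4) {
    d <- sqrt((kp$x - corners[i, 1])^2 + (kp$y - corners[i, 2])^2)
    expect_lte(min(d), 3)
  }
})

test_that("segment-test detection agrees with a brute-force oracle", {
  img <- corner_img(64, corner = 31)
  res <- reference_detect_describe(img)
  hits <- naive_segment_test(img$pixels, threshold = 10)
  expect_gt(nrow(hits), 0)
  # the detector must place a keypoint within 2 px of an oracle corner pixel
  expect_gte(nrow(res$keypoints), 1)
  dmin <- min(sqrt(outer(res$keypoints$x, hits[, 1], "-")^2 +
                   outer(res$keypoints$y, hits[, 2], "-")^2))
  expect_lte(dmin, 2)
})

test_that("the reference descriptor is invariant to uniform intensity shifts", {
  img <- to_eight_bit(small_phantom(seed = 9))
  px <- pmin(img$pixels, 240)  # leave head-room for the +10 shift
  a <- reference_detect_describe(img8(px))
  b <- reference_detect_describe(img8(px + 10))
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$descriptors$bytes, b$descriptors$bytes)
})

test_that("non-8-bit input is rejected and caps limit keypoint counts", {
  expect_error(detect_and_describe(random_img(32, 32, bits = 16L),
                                   backend_params("ref")), "8-bit")
  img <- to_eight_bit(small_phantom(seed = 3))
  res <- detect_and_describe(img, backend_params("ref", max_keypoints = 10))
  expect_lte(nrow(res$keypoints), 10)
  expect_identical(nrow(res$keypoints), n_descriptors(res$descriptors))
})
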