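test_that("hamming counts differing bits and rejects length mismatches", {
  expect_identical(hamming(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0L)
  expect_identical(hamming(c(0, 0, 0, 0), c(1, 1, 1, 1)), 4L)
  set.seed(1)
  a_bits <- sample(c(TRUE, FALSE), 256, replace = TRUE)
  b_bits <- sample(c(TRUE, FALSE), 256, replace = TRUE)
  a <- packBits(a_bits, type = "raw")
  b <- packBits(b_bits, type = "raw")
  # naive bit-by-bit oracle
  oracle <- sum(a_bits != b_bits)
  expect_identical(hamming(a, b), oracle)
  expect_identical(hamming(a, b), hamming(b, a))
  expect_error(hamming(a, b[1:16]), "length")
  expect_error(hamming(c(0, 1), c(0, 1, 1)), "length")
})

test_that("identical distinct descriptor sets match to the identity", {
  ds <- random_descriptor_set(25, 256, seed = 4)
  m <- brute_force_match(ds, ds)
  expect_identical(m$N, 25L)
  expect_identical(m$pairs$ref_index, m$pairs$tgt_index)
  expect_true(all(m$pairs$distance == 0))
  expect_identical(proposed_index(m)$value, 0)
})

test_that("a single pair matches with its plain hamming distance", {
  a <- random_descriptor_set(1, 256, seed = 1)
  b <- random_descriptor_set(1, 256, seed = 2)
  m <- brute_force_match(a, b)
  expect_identical(m$N, 1L)
  expect_identical(m$pairs$distance, hamming(a$bytes[, 1], b$bytes[, 1]))
})

test_that("brute-force matching equals the naive oracle on random instances", {
  for (i in 1:30) {
    L <- sample(c(256L, 512L), 1)
    nr <- sample(1:30, 1)
    nt <- sample(1:30, 1)
    ra <- random_descriptor_set(nr, L, seed = 1000 + i)
    rb <- random_descriptor_set(nt, L, seed = 2000 + i)
    got <- brute_force_match(ra, rb)$pairs
    want <- naive_match(descriptor_bits(ra), descriptor_bits(rb))
    expect_identical(got$ref_index, want$ref_index)
    expect_identical(got$tgt_index, want$tgt_index)
    expect_identical(got$distance, as.integer(want$distance))
  }
})

test_that("matching is one-to-one and bounded by the descriptor length", {
  ra <- random_descriptor_set(40, 256, seed = 31)
  rb <- random_descriptor_set(25, 256, seed = 32)
  m <- brute_force_match(ra, rb)
  expect_false(any(duplicated(m$pairs$ref_index)))
  expect_false(any(duplicated(m$pairs$tgt_index)))
  expect_true(all(m$pairs$distance >= 0 & m$pairs$distance <= 256))
  expect_lte(m$N, 25)
})

test_that("the index is the arithmetic mean of pair distances", {
  ra <- random_descriptor_set(60, 512, seed = 51)
  rb <- random_descriptor_set(60, 512, seed = 52)
  m <- brute_force_match(ra, rb)
  # independent accumulation
  total <- 0
  for (d in m$pairs$distance) total <- total + d
  expect_equal(proposed_index(m)$value, total / m$N)
  expect_equal(proposed_index(m)$normalized, (total / m$N) / 512)
})

test_that("zero matches is an explicit error carrying both counts", {
  e1 <- random_descriptor_set(0, 256)
  e2 <- random_descriptor_set(7, 256, seed = 3)
  m <- brute_force_match(e1, e2)
  expect_identical(m$N, 0L)
  expect_error(proposed_index(m), "0 reference vs 7 target")
})

test_that("backend mismatch is a domain error", {
  a <- random_descriptor_set(5, 256, backend = "ref")
  b <- random_descriptor_set(5, 256, backend = "orb", seed = 2)
  expect_error(brute_force_match(a, b), "backend")
})

test_that("the index trends upward with noise level (rank correlation)", {
  ph <- small_phantom(seed = 2, size = 256)
  ref8 <- to_eight_bit(ph)
  fr <- reference_detect_describe(ref8)
  sigmas <- c(2, 6, 12, 20, 30)
  pis <- sapply(seq_along(sigmas), function(i) {
    sp <- dose_noise_spec(89.1, 89.1, sigmas[i], seed = 100 + i)
    t8 <- to_eight_bit(simulate_dose_noise(ph, sp))
    ft <- reference_detect_describe(t8)
    proposed_index(brute_force_match(fr$descriptors, ft$descriptors))$value
  })
  expect_gt(cor(sigmas, pis, method = "spearman"), 0)
})
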