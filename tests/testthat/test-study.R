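test_that("pearson_test reproduces exact and textbook cases", {
  x <- 1:10
  r1 <- pearson_test(x, -x)
  expect_equal(r1$r, -1)
  expect_equal(r1$p, 0)
  expect_true(r1$significant)

  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  got <- pearson_test(x, y)
  # independent route: base R
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("the p-value matches a numerically integrated t tail to 1e-9", {
  set.seed(77)
  x <- rnorm(10)
  y <- 0.4 * x + rnorm(10)
  got <- pearson_test(x, y)
  t <- got$r * sqrt((got$n - 2) / (1 - got$r^2))
  tail <- integrate(function(u) dt(u, df = got$n - 2), abs(t), Inf,
                    rel.tol = 1e-12)$value
  expect_equal(got$p, 2 * tail, tolerance = 1e-9)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
  expect_error(pearson_test(1:5, rep(2, 5)), "constant")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
  expect_error(pearson_test(1:4, 1:5), "equal length")
})

make_mini_validity <- function() {
  # noise-free reference so the zero-noise condition reproduces it exactly
  ph <- small_phantom(seed = 2, size = 192)
  # include an effectively undegraded condition (gigantic dose -> zero noise)
  noise <- c(dose_series(ctdi = c(5.5, 27.4, 74.2), seed = 10),
             list(identity = dose_noise_spec(1e9, seed = 99)))
  run_validity_study(ph, noise_series = noise,
                     blur_series = blur_series(k = c(3, 9, 15)),
                     backends = c("ref", "orb"))
}

test_that("the validity study records conditions and correlations coherently", {
  res <- make_mini_validity()
  recs <- res$records
  expect_identical(nrow(recs), 2L * 7L)
  expect_true(all(recs$n_matches <= pmin(recs$keypoints_ref, recs$keypoints_tgt)))
  ok <- !is.na(recs$pi)
  expect_true(all(recs$pi[ok] >= 0))
  expect_true(all(recs$pi[ok] <= ifelse(recs$backend[ok] == "orb", 256, 256)))
  expect_true(all(c("pi", "psnr") %in% res$correlations$metric))
  expect_true(all(abs(res$correlations$r) <= 1))
  expect_equal(res$correlations$significant, res$correlations$p < 0.05)
})

test_that("an undegraded condition scores index 0 and SSIM 1", {
  res <- make_mini_validity()
  idr <- res$records[res$records$label == "identity", ]
  expect_true(all(idr$pi == 0))
  expect_true(all(idr$ssim == 1))
  expect_true(all(is.infinite(idr$psnr)))
})

test_that("the robustness study produces stability summaries per series", {
  ph <- small_phantom(seed = 2, size = 192)
  res <- run_robustness_study(
    to_eight_bit(ph),
    series = list(translation = translation_series(px = c(2, 6, 10)),
                  rotation = rotation_series(angles = c(5, 15, 30))),
    backends = c("ref", "brisk"))
  expect_identical(nrow(res$records), 2L * 6L)
  st <- res$stability
  expect_identical(sort(unique(st$series)), c("rotation", "translation"))
  expect_true(all(st$pi_cv >= 0))
  expect_true(all(st$ssim_rel_range >= 0 & st$ssim_rel_range <= 1))
  # SSIM degrades with rotation angle on the phantom
  rot <- res$records[res$records$series == "rotation" & res$records$backend == "ref", ]
  expect_true(all(diff(rot$ssim[order(rot$param)]) < 0))
})

test_that("reports round-trip through JSON and have the documented schema", {
  res <- make_mini_validity()
  out <- withr::local_tempdir()
  files <- write_report(res, out, plots = FALSE)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "correlations.csv")))
  expect_true(file.exists(file.path(out, "study.json")))

  recs <- read.csv(file.path(out, "records.csv"))
  expect_identical(
    names(recs),
    c("series", "label", "param", "backend", "keypoints_ref", "keypoints_tgt",
      "n_matches", "pi", "ssim", "psnr"))

  back <- read_study_result(file.path(out, "study.json"))
  expect_equal(back$records$pi, res$records$pi, tolerance = 1e-12)
  expect_equal(back$records$ssim, res$records$ssim, tolerance = 1e-12)
  expect_equal(back$correlations$r, res$correlations$r, tolerance = 1e-12)
  expect_identical(back$records$label, res$records$label)
})
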