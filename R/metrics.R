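#' SSIM parameters
#'
#' @param window odd window side length in pixels (default 7, uniform
#'   weighting).
#' @param K1,K2 stabilization constants; `C1 = (K1 * data_range)^2`,
#'   `C2 = (K2 * data_range)^2`.
#' @param data_range dynamic range of the images (255 for 8-bit); `NULL`
#'   derives it from the image bit depth.
#' @param gaussian_weighted use an 11-point Gaussian window (sigma 1.5)
#'   instead of the uniform window.
#' @export
ssim_params <- function(window = 7L, K1 = 0.01, K2 = 0.03, data_range = NULL,
                        gaussian_weighted = FALSE) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd and >= 3")
  if (K1 <= 0 || K2 <= 0) stop("K1 and K2 must be > 0")
  structure(list(window = window, K1 = K1, K2 = K2, data_range = data_range,
                 gaussian_weighted = gaussian_weighted),
            class = "ssim_params")
}

#' Structural similarity index
#'
#' Mean local SSIM between two images of equal size: within each sliding
#' window the luminance/contrast/structure comparison
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) / ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 +
#' sigma_y^2 + C2))` is computed from the local moments, and the mean over
#' all fully interior window positions is returned. Identical images score
#' exactly 1. Symmetric in its arguments.
#'
#' @param ref,tgt [gray_image()]s of equal dimensions and bit depth.
#' @param params an [ssim_params()].
#' @param full also return the local SSIM map.
#' @return the mean SSIM, or (with `full = TRUE`) a list `(mean, map)`.
#' @export
ssim <- function(ref, tgt, params = ssim_params(), full = FALSE) {
  assert_gray_image(ref)
  assert_gray_image(tgt)
  if (!all(dim(ref$pixels) == dim(tgt$pixels))) stop("image dimensions differ")
  if (ref$bit_depth != tgt$bit_depth) stop("image bit depths differ")
  stopifnot(inherits(params, "ssim_params"))
  dr <- params$data_range %||% (2^ref$bit_depth - 1)
  C1 <- (params$K1 * dr)^2
  C2 <- (params$K2 * dr)^2
  x <- ref$pixels
  y <- tgt$pixels
  if (params$gaussian_weighted) {
    w <- 11L
    kern <- gaussian_kernel(w, 1.5)
    mu_x <- sep_filter_valid(x, kern)
    mu_y <- sep_filter_valid(y, kern)
    xx <- sep_filter_valid(x * x, kern)
    yy <- sep_filter_valid(y * y, kern)
    xy <- sep_filter_valid(x * y, kern)
  } else {
    w <- params$window
    mu_x <- box_mean_valid(x, w)
    mu_y <- box_mean_valid(y, w)
    xx <- box_mean_valid(x * x, w)
    yy <- box_mean_valid(y * y, w)
    xy <- box_mean_valid(x * y, w)
  }
  vx <- xx - mu_x^2
  vy <- yy - mu_y^2
  cxy <- xy - mu_x * mu_y
  map <- ((2 * mu_x * mu_y + C1) * (2 * cxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (vx + vy + C2))
  m <- mean(map)
  if (full) list(mean = m, map = map) else m
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels; `Inf` for identical images
#' (zero MSE), reported as such rather than as an error.
#'
#' @param ref,tgt [gray_image()]s of equal dimensions.
#' @param data_range peak intensity; `NULL` derives it from the bit depth.
#' @export
psnr <- function(ref, tgt, data_range = NULL) {
  assert_gray_image(ref)
  assert_gray_image(tgt)
  if (!all(dim(ref$pixels) == dim(tgt$pixels))) stop("image dimensions differ")
  dr <- data_range %||% (2^ref$bit_depth - 1)
  mse <- mean((ref$pixels - tgt$pixels)^2)
  if (mse == 0) return(Inf)
  10 * log10(dr^2 / mse)
}

# ---- local-moment helpers ----------------------------------------------------

# mean over every fully interior w x w window, via a summed-area table
box_mean_valid <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  if (h < w || wd < w) stop("image smaller than the SSIM window")
  S <- matrix(0, h + 1, wd + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i0 <- 1:(h - w + 1)
  j0 <- 1:(wd - w + 1)
  (S[i0 + w, j0 + w, drop = FALSE] - S[i0, j0 + w, drop = FALSE] -
     S[i0 + w, j0, drop = FALSE] + S[i0, j0, drop = FALSE]) / (w * w)
}

# separable weighted filtering, valid region only; kern sums to 1
sep_filter_valid <- function(m, kern) {
  k <- length(kern)
  h <- nrow(m); wd <- ncol(m)
  out1 <- matrix(0, h - k + 1, wd)
  for (i in seq_len(k)) {
    out1 <- out1 + kern[i] * m[i:(h - k + i), , drop = FALSE]
  }
  out2 <- matrix(0, h - k + 1, wd - k + 1)
  for (j in seq_len(k)) {
    out2 <- out2 + kern[j] * out1[, j:(wd - k + j), drop = FALSE]
  }
  out2
}
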