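#' Gaussian-blur sigma implied by a kernel size
#'
#' The blur series ties sigma to the kernel size `k` by
#' `sigma = 0.3 * (k/2 - 1) + 0.8` (so k = 3 gives 0.95, k = 21 gives 3.65),
#' with `k/2` evaluated as the real division. The common computer-vision
#' library convention `0.3 * ((k - 1)/2 - 1) + 0.8` differs (k = 3 gives
#' 0.8) and is available via `convention = "opencv"` for compatibility.
#'
#' @param k odd kernel size, `>= 3`.
#' @param convention `"half-kernel"` (default) or `"opencv"`.
#' @return the Gaussian sigma in pixels.
#' @export
blur_sigma <- function(k, convention = c("half-kernel", "opencv")) {
  convention <- match.arg(convention)
  if (!is.numeric(k) || k < 3 || k %% 2 == 0) {
    stop("`k` must be an odd kernel size >= 3")
  }
  switch(convention,
         "half-kernel" = 0.3 * (k / 2 - 1) + 0.8,
         "opencv" = 0.3 * ((k - 1) / 2 - 1) + 0.8)
}

#' Blur specification
#'
#' @inheritParams blur_sigma
#' @export
blur_spec <- function(k, convention = c("half-kernel", "opencv")) {
  sigma <- blur_sigma(k, convention)  # validates k
  structure(list(k = as.integer(k), sigma = sigma,
                 convention = match.arg(convention)),
            class = "blur_spec")
}

gaussian_kernel <- function(k, sigma) {
  c0 <- (k - 1) / 2
  g <- exp(-((0:(k - 1)) - c0)^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian blur with sigma derived from the kernel size
#'
#' Separable `k x k` Gaussian convolution with reflective border handling
#' (edge not repeated); output dimensions and metadata are unchanged and a
#' constant image passes through untouched (the kernel is normalized).
#'
#' @param img a [gray_image()].
#' @param spec a [blur_spec()], or an odd kernel size which is promoted via
#'   [blur_spec()].
#' @export
gaussian_blur <- function(img, spec) {
  assert_gray_image(img)
  if (is.numeric(spec)) spec <- blur_spec(spec)
  stopifnot(inherits(spec, "blur_spec"))
  kern <- gaussian_kernel(spec$k, spec$sigma)
  out <- convolve_separable(img$pixels, kern)
  px <- clip(round_half_up(out), 0, 2^img$bit_depth - 1)
  gray_image(px, bit_depth = img$bit_depth, spacing_mm = img$spacing_mm,
             slope = img$slope, intercept = img$intercept)
}

# separable convolution with reflect-101 borders (edge sample not repeated)
convolve_separable <- function(m, kern) {
  k <- length(kern)
  r <- (k - 1) / 2
  reflect_idx <- function(i, n) {
    # reflect around the edge samples until inside [1, n]
    while (any(bad <- i < 1 | i > n)) {
      i[bad & i < 1] <- 2 - i[bad & i < 1]
      i[bad & i > n] <- 2 * n - i[bad & i > n]
    }
    i
  }
  h <- nrow(m); wd <- ncol(m)
  tmp <- matrix(0, h, wd)
  for (t in seq_len(k)) {
    rows <- reflect_idx(seq_len(h) + (t - 1 - r), h)
    tmp <- tmp + kern[t] * m[rows, , drop = FALSE]
  }
  out <- matrix(0, h, wd)
  for (t in seq_len(k)) {
    cols <- reflect_idx(seq_len(wd) + (t - 1 - r), wd)
    out <- out + kern[t] * tmp[, cols, drop = FALSE]
  }
  out
}

#' Affine transform specification
#'
#' Exactly one kind is parameterized: `translate` by `(dx, dy)` pixels
#' (positive dx moves content rightward, positive dy downward), `rotate` by
#' `angle` degrees about the geometric image center, or `scale` by `factor`
#' about the center. Interpolation is bilinear; regions exposed by the
#' transform are filled with the `border` constant (default 0, air).
#'
#' @param kind `"translate"`, `"rotate"` or `"scale"`.
#' @param dx,dy translation in pixels.
#' @param angle rotation angle in degrees; positive angles rotate the
#'   displayed content clockwise.
#' @param factor scale factor, `> 0`.
#' @param border fill value for exposed regions.
#' @export
affine_spec <- function(kind = c("translate", "rotate", "scale"),
                        dx = 0, dy = 0, angle = 0, factor = 1, border = 0) {
  kind <- match.arg(kind)
  if (factor <= 0) stop("`factor` must be > 0")
  structure(list(kind = kind, dx = dx, dy = dy, angle = angle,
                 factor = factor, border = border),
            class = "affine_spec")
}

#' Apply an affine transform
#'
#' Output dimensions equal input dimensions. Identity parameters (zero
#' shift, zero angle, factor 1) return a bit-identical image; integer
#' translations are lossless shifts.
#'
#' @param img a [gray_image()].
#' @param spec an [affine_spec()].
#' @export
apply_affine <- function(img, spec) {
  assert_gray_image(img)
  stopifnot(inherits(spec, "affine_spec"))
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  M <- switch(spec$kind,
    translate = c(1, 0, -spec$dx, 0, 1, -spec$dy),
    rotate = {
      th <- spec$angle * pi / 180
      c(cos(th), sin(th), cx - cos(th) * cx - sin(th) * cy,
        -sin(th), cos(th), cy + sin(th) * cx - cos(th) * cy)
    },
    scale = {
      f <- spec$factor
      c(1 / f, 0, cx - cx / f, 0, 1 / f, cy - cy / f)
    }
  )
  out <- cpp_warp_affine(img$pixels, M, spec$border)
  px <- clip(round_half_up(out), 0, 2^img$bit_depth - 1)
  gray_image(px, bit_depth = img$bit_depth, spacing_mm = img$spacing_mm,
             slope = img$slope, intercept = img$intercept)
}

# ---- standard degradation series --------------------------------------------

#' Standard degradation and transform series
#'
#' The condition grids used by the validation studies: ten simulated dose
#' levels (CTDIvol 2.7-74.2 mGy against a 89.1 mGy reference), ten Gaussian
#' kernel sizes 3-21, eleven translations of 2-40 px, eleven rotations of
#' 1-45 degrees, five reduction factors 0.75-0.95 and five enlargement
#' factors 1.05-1.25.
#'
#' @param ctdi dose values in mGy.
#' @param ref_ctdi,sigma_at_ref see [dose_noise_spec()].
#' @param seed base seed; condition `i` uses `seed + i`.
#' @return a named list of specification objects.
#' @export
dose_series <- function(ctdi = c(2.7, 5.5, 13.7, 21.9, 27.4, 35.6, 41.0,
                                 53.4, 59.4, 74.2),
                        ref_ctdi = 89.1, sigma_at_ref = 4, seed = 1L) {
  out <- lapply(seq_along(ctdi), function(i) {
    dose_noise_spec(ctdi[i], ref_ctdi, sigma_at_ref, seed = seed + i)
  })
  names(out) <- sprintf("%.1f mGy", ctdi)
  out
}

#' @rdname dose_series
#' @param k odd Gaussian kernel sizes.
#' @param convention sigma convention, see [blur_sigma()].
#' @export
blur_series <- function(k = seq(3L, 21L, by = 2L),
                        convention = "half-kernel") {
  out <- lapply(k, blur_spec, convention = convention)
  names(out) <- sprintf("k=%d", k)
  out
}

#' @rdname dose_series
#' @param px translation amounts in pixels (applied along x).
#' @export
translation_series <- function(px = c(2, 4, 8, 12, 16, 20, 24, 28, 32, 36, 40)) {
  out <- lapply(px, function(p) affine_spec("translate", dx = p, dy = 0))
  names(out) <- sprintf("%d px", px)
  out
}

#' @rdname dose_series
#' @param angles rotation angles in degrees.
#' @export
rotation_series <- function(angles = c(1, 3, 5, 10, 15, 20, 25, 30, 35, 40, 45)) {
  out <- lapply(angles, function(a) affine_spec("rotate", angle = a))
  names(out) <- sprintf("%g deg", angles)
  out
}

#' @rdname dose_series
#' @param factors scale factors.
#' @export
reduction_series <- function(factors = c(0.75, 0.8, 0.85, 0.9, 0.95)) {
  out <- lapply(factors, function(f) affine_spec("scale", factor = f))
  names(out) <- sprintf("x%.2f", factors)
  out
}

#' @rdname dose_series
#' @export
enlargement_series <- function(factors = c(1.05, 1.1, 1.15, 1.2, 1.25)) {
  out <- lapply(factors, function(f) affine_spec("scale", factor = f))
  names(out) <- sprintf("x%.2f", factors)
  out
}
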