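#' Synthetic head-phantom specification
#'
#' Parameters of the head-CT-like test object: a bright elliptical skull
#' ring enclosing uniform soft tissue sprinkled with randomly placed,
#' non-overlapping low-contrast ellipses, on an air background. The phantom
#' is generated in Hounsfield units and stored like a CT slice (stored value
#' = HU + 1024, 16-bit, rescale intercept -1024).
#'
#' @param size image side in pixels (square), default 512.
#' @param skull_outer,skull_inner outer/inner skull radii as a fraction of
#'   `size`; `0 < inner < outer < 0.5`.
#' @param tissue_mean interior soft-tissue value in HU.
#' @param n_structures number of internal low-contrast ellipses.
#' @param structure_contrast contrast scale of the ellipses in HU. Real
#'   slices show a continuum of tissue contrasts (gray/white interfaces of
#'   ~10 HU up to calcifications of hundreds of HU), so each structure draws
#'   its absolute contrast as `structure_contrast * 2^u` with `u` uniform on
#'   `[-1, 3]` (i.e. 0.5x to 8x the scale), with random sign.
#' @param texture_sigma standard deviation (HU) of the smooth random
#'   texture field added to the interior. Real soft tissue is not uniform:
#'   parenchymal structure and the reconstruction kernel leave correlated
#'   texture at millimetre scales everywhere in a CT slice, which is what
#'   gives feature detectors their working population of keypoints at every
#'   pyramid scale. Generated as seeded Gaussian white noise smoothed with a
#'   5-pixel Gaussian (about 2.5 mm at the default field of view), part of
#'   the phantom itself (identical across all degraded targets); 0 disables.
#' @param ring_waviness standard deviation of the fractional radial
#'   modulation of the skull boundaries. Real skulls are not smooth annuli:
#'   sutures and inner-table irregularities give the bone edge corner-like
#'   structure at full bone/tissue contrast. The default (0.011, i.e. bumps
#'   of a few pixels at the default size) emulates that; 0 gives perfectly
#'   elliptical boundaries.
#' @param seed integer seed making the structure layout reproducible.
#' @export
phantom_spec <- function(size = 512L, skull_outer = 0.45, skull_inner = 0.42,
                         tissue_mean = 40, n_structures = 100L,
                         structure_contrast = 15, texture_sigma = 5,
                         ring_waviness = 0.011, seed = 1L) {
  size <- as.integer(size)
  if (size < 32) stop("`size` must be at least 32")
  if (!(skull_inner > 0 && skull_inner < skull_outer && skull_outer < 0.5)) {
    stop("need 0 < skull_inner < skull_outer < 0.5")
  }
  if (n_structures < 0) stop("`n_structures` must be >= 0")
  if (ring_waviness < 0) stop("`ring_waviness` must be >= 0")
  if (texture_sigma < 0) stop("`texture_sigma` must be >= 0")
  structure(
    list(size = size, skull_outer = skull_outer, skull_inner = skull_inner,
         tissue_mean = tissue_mean, n_structures = as.integer(n_structures),
         structure_contrast = structure_contrast,
         texture_sigma = texture_sigma,
         ring_waviness = ring_waviness, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic head-CT phantom slice
#'
#' Deterministic for a fixed spec (including seed). Air is -1000 HU, the
#' skull ring 1500 HU, the interior `tissue_mean` HU with `n_structures`
#' non-overlapping elliptical inserts at `tissue_mean +/- structure_contrast`.
#' The head outline is slightly elliptical (width 0.92 of height). Pixel
#' spacing corresponds to a 250 mm reconstruction field of view.
#'
#' @param spec a [phantom_spec()].
#' @return a 16-bit CT-like [gray_image()] (see [as_hu()]).
#' @export
generate_head_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  ctr <- (n - 1) / 2
  xg <- matrix(rep(0:(n - 1), each = n), nrow = n) - ctr   # [y, x] = x coord
  yg <- matrix(rep(0:(n - 1), times = n), nrow = n) - ctr  # [y, x] = y coord
  rr <- sqrt((xg / 0.92)^2 + yg^2)
  # irregular skull boundaries: seeded harmonic modulation of both radii,
  # evaluated through a fine angular lookup table
  if (spec$ring_waviness > 0) {
    wav <- with_seed(spec$seed + 77L, ring_waviness_tables(spec$ring_waviness))
    phi_idx <- 1L + as.integer(round((atan2(yg, xg / 0.92) + pi) /
                                       (2 * pi) * (length(wav$outer) - 1)))
    w_out <- matrix(wav$outer[phi_idx], n, n)
    w_in <- matrix(wav$inner[phi_idx], n, n)
  } else {
    w_out <- w_in <- 0
  }
  hu <- matrix(-1000, n, n)
  hu[rr <= spec$skull_outer * n * (1 + w_out)] <- 1500
  interior <- rr <= spec$skull_inner * n * (1 + w_in)
  hu[interior] <- spec$tissue_mean

  if (spec$n_structures > 0) {
    el <- with_seed(spec$seed, place_ellipses(spec))
    for (i in seq_len(nrow(el))) {
      a <- el$a[i]; b <- el$b[i]; th <- el$theta[i]
      dx <- xg - el$x[i]
      dy <- yg - el$y[i]
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      mask <- ((u / a)^2 + (v / b)^2 <= 1) & interior
      hu[mask] <- spec$tissue_mean + el$contrast[i]
    }
  }
  if (spec$texture_sigma > 0) {
    tex <- with_seed(spec$seed + 131L, {
      field <- matrix(rnorm(n * n), n, n)
      convolve_separable(field, gaussian_kernel(31L, 5))
    })
    tex <- tex / stats::sd(tex) * spec$texture_sigma
    hu[interior] <- hu[interior] + tex[interior]
  }
  px <- clip(round_half_up(hu) + 1024, 0, 65535)
  gray_image(px, bit_depth = 16L, spacing_mm = rep(250 / n, 2),
             slope = 1, intercept = -1024)
}

# harmonic radius-modulation profiles for the two skull boundaries;
# amplitudes fall off as 1/k and the profile is normalized to the requested
# standard deviation, giving bumps a few pixels high and a few tens of
# pixels wide at the default size (suture-like irregularity)
ring_waviness_tables <- function(sd_target, nphi = 4096L, harmonics = 8:64) {
  one <- function() {
    phase <- stats::runif(length(harmonics), 0, 2 * pi)
    # periodic: the (nphi+1)-th sample would repeat the first
    phi <- seq(-pi, pi, length.out = nphi + 1L)[seq_len(nphi)]
    w <- rowSums(vapply(seq_along(harmonics), function(i) {
      cos(harmonics[i] * phi + phase[i]) / harmonics[i]
    }, numeric(nphi)))
    w <- c(w, w[1L])  # wrap so index nphi+1 (phi = +pi) maps back
    w / stats::sd(w) * sd_target
  }
  list(outer = one(), inner = one())
}

# rejection-sample non-overlapping ellipse parameters inside the skull
place_ellipses <- function(spec) {
  n <- spec$size
  rmax <- spec$skull_inner * n * 0.85
  out <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                    b = numeric(0), theta = numeric(0), contrast = numeric(0))
  tries <- 0L
  while (nrow(out) < spec$n_structures) {
    tries <- tries + 1L
    if (tries > 500L * spec$n_structures) {
      stop("could not place ", spec$n_structures, " non-overlapping structures")
    }
    a <- stats::runif(1, 2, 12)
    b <- stats::runif(1, 2, a)
    rho <- sqrt(stats::runif(1)) * (rmax - a)
    ang <- stats::runif(1, 0, 2 * pi)
    x <- rho * cos(ang) * 0.92
    y <- rho * sin(ang)
    theta <- stats::runif(1, 0, pi)
    contrast <- sample(c(-1, 1), 1) * spec$structure_contrast *
      2^stats::runif(1, -1, 3)
    if (nrow(out) > 0) {
      d <- sqrt((out$x - x)^2 + (out$y - y)^2)
      if (any(d < out$a + a + 2)) next
    }
    out <- rbind(out, data.frame(x = x, y = y, a = a, b = b,
                                 theta = theta, contrast = contrast))
  }
  out
}

#' Dose-dependent quantum-noise specification
#'
#' First-order emulation of CT quantum noise after reconstruction: additive
#' zero-mean white Gaussian noise whose standard deviation follows the
#' inverse-square-root dose law `sigma = sigma_at_ref * sqrt(ref_ctdi / ctdi)`.
#'
#' @param ctdi volume CT dose index of the simulated acquisition, mGy (> 0).
#' @param ref_ctdi reference dose at which `sigma_at_ref` is specified,
#'   default 89.1 mGy.
#' @param sigma_at_ref noise standard deviation at the reference dose, in the
#'   image's stored intensity units (HU for CT-like images); default 4.
#' @param seed integer seed for the noise realization.
#' @export
dose_noise_spec <- function(ctdi, ref_ctdi = 89.1, sigma_at_ref = 4, seed = 1L) {
  if (!is.numeric(ctdi) || ctdi <= 0) stop("`ctdi` must be > 0")
  if (ref_ctdi <= 0 || sigma_at_ref <= 0) stop("dose parameters must be > 0")
  structure(
    list(ctdi = ctdi, ref_ctdi = ref_ctdi, sigma_at_ref = sigma_at_ref,
         seed = as.integer(seed)),
    class = "dose_noise_spec"
  )
}

#' Noise level implied by a dose-noise specification
#' @param spec a [dose_noise_spec()].
#' @return the Gaussian standard deviation in stored intensity units.
#' @export
noise_sigma <- function(spec) {
  stopifnot(inherits(spec, "dose_noise_spec"))
  spec$sigma_at_ref * sqrt(spec$ref_ctdi / spec$ctdi)
}

#' Add dose-dependent quantum noise to an image
#'
#' Adds white Gaussian noise with the standard deviation of [noise_sigma()],
#' rounds to integers and clips to the image's valid range (physical
#' saturation, no wrap-around). Deterministic for a fixed seed.
#'
#' @param img an 8- or 16-bit [gray_image()].
#' @param spec a [dose_noise_spec()].
#' @return a [gray_image()] with the same metadata.
#' @export
simulate_dose_noise <- function(img, spec) {
  assert_gray_image(img)
  stopifnot(inherits(spec, "dose_noise_spec"))
  sigma <- noise_sigma(spec)
  noise <- with_seed(spec$seed, rnorm(length(img$pixels), 0, sigma))
  px <- clip(round_half_up(img$pixels + noise), 0, 2^img$bit_depth - 1)
  gray_image(matrix(px, nrow(img$pixels), ncol(img$pixels)),
             bit_depth = img$bit_depth, spacing_mm = img$spacing_mm,
             slope = img$slope, intercept = img$intercept)
}
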