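#' Feature backend parameters
#'
#' Selects one of the four in-package binary-feature backends and its
#' detector settings. All backends share a FAST-9/16 segment-test corner
#' detector; they differ in scale handling and descriptor:
#'
#' * `"orb"` - detection on an 8-level image pyramid (factor 1.2), ranked
#'   by corner response and capped at 500 keypoints, intensity-centroid
#'   orientation, steered scale-adaptive 256-bit BRIEF-style descriptor
#'   (pattern frozen from a fixed seed).
#' * `"brisk"` - detection on three pyramid octaves (threshold 30),
#'   60-point concentric ring sampling pattern, gradient-based orientation,
#'   512-bit descriptor from the 512 shortest point pairs.
#' * `"akaze"` - detection on a three-level Gaussian scale space with an
#'   oriented MLDB-style 486-bit descriptor (intensity + derivative cell
#'   comparisons on 2x2/3x3/4x4 grids).
#' * `"ref"` - plain single-scale segment-test detector (threshold 10, the
#'   conventional default for a bare FAST detector) with an unoriented
#'   256-bit intensity-comparison descriptor; the simplest, fully
#'   brute-force verifiable backend, used as the in-repo comparison
#'   standard.
#'
#' Descriptor bit lengths are fixed per backend: ORB 256, BRISK 512,
#' AKAZE 486, REF 256.
#'
#' @param backend one of `"akaze"`, `"brisk"`, `"orb"`, `"ref"`.
#' @param max_keypoints optional cap; the strongest keypoints by detector
#'   response are kept. Defaults to 500 for `"orb"` (its conventional cap)
#'   and unlimited otherwise.
#' @param threshold FAST segment-test threshold; backend-specific default.
#' @export
backend_params <- function(backend = c("akaze", "brisk", "orb", "ref"),
                           max_keypoints = NULL, threshold = NULL) {
  backend <- match.arg(backend)
  defaults <- list(
    akaze = list(threshold = 20L, max_keypoints = NULL),
    brisk = list(threshold = 30L, max_keypoints = NULL),
    orb = list(threshold = 20L, max_keypoints = 500L),
    ref = list(threshold = 10L, max_keypoints = NULL)
  )[[backend]]
  threshold <- as.integer(threshold %||% defaults$threshold)
  if (threshold < 1) stop("`threshold` must be >= 1")
  if (is.null(max_keypoints)) max_keypoints <- defaults$max_keypoints
  if (!is.null(max_keypoints) && max_keypoints < 1) {
    stop("`max_keypoints` must be >= 1 when set")
  }
  structure(list(backend = backend, threshold = threshold,
                 max_keypoints = max_keypoints),
            class = "backend_params")
}

#' Descriptor bit length of a backend
#' @param backend backend name.
#' @export
descriptor_length <- function(backend) {
  switch(backend, orb = 256L, brisk = 512L, akaze = 486L, ref = 256L,
         stop("unknown backend `", backend, "`"))
}

# ---- frozen sampling patterns ------------------------------------------------

the <- new.env(parent = emptyenv())

# BRIEF-style point-pair pattern: n_bits x 4 integer offsets in
# [-half, half]^2, drawn from the package's own deterministic generator so
# the pattern is identical in every session.
brief_pattern <- function(seed, n_bits = 256L, half = 13L) {
  key <- sprintf("brief_%d_%d_%d", seed, n_bits, half)
  if (!is.null(the[[key]])) return(the[[key]])
  u <- lcg_uniform(4L * n_bits, seed)
  p <- matrix(floor(u * (2L * half + 1L)) - half, ncol = 4L)
  storage.mode(p) <- "integer"
  the[[key]] <- p
  p
}

# BRISK-style pattern: 60 points on concentric rings (radius, count,
# smoothing half-width), the 512 shortest point pairs as comparison bits and
# the long pairs (distance >= 13.67) for orientation.
brisk_pattern <- function() {
  if (!is.null(the$brisk)) return(the$brisk)
  rings <- data.frame(
    r = c(0, 2.9, 4.9, 7.4, 10.8),
    n = c(1L, 10L, 14L, 15L, 20L),
    hw = c(1, 1, 2, 2, 3)
  )
  pts <- do.call(rbind, lapply(seq_len(nrow(rings)), function(i) {
    k <- rings$n[i]
    ang <- 2 * pi * (seq_len(k) - 1) / k + pi / k * (i - 1)
    cbind(x = rings$r[i] * cos(ang), y = rings$r[i] * sin(ang),
          hw = rep(rings$hw[i], k))
  }))
  np <- nrow(pts)
  pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  d <- sqrt((pts[pairs[, 1], 1] - pts[pairs[, 2], 1])^2 +
            (pts[pairs[, 1], 2] - pts[pairs[, 2], 2])^2)
  ord <- order(d, pairs[, 1], pairs[, 2])
  short <- pairs[ord[1:512], , drop = FALSE] - 1L  # 0-based for C++
  long <- pairs[d >= 13.67, , drop = FALSE] - 1L
  storage.mode(short) <- "integer"
  storage.mode(long) <- "integer"
  the$brisk <- list(pts = pts, short = short, long = long)
  the$brisk
}

# ---- descriptor container ----------------------------------------------------

# bytes: packed descriptor matrix, one column per keypoint, byte count padded
# to a multiple of 8 for the word-wise matcher; L: true bit length.
descriptor_set <- function(bytes, L, backend) {
  structure(list(bytes = bytes, L = as.integer(L), backend = backend),
            class = "descriptor_set")
}

#' Number of descriptors in a descriptor set
#' @param ds a descriptor set as returned by [detect_and_describe()].
#' @export
n_descriptors <- function(ds) {
  stopifnot(inherits(ds, "descriptor_set"))
  ncol(ds$bytes)
}

#' Unpack descriptors to a logical bit matrix
#'
#' @param ds a descriptor set.
#' @return an `N x L` logical matrix (row `i` = bits of descriptor `i`).
#' @export
descriptor_bits <- function(ds) {
  stopifnot(inherits(ds, "descriptor_set"))
  n <- ncol(ds$bytes)
  out <- matrix(FALSE, n, ds$L)
  for (i in seq_len(n)) {
    out[i, ] <- as.logical(rawToBits(ds$bytes[, i]))[seq_len(ds$L)]
  }
  out
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d x %d bits, backend %s\n",
              ncol(x$bytes), x$L, x$backend))
  invisible(x)
}

# ---- detection ---------------------------------------------------------------

#' Detect keypoints and compute binary descriptors
#'
#' Runs the selected backend on an 8-bit image. Keypoints and descriptor
#' rows are index-aligned and the output is fully deterministic for a fixed
#' image and parameters. A structureless image yields an empty result (not
#' an error).
#'
#' @param img an 8-bit [gray_image()].
#' @param params a [backend_params()].
#' @return a list with `keypoints` (data frame with 0-based `x`, `y`,
#'   `scale`, `orientation` in degrees, `response`) and `descriptors`
#'   (a descriptor set; see [descriptor_bits()]).
#' @export
detect_and_describe <- function(img, params = backend_params("orb")) {
  assert_gray_image(img, bits = 8L)
  stopifnot(inherits(params, "backend_params"))
  px <- img$pixels
  storage.mode(px) <- "integer"
  res <- switch(params$backend,
    ref = detect_ref(px, params),
    orb = detect_orb(px, params),
    brisk = detect_brisk(px, params),
    akaze = detect_akaze(px, params)
  )
  if (!is.null(params$max_keypoints) && nrow(res$keypoints) > params$max_keypoints) {
    keep <- order(-res$keypoints$response, res$keypoints$y,
                  res$keypoints$x)[seq_len(params$max_keypoints)]
    res$keypoints <- res$keypoints[keep, , drop = FALSE]
    rownames(res$keypoints) <- NULL
    res$descriptors$bytes <- res$descriptors$bytes[, keep, drop = FALSE]
  }
  res
}

#' Reference backend: segment-test corners with a fixed comparison pattern
#'
#' Convenience wrapper for the `"ref"` backend of [detect_and_describe()]:
#' a FAST segment-test corner detector paired with an unoriented 256-bit
#' pairwise intensity-comparison descriptor whose sampling pattern is
#' generated once from a fixed seed and frozen. Because the descriptor uses
#' only intensity comparisons it is invariant to uniform intensity shifts.
#'
#' @inheritParams detect_and_describe
#' @export
reference_detect_describe <- function(img, params = backend_params("ref")) {
  params$backend <- "ref"
  detect_and_describe(img, params)
}

kp_frame <- function(det, scale = 1, orientation = 0) {
  data.frame(x = det$x, y = det$y, scale = rep(scale, length(det$x)),
             orientation = rep_len(orientation, length(det$x)),
             response = det$response)
}

detect_ref <- function(px, params) {
  det <- cpp_fast_detect(px, params$threshold, margin = 18L, nonmax = TRUE)
  kp <- refine_kp(px, kp_frame(det))
  pat <- brief_pattern(seed = 20201L, n_bits = 256L, half = 13L)
  bytes <- cpp_brief_describe(px, kp$x, kp$y, rep(0, nrow(kp)),
                              rep(1, nrow(kp)), pat, 2L)
  list(keypoints = kp, descriptors = descriptor_set(bytes, 256L, "ref"))
}

# Successively downsampled image pyramid. Each level is resized from the
# previous by `factor` (with optional Gaussian pre-smoothing for octave
# pyramids); levels smaller than `min_dim` are dropped. Returns the level
# images with their cumulative x/y scale relative to the base.
pyramid_levels <- function(px, factor, n_levels, pre_sigma = 0, min_dim = 64L) {
  h0 <- nrow(px); w0 <- ncol(px)
  levels <- list(list(img = px, sx = 1, sy = 1))
  cur <- px
  for (l in seq_len(n_levels - 1L)) {
    nh <- as.integer(round(nrow(cur) / factor))
    nw <- as.integer(round(ncol(cur) / factor))
    if (min(nh, nw) < min_dim) break
    src <- if (pre_sigma > 0) blur_int_matrix(cur, pre_sigma) else cur
    cur <- cpp_resize(src, nh, nw)
    levels[[length(levels) + 1L]] <- list(img = cur, sx = w0 / nw, sy = h0 / nh)
  }
  levels
}

# FAST detection on every pyramid level; keypoint coordinates are mapped to
# full resolution (pixel-center convention) and `scale` records the level's
# magnification. Coarse levels keep detection alive on smoothed or noisy
# images, as in the published multi-scale detectors.
pyramid_detect <- function(levels, threshold, margin) {
  out <- lapply(seq_along(levels), function(l) {
    lv <- levels[[l]]
    det <- cpp_fast_detect(lv$img, as.integer(threshold), margin = margin,
                           nonmax = TRUE)
    if (length(det$x) == 0) return(NULL)
    data.frame(x = (det$x + 0.5) * lv$sx - 0.5,
               y = (det$y + 0.5) * lv$sy - 0.5,
               lx = det$x, ly = det$y,
               scale = lv$sx, orientation = 0, response = det$response,
               level = l)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), lx = numeric(0),
                      ly = numeric(0), scale = numeric(0),
                      orientation = numeric(0), response = numeric(0),
                      level = integer(0)))
  }
  kp <- do.call(rbind, out)
  rownames(kp) <- NULL
  kp
}

# Distribute a total keypoint budget over pyramid levels with geometrically
# decreasing per-level quotas (proportional to level area); unused quota
# rolls over to the next level. Within a level the strongest responses win.
per_level_budget <- function(kp, total, n_levels, factor) {
  if (nrow(kp) <= total) return(kp)
  f <- 1 / factor^2
  quota <- total * (1 - f) / (1 - f^n_levels) * f^(seq_len(n_levels) - 1)
  keep <- logical(nrow(kp))
  carry <- 0
  for (l in seq_len(n_levels)) {
    idx <- which(kp$level == l)
    q <- floor(quota[l] + carry)
    if (length(idx) <= q) {
      keep[idx] <- TRUE
      carry <- quota[l] + carry - length(idx)
    } else {
      ord <- idx[order(-kp$response[idx], kp$y[idx], kp$x[idx])]
      keep[ord[seq_len(q)]] <- TRUE
      carry <- quota[l] + carry - q
    }
  }
  kp[keep, , drop = FALSE]
}

# sub-pixel corner refinement on the full-resolution image, search window
# proportional to the detection scale; descriptor sampling then stays
# centred on the same physical corner whatever pyramid level detected it
refine_kp <- function(px, kp, iters = 4L) {
  if (nrow(kp) == 0) return(kp)
  wh <- pmax(3, round(2 * kp$scale))
  q <- cpp_corner_refine(px, kp$x, kp$y, wh, iters)
  kp$x <- q$x
  kp$y <- q$y
  kp
}

# single-scale assignment: keep, per image structure, the strongest
# detection across pyramid levels (cross-scale non-maximum suppression)
scale_select <- function(kp, mult = 1.5) {
  if (nrow(kp) < 2) return(kp)
  keep <- cpp_scale_nms(kp$x, kp$y, kp$scale, kp$response, mult,
                        max(kp$scale))
  kp <- kp[keep, , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

detect_orb <- function(px, params) {
  levels <- pyramid_levels(px, factor = 1.2, n_levels = 8L)
  kp <- pyramid_detect(levels, params$threshold, margin = 22L)
  kp <- scale_select(kp)
  if (nrow(kp) > 0) {
    # rank by Harris corner response on the keypoint's level, as the
    # published detector does; segment-test responses over-rank pure noise
    for (l in unique(kp$level)) {
      idx <- which(kp$level == l)
      kp$response[idx] <- cpp_harris_response(levels[[l]]$img, kp$lx[idx],
                                              kp$ly[idx], 3L, 0.04)
    }
  }
  if (!is.null(params$max_keypoints)) {
    kp <- per_level_budget(kp, params$max_keypoints, length(levels), 1.2)
    rownames(kp) <- NULL
  }
  kp <- refine_kp(px, kp)
  if (nrow(kp) > 0) {
    # intensity-centroid orientation on the full-resolution image with the
    # disc radius scaled to the detection level (same physical support as
    # the level-image estimate, but exactly shift-covariant)
    for (s in unique(kp$scale)) {
      idx <- which(kp$scale == s)
      kp$orientation[idx] <- cpp_orientation_ic(px, kp$x[idx], kp$y[idx],
                                                as.integer(round(15 * s)))
    }
  }
  pat <- brief_pattern(seed = 1001L, n_bits = 256L, half = 13L)
  bytes <- cpp_brief_describe(px, kp$x, kp$y, kp$orientation, kp$scale, pat, 2L)
  kp$level <- NULL
  kp$lx <- NULL
  kp$ly <- NULL
  list(keypoints = kp, descriptors = descriptor_set(bytes, 256L, "orb"))
}

detect_brisk <- function(px, params) {
  levels <- pyramid_levels(px, factor = 2, n_levels = 3L, pre_sigma = 1.4)
  kp <- pyramid_detect(levels, params$threshold, margin = 16L)
  kp <- scale_select(kp)
  kp <- refine_kp(px, kp)
  pat <- brisk_pattern()
  bytes <- cpp_brisk_describe(px, kp$x, kp$y, kp$scale, pat$pts,
                              pat$short, pat$long)
  kp$level <- NULL
  kp$lx <- NULL
  kp$ly <- NULL
  list(keypoints = kp, descriptors = descriptor_set(bytes, 512L, "brisk"))
}

detect_akaze <- function(px, params) {
  levels <- pyramid_levels(px, factor = 2, n_levels = 4L, pre_sigma = 1.4)
  kp <- pyramid_detect(levels, params$threshold, margin = 20L)
  kp <- scale_select(kp)
  kp <- refine_kp(px, kp)
  # orientation and descriptor sample the full-resolution image with the
  # pattern, smoothing and derivative step scaled per keypoint, so sampling
  # follows the refined position exactly whatever octave detected it
  bytes <- matrix(raw(0), nrow = 64L, ncol = 0L)
  if (nrow(kp) > 0) {
    bytes <- matrix(as.raw(0), nrow = 64L, ncol = nrow(kp))
    for (s in unique(kp$scale)) {
      idx <- which(kp$scale == s)
      ori <- cpp_orientation_ic(px, kp$x[idx], kp$y[idx],
                                as.integer(round(6 * s)))
      kp$orientation[idx] <- ori
      bytes[, idx] <- cpp_mldb_describe(px, kp$x[idx], kp$y[idx], ori, s, 12L)
    }
  }
  kp$level <- NULL
  kp$lx <- NULL
  kp$ly <- NULL
  list(keypoints = kp, descriptors = descriptor_set(bytes, 486L, "akaze"))
}

# integer-valued Gaussian smoothing used to build the akaze scale space
blur_int_matrix <- function(px, sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  out <- convolve_separable(px, gaussian_kernel(k, sigma))
  out <- round_half_up(out)
  storage.mode(out) <- "integer"
  out
}
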