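#' Hamming distance between two binary descriptors
#'
#' Counts differing bits. Accepts raw vectors (packed bits) or logical /
#' 0-1 numeric vectors of equal length.
#'
#' @param a,b two descriptors of equal bit length.
#' @return integer number of differing bits.
#' @export
hamming <- function(a, b) {
  if (is.raw(a) && is.raw(b)) {
    return(cpp_hamming_raw(a, b))
  }
  if (length(a) != length(b)) stop("descriptors must have equal bit length")
  sum(as.logical(a) != as.logical(b))
}

match_set <- function(pairs, L, backend, n_ref, n_tgt) {
  structure(list(pairs = pairs, N = nrow(pairs), L = as.integer(L),
                 backend = backend, n_ref = n_ref, n_tgt = n_tgt),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %d pairs (%d vs %d keypoints), backend %s, L = %d\n",
              x$N, x$n_ref, x$n_tgt, x$backend, x$L))
  invisible(x)
}

#' Brute-force descriptor matching with mutual cross-check
#'
#' For every reference descriptor the nearest target descriptor by Hamming
#' distance is found by exhaustive search; a pair is kept only when the
#' nearest-neighbour relation holds in both directions, which enforces a
#' one-to-one correspondence. Ties in distance are broken toward the lowest
#' index, making the result deterministic. No ratio test and no distance
#' cutoff are applied.
#'
#' @param ref,tgt descriptor sets from [detect_and_describe()] computed with
#'   the same backend.
#' @return a `match_set` whose `pairs` data frame holds 1-based `ref_index`,
#'   `tgt_index` and the Hamming `distance` per matched pair.
#' @export
brute_force_match <- function(ref, tgt) {
  stopifnot(inherits(ref, "descriptor_set"), inherits(tgt, "descriptor_set"))
  if (!identical(ref$backend, tgt$backend) || ref$L != tgt$L) {
    stop("descriptor sets come from different backends (",
         ref$backend, " vs ", tgt$backend, ")")
  }
  res <- cpp_bf_match(ref$bytes, tgt$bytes)
  pairs <- data.frame(ref_index = res$ref_index, tgt_index = res$tgt_index,
                      distance = res$distance)
  match_set(pairs, L = ref$L, backend = ref$backend,
            n_ref = ncol(ref$bytes), n_tgt = ncol(tgt$bytes))
}

#' The keypoint-feature quality index
#'
#' The mean Hamming distance over all matched keypoint pairs, in raw bits.
#' 0 means every matched feature is bit-identical (the target equals the
#' reference); larger values indicate degraded image quality. The value is
#' bounded by the descriptor bit length `L`; a normalized value / L is also
#' reported for cross-backend comparison but the index itself is the raw
#' mean, which is what validation against SSIM uses.
#'
#' An empty match set has no defined index: that is an error carrying both
#' keypoint counts, never a silent 0 or NaN.
#'
#' @param matches a `match_set` from [brute_force_match()].
#' @return an object of class `pi_value` with fields `value` (mean Hamming
#'   distance in bits), `n` (pairs used), `backend`, `L`, `normalized`.
#' @export
proposed_index <- function(matches) {
  stopifnot(inherits(matches, "match_set"))
  if (matches$N < 1) {
    stop(sprintf(paste0("quality index undefined: no keypoint matches ",
                        "(%d reference vs %d target keypoints, backend %s)"),
                 matches$n_ref, matches$n_tgt, matches$backend))
  }
  value <- mean(matches$pairs$distance)
  structure(list(value = value, n = matches$N, backend = matches$backend,
                 L = matches$L, normalized = value / matches$L),
            class = "pi_value")
}

#' @export
print.pi_value <- function(x, ...) {
  cat(sprintf("quality index (mean Hamming distance): %.4g bits over %d pairs [%s, L = %d]\n",
              x$value, x$n, x$backend, x$L))
  invisible(x)
}

#' Score a target image against a reference in one call
#'
#' Detects, matches and averages: the full measurement pipeline for one
#' backend, optionally with SSIM/PSNR computed on the same image pair.
#'
#' @param ref,tgt 8-bit [gray_image()]s of equal size.
#' @param params a [backend_params()].
#' @param with_ssim,with_psnr include the conventional metrics in the result.
#' @return a list with `pi` (a `pi_value`), the two keypoint/descriptor
#'   results, `matches`, and optionally `ssim` and `psnr`.
#' @export
score_pair <- function(ref, tgt, params = backend_params("orb"),
                       with_ssim = FALSE, with_psnr = FALSE) {
  fr <- detect_and_describe(ref, params)
  ft <- detect_and_describe(tgt, params)
  m <- brute_force_match(fr$descriptors, ft$descriptors)
  out <- list(pi = proposed_index(m), ref_features = fr, tgt_features = ft,
              matches = m)
  if (with_ssim) out$ssim <- ssim(ref, tgt)
  if (with_psnr) out$psnr <- psnr(ref, tgt)
  out
}
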