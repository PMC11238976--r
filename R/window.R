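#' Display window specification
#'
#' A linear intensity window in physical units (Hounsfield units for CT):
#' values in `[center - width/2, center + width/2]` are mapped onto
#' `[0, 255]` by [to_eight_bit()], values outside are clipped.
#'
#' @param center window center (HU for CT images).
#' @param width window width, `> 0`.
#' @export
window_spec <- function(center, width) {
  if (!is.numeric(width) || width <= 0) stop("window `width` must be > 0")
  structure(list(center = center, width = width), class = "window_spec")
}

#' Default brain display window (center 40 HU, width 80 HU)
#' @export
brain_window <- function() window_spec(center = 40, width = 80)

#' Convert an image to the 8-bit domain used by the feature backends
#'
#' Linearly maps the window interval onto `[0, 255]` with round-half-up and
#' clipping; the window is expressed in the image's physical units (so HU for
#' DICOM/CT images carrying a rescale). With `window = NULL`, 8-bit input is
#' returned unchanged, CT-like input (non-trivial rescale) gets the
#' conventional brain window (center 40, width 80 HU), and other 16-bit
#' input is min-max scaled. The map is monotone non-decreasing.
#'
#' @param img a [gray_image()].
#' @param window a [window_spec()] or `NULL` for the defaults above.
#' @return an 8-bit [gray_image()].
#' @export
to_eight_bit <- function(img, window = NULL) {
  assert_gray_image(img)
  if (is.null(window)) {
    if (img$bit_depth == 8L) return(img)
    if (img$slope != 1 || img$intercept != 0) {
      window <- brain_window()
    } else {
      lo <- min(img$pixels)
      hi <- max(img$pixels)
      if (hi == lo) hi <- lo + 1
      window <- window_spec(center = (lo + hi) / 2, width = hi - lo)
    }
  }
  stopifnot(inherits(window, "window_spec"))
  phys <- as_hu(img)
  low <- window$center - window$width / 2
  v <- (phys - low) / window$width * 255
  px <- clip(round_half_up(v), 0, 255)
  gray_image(px, bit_depth = 8L, spacing_mm = img$spacing_mm)
}
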