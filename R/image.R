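#' Grayscale image container
#'
#' The unit every metric in the package consumes: a 2-D intensity raster with
#' its bit depth and optional physical metadata. Pixels are stored in a
#' numeric matrix indexed `[row, col]` with the origin at the top-left; in
#' keypoint coordinates `x` is the 0-based column and `y` the 0-based row.
#' Stored intensities are non-negative integers within `[0, 2^bit_depth - 1]`.
#' CT images additionally carry a linear rescale (`slope`, `intercept`) so
#' that Hounsfield units are `slope * stored + intercept`; see [as_hu()].
#'
#' @param pixels numeric matrix of stored intensity values.
#' @param bit_depth integer, 8 or 16.
#' @param spacing_mm optional numeric pair, physical pixel spacing (row, col).
#' @param slope,intercept linear rescale mapping stored values to physical
#'   units (defaults 1 and 0, i.e. stored values are the physical values).
#' @return an object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:254, 15, 17), bit_depth = 8)
#' dim(img)
#' @export
gray_image <- function(pixels, bit_depth = 8L, spacing_mm = NULL,
                       slope = 1, intercept = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must be at least 1x1")
  mx <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > mx)) {
    stop("intensities must lie within [0, 2^bit_depth - 1]")
  }
  if (!is.null(spacing_mm)) {
    spacing_mm <- as.numeric(spacing_mm)
    if (length(spacing_mm) != 2 || any(spacing_mm <= 0)) {
      stop("`spacing_mm` must be a positive (row, col) pair")
    }
  }
  # normalize storage: plain double matrix without carried-over attributes
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  structure(
    list(pixels = pixels, bit_depth = bit_depth, spacing_mm = spacing_mm,
         slope = slope, intercept = intercept),
    class = "gray_image"
  )
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit", nrow(x$pixels), ncol(x$pixels),
              x$bit_depth))
  if (!is.null(x$spacing_mm)) {
    cat(sprintf(", spacing %.4g x %.4g mm", x$spacing_mm[1], x$spacing_mm[2]))
  }
  if (x$slope != 1 || x$intercept != 0) {
    cat(sprintf(", rescale %g * stored + %g", x$slope, x$intercept))
  }
  cat("\n")
  invisible(x)
}

#' Rescaled intensity values (Hounsfield units for CT)
#'
#' Applies the image's linear rescale, `slope * stored + intercept`. For a
#' DICOM CT slice this yields Hounsfield units; for plain raster images it is
#' the identity.
#'
#' @param img a [gray_image()].
#' @return numeric matrix of rescaled values.
#' @export
as_hu <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  img$slope * img$pixels + img$intercept
}

assert_gray_image <- function(img, bits = NULL) {
  if (!inherits(img, "gray_image")) stop("expected a `gray_image`")
  if (!is.null(bits) && img$bit_depth != bits) {
    stop(sprintf("expected a %d-bit image, got %d-bit", bits, img$bit_depth))
  }
  invisible(img)
}
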