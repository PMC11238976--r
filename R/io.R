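#' Read a grayscale image file
#'
#' Reads single-frame DICOM (uncompressed, MONOCHROME2), PNG or TIFF
#' (8/16-bit grayscale) into a [gray_image()]. DICOM rescale slope/intercept
#' and pixel spacing are carried on the returned object, so [as_hu()] gives
#' Hounsfield units. Color inputs are rejected.
#'
#' @param path file path; format is detected from the DICM magic bytes or the
#'   file extension (`.dcm`, `.png`, `.tif`/`.tiff`).
#' @return a [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read `", path, "`: file does not exist")
  if (is_dicom_file(path)) return(read_dicom(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(read_png_gray(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff_gray(path))
  stop("unsupported image format: `", path, "`")
}

#' Write a grayscale image file
#'
#' PNG output supports 8-bit images; TIFF output supports 8- and 16-bit.
#' Round trips through [read_image()] are bit-exact.
#'
#' @param img a [gray_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  mx <- 2^img$bit_depth - 1
  if (ext == "png") {
    if (img$bit_depth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit images")
    png::writePNG(img$pixels / mx, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img$pixels / mx, path, bits.per.sample = img$bit_depth,
                    compression = "none")
  } else {
    stop("unsupported output format: `", path, "`")
  }
  invisible(path)
}

read_png_gray <- function(path) {
  px <- png::readPNG(path, info = TRUE)
  info <- attr(px, "info")
  bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  if (bits < 8L) bits <- 8L
  px <- drop_gray_alpha(px, path)
  gray_image(round(px * (2^bits - 1)), bit_depth = bits)
}

read_tiff_gray <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  info <- attributes(px)
  bits <- as.integer(info$bits.per.sample %||% 8L)
  px <- drop_gray_alpha(px, path)
  gray_image(px, bit_depth = bits)
}

# accept pure grayscale (matrix) or gray+alpha with opaque alpha; reject color
drop_gray_alpha <- function(px, path) {
  if (is.matrix(px)) return(px)
  if (length(dim(px)) == 3 && dim(px)[3] == 2) return(px[, , 1])
  stop("color images are not supported: `", path, "`")
}
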