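# Minimal single-frame DICOM reader.
#
# Supports uncompressed little-endian transfer syntaxes (implicit and
# explicit VR), unsigned MONOCHROME2 pixel data, 8 or 16 bits allocated.
# This covers single-slice CT exports; everything else (multi-frame, color,
# signed, compressed, big-endian) is rejected with an unsupported-format
# error. Only the tags the package needs are interpreted.

is_dicom_file <- function(path) {
  if (tolower(tools::file_ext(path)) == "dcm") return(TRUE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 132) return(FALSE)
  hdr <- readBin(path, "raw", n = 132)
  identical(hdr[129:132], charToRaw("DICM"))
}

read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140) stop("unreadable DICOM file: `", path, "`")
  pos <- 1L
  if (identical(raw[129:132], charToRaw("DICM"))) pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) {
    as.double(raw[i]) + 256 * as.double(raw[i + 1L]) +
      65536 * as.double(raw[i + 2L]) + 16777216 * as.double(raw[i + 3L])
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  explicit_meta <- TRUE
  explicit_data <- TRUE
  transfer <- "1.2.840.10008.1.2.1"
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos)
    elem <- u16(pos + 2L)
    in_meta <- group == 2L
    explicit <- if (in_meta) explicit_meta else explicit_data
    # sniff: two uppercase letters where the VR would sit
    vr_bytes <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    looks_explicit <- grepl("^[A-Z][A-Z]$", vr_bytes)
    if (explicit && !looks_explicit) explicit <- FALSE
    if (explicit) {
      vr <- vr_bytes
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L)
        data_at <- pos + 12L
      } else {
        len <- u16(pos + 6L)
        data_at <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L)
      data_at <- pos + 8L
    }
    if (len == 4294967295) {
      stop("unsupported DICOM file (undefined-length element): `", path, "`")
    }
    if (data_at + len - 1L > n) stop("unreadable DICOM file (truncated): `", path, "`")
    key <- sprintf("%04x,%04x", group, elem)
    val_raw <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    if (key %in% c("0002,0010", "0008,0060", "0028,0004")) {
      tags[[key]] <- trimws(rawToChar(val_raw))
    } else if (key == "0028,0008") {
      # NumberOfFrames has VR IS (text) in both implicit and explicit syntaxes
      tags[[key]] <- as.numeric(trimws(rawToChar(val_raw)))
    } else if (key %in% c("0028,0002", "0028,0010", "0028,0011",
                          "0028,0100", "0028,0103")) {
      tags[[key]] <- u16(data_at)
    } else if (key %in% c("0028,1052", "0028,1053", "0028,0030")) {
      parts <- strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]
      tags[[key]] <- as.numeric(parts)
    } else if (key == "7fe0,0010") {
      tags[["pixel_data"]] <- val_raw
    }
    if (key == "0002,0010") {
      transfer <- tags[[key]]
      if (transfer == "1.2.840.10008.1.2") {
        explicit_data <- FALSE
      } else if (transfer != "1.2.840.10008.1.2.1") {
        stop("unsupported DICOM transfer syntax `", transfer, "`: `", path, "`")
      }
    }
    pos <- data_at + as.integer(len)
  }
  rows <- tags[["0028,0010"]]
  cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]] %||% 16L
  if (is.null(rows) || is.null(cols) || is.null(tags$pixel_data)) {
    stop("unreadable DICOM file (missing image tags): `", path, "`")
  }
  if ((tags[["0028,0002"]] %||% 1) != 1) {
    stop("unsupported DICOM file (color / multi-sample): `", path, "`")
  }
  if ((tags[["0028,0008"]] %||% 1) != 1) {
    stop("unsupported DICOM file (multi-frame): `", path, "`")
  }
  pi <- tags[["0028,0004"]] %||% "MONOCHROME2"
  if (!identical(pi, "MONOCHROME2")) {
    stop("unsupported DICOM photometric interpretation `", pi, "`")
  }
  if ((tags[["0028,0103"]] %||% 0) != 0) {
    stop("unsupported DICOM file (signed pixel data)")
  }
  if (!bits %in% c(8, 16)) stop("unsupported DICOM bit depth ", bits)
  nbytes <- bits / 8
  npix <- rows * cols
  if (length(tags$pixel_data) < npix * nbytes) {
    stop("unreadable DICOM file (pixel data too short; compressed?)")
  }
  v <- readBin(tags$pixel_data, "integer", n = npix, size = nbytes,
               signed = FALSE, endian = "little")
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  gray_image(px, bit_depth = as.integer(bits),
             spacing_mm = tags[["0028,0030"]],
             slope = (tags[["0028,1053"]] %||% 1),
             intercept = (tags[["0028,1052"]] %||% 0))
}
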