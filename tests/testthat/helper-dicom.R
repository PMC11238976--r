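# minimal single-frame DICOM writer (explicit VR little endian), used only
# to build test fixtures in code

write_minimal_dicom <- function(path, pixels, slope = 1, intercept = -1024,
                                spacing = c(0.5, 0.5), photometric = "MONOCHROME2",
                                frames = NULL) {
  u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  pad_even <- function(s, pad = " ") {
    if (nchar(s) %% 2 == 1) paste0(s, pad) else s
  }
  elem_str <- function(group, el, vr, value, pad = " ") {
    value <- pad_even(value, pad)
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(nchar(value))
    writeChar(value, con, eos = NULL)
  }
  elem_us <- function(group, el, value) {
    u16(group); u16(el); writeChar("US", con, eos = NULL); u16(2L); u16(value)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta group with its group length
  ts <- pad_even("1.2.840.10008.1.2.1", " ")
  meta_len <- 8L + nchar(ts)
  u16(0x0002); u16(0x0000); writeChar("UL", con, eos = NULL); u16(4L)
  u32(meta_len)
  elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1", " ")

  elem_str(0x0008, 0x0060, "CS", "CT")
  elem_us(0x0028, 0x0002, 1L)
  elem_str(0x0028, 0x0004, "CS", photometric)
  if (!is.null(frames)) elem_str(0x0028, 0x0008, "IS", as.character(frames))
  elem_us(0x0028, 0x0010, nrow(pixels))
  elem_us(0x0028, 0x0011, ncol(pixels))
  elem_str(0x0028, 0x0030, "DS", paste(spacing, collapse = "\\"))
  elem_us(0x0028, 0x0100, 16L)
  elem_us(0x0028, 0x0103, 0L)
  elem_str(0x0028, 0x1052, "DS", as.character(intercept))
  elem_str(0x0028, 0x1053, "DS", as.character(slope))
  # PixelData, OW with 4-byte length (row-major)
  v <- as.integer(t(pixels))
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0L)
  u32(length(v) * 2L)
  writeBin(v, con, size = 2, endian = "little")
  invisible(path)
}
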