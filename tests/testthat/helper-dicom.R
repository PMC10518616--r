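# Synthetic single-frame DICOM writer (explicit VR little endian) used as
# the read_dicom_slice test fixture. Bytes are assembled by hand so the
# reader is tested against the wire format, not against itself.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

pad_even <- function(r, pad = as.raw(0)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

dicom_element <- function(group, elem, vr, value) {
  value <- pad_even(value, if (vr %in% c("UI", "OB")) as.raw(0)
                    else charToRaw(" "))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(u16le(group), u16le(elem), charToRaw(vr), as.raw(c(0, 0)),
      u32le(length(value)), value)
  } else {
    c(u16le(group), u16le(elem), charToRaw(vr), u16le(length(value)), value)
  }
}

write_test_dicom <- function(path, stored, slope = 1, intercept = -1024,
                             signed = FALSE, spacing = c(0.7, 0.7),
                             frames = 1L, samples_per_pixel = 1L,
                             photometric = "MONOCHROME2",
                             omit_pixeldata = FALSE,
                             transfer_syntax = "1.2.840.10008.1.2.1") {
  rows <- nrow(stored); cols <- ncol(stored)
  pix <- writeBin(as.integer(as.vector(t(stored))), raw(), size = 2L,
                  endian = "little")
  body <- c(
    dicom_element(0x0002, 0x0010, "UI", charToRaw(transfer_syntax)),
    dicom_element(0x0008, 0x0060, "CS", charToRaw("CT")),
    dicom_element(0x0028, 0x0002, "US", u16le(samples_per_pixel)),
    dicom_element(0x0028, 0x0004, "CS", charToRaw(photometric)),
    if (frames != 1L)
      dicom_element(0x0028, 0x0008, "IS", charToRaw(as.character(frames))),
    dicom_element(0x0028, 0x0010, "US", u16le(rows)),
    dicom_element(0x0028, 0x0011, "US", u16le(cols)),
    if (!is.null(spacing))
      dicom_element(0x0028, 0x0030, "DS",
                    charToRaw(paste(spacing, collapse = "\\"))),
    dicom_element(0x0028, 0x0100, "US", u16le(16)),
    dicom_element(0x0028, 0x0103, "US", u16le(as.integer(signed))),
    dicom_element(0x0028, 0x1052, "DS", charToRaw(as.character(intercept))),
    dicom_element(0x0028, 0x1053, "DS", charToRaw(as.character(slope))),
    if (!omit_pixeldata) dicom_element(0x7fe0, 0x0010, "OW", pix))
  writeBin(c(as.raw(rep(0, 128)), charToRaw("DICM"), body), path)
  invisible(path)
}
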