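# Minimal DICOM writer for test fixtures only: one explicit- or
# implicit-VR little-endian CT slice per file, 16-bit signed pixels.

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                   endian = "little")

dcm_pad <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2 == 1) v <- c(v, pad)
  v
}

dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  if (is.character(value)) {
    value <- charToRaw(value)
    value <- dcm_pad(value, if (vr == "UI") as.raw(0) else as.raw(0x20))
  }
  stopifnot(is.raw(value), length(value) %% 2 == 0)
  head <- c(dcm_uint16(group), dcm_uint16(elem))
  if (explicit) {
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
      c(head, charToRaw(vr), as.raw(c(0, 0)), dcm_uint32(length(value)), value)
    else
      c(head, charToRaw(vr), dcm_uint16(length(value)), value)
  } else {
    c(head, dcm_uint32(length(value)), value)
  }
}

# hu: matrix [x, y]; stored pixel = round((hu - intercept) / slope), int16
write_test_dicom_slice <- function(path, hu, ipp, pixel_spacing = c(0.5, 0.5),
                                   series_uid = "1.2.3.4", frame_uid = "1.2.3.9",
                                   slope = 1, intercept = -1024,
                                   explicit = TRUE, drop_rescale = FALSE) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- dcm_element(0x0002, 0x0010, "UI", ts, explicit = TRUE)
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta)),
                        explicit = TRUE), meta)
  cols <- nrow(hu); rows <- ncol(hu)   # x = columns, y = rows
  # row-major pixel data: x varies fastest, which for an [x, y] matrix is
  # plain column-major vectorization
  stored <- as.integer(round((as.vector(hu) - intercept) / slope))
  px <- writeBin(stored, raw(), size = 2, endian = "little")
  ds <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                          collapse = "\\")
  body <- c(
    dcm_element(0x0020, 0x000E, "UI", series_uid, explicit),
    dcm_element(0x0020, 0x0032, "DS", ds(ipp), explicit),
    dcm_element(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0)), explicit),
    dcm_element(0x0020, 0x0052, "UI", frame_uid, explicit),
    dcm_element(0x0028, 0x0010, "US", dcm_uint16(rows), explicit),
    dcm_element(0x0028, 0x0011, "US", dcm_uint16(cols), explicit),
    dcm_element(0x0028, 0x0030, "DS",
                ds(c(pixel_spacing[2], pixel_spacing[1])), explicit),
    dcm_element(0x0028, 0x0100, "US", dcm_uint16(16), explicit),
    dcm_element(0x0028, 0x0103, "US", dcm_uint16(1), explicit)
  )
  if (!drop_rescale)
    body <- c(body,
              dcm_element(0x0028, 0x1052, "DS", ds(intercept), explicit),
              dcm_element(0x0028, 0x1053, "DS", ds(slope), explicit))
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", px, explicit))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# write every z-slice of a ct_volume as one DICOM file, shuffled filenames
write_test_dicom_series <- function(ct, dir, explicit = TRUE,
                                    series_uid = "1.2.3.4",
                                    reverse_names = FALSE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(ct$voxels)[3]
  name_idx <- if (reverse_names) rev(seq_len(nz)) else seq_len(nz)
  for (k in seq_len(nz)) {
    ipp <- c(ct$origin[1], ct$origin[2],
             ct$origin[3] + (k - 1) * ct$spacing[3])
    write_test_dicom_slice(
      file.path(dir, sprintf("slice%03d.dcm", name_idx[k])),
      hu = ct$voxels[, , k], ipp = ipp,
      pixel_spacing = ct$spacing[1:2], series_uid = series_uid,
      explicit = explicit, ...)
  }
  invisible(dir)
}
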