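# Hand-written NIfTI-1 file with explicit scl_slope / scl_inter fields and
# int16 data, to exercise reader-side calibration against a file this
# package did not write.

write_raw_nifti_int16 <- function(path, arr, pixdim = c(0.5, 0.5, 0.5),
                                  scl_slope = 1, scl_inter = 0) {
  dm <- dim(arr)
  stopifnot(length(dm) == 3)
  hdr <- raw(348)
  put_i32 <- function(h, off, x) {
    h[(off + 1):(off + 4)] <- writeBin(as.integer(x), raw(), size = 4,
                                       endian = "little"); h
  }
  put_i16 <- function(h, off, x) {
    n <- length(x)
    h[(off + 1):(off + 2 * n)] <- writeBin(as.integer(x), raw(), size = 2,
                                           endian = "little"); h
  }
  put_f32 <- function(h, off, x) {
    n <- length(x)
    h[(off + 1):(off + 4 * n)] <- writeBin(as.numeric(x), raw(), size = 4,
                                           endian = "little"); h
  }
  hdr <- put_i32(hdr, 0, 348L)
  hdr <- put_i16(hdr, 40, c(3L, dm, 1L, 1L, 1L, 1L))    # dim[8]
  hdr <- put_i16(hdr, 70, 4L)                           # datatype int16
  hdr <- put_i16(hdr, 72, 16L)                          # bitpix
  hdr <- put_f32(hdr, 76, c(1, pixdim, 1, 1, 1, 1))     # pixdim[8]
  hdr <- put_f32(hdr, 108, 352)                         # vox_offset
  hdr <- put_f32(hdr, 112, scl_slope)
  hdr <- put_f32(hdr, 116, scl_inter)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))        # magic
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                                 # extension flag
  writeBin(as.integer(arr), con, size = 2, endian = "little")
  invisible(path)
}
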