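# Minimal DICOM series reader: uncompressed 16-bit CT slices, explicit or
# implicit VR little endian. Only the tags needed to assemble a calibrated
# HU volume are interpreted; everything else is skipped by length.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

# tags we interpret, keyed "GGGGEEEE" (upper-case hex)
DICOM_TAGS <- c(
  series_uid   = "0020000E",
  frame_of_ref = "00200052",
  ipp          = "00200032",
  iop          = "00200037",
  rows         = "00280010",
  cols         = "00280011",
  pixel_spacing = "00280030",
  bits_allocated = "00280100",
  pixel_representation = "00280103",
  rescale_intercept = "00281052",
  rescale_slope = "00281053",
  pixel_data   = "7FE00010"
)

read_uint16 <- function(raw2) readBin(raw2, "integer", size = 2,
                                      signed = FALSE, endian = "little")
read_uint32 <- function(raw4) {
  v <- readBin(raw4, "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# parse one DICOM file into a list of raw values keyed by tag
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 136 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  pos <- 133L
  elems <- list()
  transfer_syntax <- TS_EXPLICIT_LE
  explicit <- TRUE
  in_meta <- TRUE
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n + 1L && pos <= n) {
    group <- read_uint16(bytes[pos:(pos + 1L)])
    elem <- read_uint16(bytes[(pos + 2L):(pos + 3L)])
    if (in_meta && group != 0x0002L) {
      in_meta <- FALSE
      explicit <- transfer_syntax != TS_IMPLICIT_LE
      if (!transfer_syntax %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax ", transfer_syntax,
             " in ", path)
    }
    use_explicit <- in_meta || explicit   # file meta is always explicit VR
    if (use_explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- read_uint32(bytes[(pos + 8L):(pos + 11L)])
        hdr_len <- 12L
      } else {
        len <- read_uint16(bytes[(pos + 6L):(pos + 7L)])
        hdr_len <- 8L
      }
    } else {
      len <- read_uint32(bytes[(pos + 4L):(pos + 7L)])
      hdr_len <- 8L
    }
    if (len == 2^32 - 1)
      stop("undefined-length sequences are not supported (tag ",
           sprintf("%04X,%04X", group, elem), ") in ", path)
    key <- sprintf("%04X%04X", group, elem)
    val_start <- pos + hdr_len
    if (len > 0 && val_start + len - 1L > n)
      stop("truncated DICOM element ", key, " in ", path)
    if (key %in% DICOM_TAGS || key == "00020010")
      elems[[key]] <- if (len > 0) bytes[val_start:(val_start + len - 1L)]
                      else raw(0)
    if (key == "00020010")
      transfer_syntax <- raw_to_string(elems[[key]])
    pos <- val_start + len
  }
  elems$.transfer_syntax <- transfer_syntax
  elems
}

# strings are space- or NUL-padded to even length
raw_to_string <- function(v) trimws(rawToChar(v[v != as.raw(0)]))

dicom_string <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  raw_to_string(v)
}

dicom_numeric <- function(elems, key) {
  s <- dicom_string(elems, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16_value <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  read_uint16(v[1:2])
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, parse_dicom_file)

  uids <- vapply(slices, function(e) dicom_string(e, DICOM_TAGS["series_uid"]) %||% "",
                 character(1))
  if (length(unique(uids)) > 1L)
    stop("directory mixes multiple DICOM series: SeriesInstanceUIDs ",
         paste(unique(uids), collapse = ", "))
  fors <- unique(vapply(slices, function(e)
    dicom_string(e, DICOM_TAGS["frame_of_ref"]) %||% "", character(1)))
  fors <- fors[fors != ""]
  if (length(fors) > 1L)
    stop("DICOM series spans multiple frames of reference: ",
         paste(fors, collapse = ", "))

  first <- slices[[1]]
  rows <- dicom_uint16_value(first, DICOM_TAGS["rows"])
  cols <- dicom_uint16_value(first, DICOM_TAGS["cols"])
  if (is.null(rows) || is.null(cols))
    stop("DICOM slices lack Rows/Columns")
  ps <- dicom_numeric(first, DICOM_TAGS["pixel_spacing"])
  if (is.null(ps) || length(ps) != 2L)
    stop("DICOM slices lack PixelSpacing")
  iop <- dicom_numeric(first, DICOM_TAGS["iop"]) %||% c(1, 0, 0, 0, 1, 0)
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  ipps <- lapply(slices, function(e) dicom_numeric(e, DICOM_TAGS["ipp"]))
  if (any(vapply(ipps, is.null, logical(1))))
    stop("DICOM slices lack ImagePositionPatient; cannot order spatially")
  zpos <- vapply(ipps, function(p) sum(p * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; ipps <- ipps[ord]; zpos <- zpos[ord]

  nz <- length(slices)
  slice_spacing <- if (nz > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0)) stop("duplicate or non-monotone DICOM slice positions")
    if (max(dz) - min(dz) > 1e-3)
      warning("non-uniform DICOM slice spacing; using the mean")
    mean(dz)
  } else ps[1]

  vol <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    e <- slices[[k]]
    slope <- dicom_numeric(e, DICOM_TAGS["rescale_slope"])
    inter <- dicom_numeric(e, DICOM_TAGS["rescale_intercept"])
    if (is.null(slope) || is.null(inter))
      stop("DICOM slice missing RescaleSlope/RescaleIntercept; ",
           "refusing to assume an identity rescale")
    bits <- dicom_uint16_value(e, DICOM_TAGS["bits_allocated"]) %||% 16L
    if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
    signed <- (dicom_uint16_value(e, DICOM_TAGS["pixel_representation"]) %||% 0L) == 1L
    px <- e[[DICOM_TAGS["pixel_data"]]]
    if (is.null(px)) stop("DICOM slice has no PixelData")
    vals <- readBin(px, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
    # pixel data is row-major (columns vary fastest), so filling a
    # cols x rows matrix column-by-column puts x fastest
    vol[, , k] <- matrix(vals, nrow = cols, ncol = rows) * slope + inter
  }
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  spacing <- c(ps[2], ps[1], slice_spacing)
  ct <- ct_volume(vol, spacing = spacing, origin = ipps[[1]])
  ct$orientation <- iop
  ct
}

`%||%` <- function(a, b) if (is.null(a)) b else a
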