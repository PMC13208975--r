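#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' Returns a HU-calibrated [ct_volume()]. For NIfTI, any scl slope/intercept
#' in the header is applied on read (the NIfTI convention that a zero slope
#' means "no scaling" is honoured). For DICOM, the series must share one
#' SeriesInstanceUID and frame of reference; slices are ordered by their
#' spatial position along the slice normal (never by filename), and
#' RescaleSlope/RescaleIntercept must both be present — they are never
#' silently assumed.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or `"dicom"`.
#' @return a [ct_volume()].
#' @export
read_ct <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (!file.exists(path) && !dir.exists(path))
    stop("path does not exist: ", path)
  switch(format,
         nifti = read_ct_nifti(path),
         dicom = read_dicom_series(path))
}

read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)     # scl slope/intercept applied on read
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    dm <- dim(img)
  }
  if (length(dm) != 3L)
    stop("expected a 3-D scalar NIfTI volume, got ", length(dm),
         " dimensions (", paste(dm, collapse = "x"), ")")
  hdr <- RNifti::niftiHeader(path)
  spacing <- abs(hdr$pixdim[2:4])
  origin <- nifti_world_origin(hdr)
  ct_volume(img[, , , drop = FALSE] * 1.0, spacing = spacing, origin = origin)
}

# translation part of the sform/qform, falling back to zero when neither is set
nifti_world_origin <- function(hdr) {
  if (hdr$sform_code > 0)
    return(c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4]))
  if (hdr$qform_code > 0)
    return(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  c(0, 0, 0)
}

#' Read a binary volume-of-interest mask
#'
#' Nonzero voxels become foreground. The mask grid must match the reference
#' CT; an all-zero mask is returned with its empty flag set (a warning is
#' raised here, an error only at scoring time).
#'
#' @param path NIfTI mask file.
#' @param reference the companion [ct_volume()].
#' @return a [voi_mask()].
#' @export
read_mask <- function(path, reference) {
  if (!inherits(reference, "ct_volume"))
    stop("'reference' must be a ct_volume")
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    dm <- dim(img)
  }
  if (!identical(dm, dim(reference$voxels)))
    stop(sprintf("mask shape (%s) does not match CT shape (%s): %s",
                 paste(dm, collapse = ","),
                 paste(dim(reference$voxels), collapse = ","), path))
  m <- voi_mask(array(as.vector(img) != 0, dm), reference = reference)
  if (attr(m, "empty"))
    warning("mask has no foreground voxels: ", path)
  m
}

#' Write a NIfTI volume
#'
#' Writes a [ct_volume()], [voi_mask()] or plain 3-D array as float64
#' NIfTI-1 (so write/read round trips are the identity on voxel data) with
#' the grid spacing and world origin in the header.
#'
#' @param x object to write.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels; spacing <- x$spacing; origin <- x$origin
  } else if (inherits(x, "voi_mask")) {
    spacing <- attr(x, "spacing"); origin <- attr(x, "origin")
    arr <- array(as.double(x), dim(x))
  } else {
    arr <- x; spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  }
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

SCHEMA_VERSION <- "1.0"

#' Flatten a result object to a serializable named list
#'
#' Every volume field is emitted in both mm^3 and cm^3 under explicit unit
#' keys, and a schema version string is attached.
#'
#' @param x a result object (`densitometric_profile`, `pabcd_result`,
#'   `lms_result`, `modified_lms_result`, `agreement_report`, or a plain
#'   named list).
#' @return a named list of scalars/vectors.
#' @export
as_result_record <- function(x) UseMethod("as_result_record")

#' @export
as_result_record.default <- function(x) {
  c(list(schema_version = SCHEMA_VERSION), as.list(x))
}

#' Write a result record to JSON or append it as a CSV row
#'
#' @param record a result object accepted by [as_result_record()].
#' @param path output file.
#' @param format `"json"` or `"csv_row"` (appends to `path`, writing a
#'   header when the file does not yet exist).
#' @return `path`, invisibly.
#' @export
write_result <- function(record, path, format = c("json", "csv_row")) {
  format <- match.arg(format)
  rec <- as_result_record(record)
  rec <- rec[!vapply(rec, is.null, logical(1))]
  if (format == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    flat <- lapply(rec, function(v) {
      if (length(v) == 1L && is.atomic(v)) v else
        paste(format(v, digits = 17), collapse = ";")
    })
    df <- as.data.frame(flat, stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(path), append = file.exists(path))
  }
  invisible(path)
}

#' Read back a JSON result record
#'
#' @param path file written by [write_result()] with `format = "json"`.
#' @return a named list.
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# both-unit volume emission helper: takes named mm^3 scalars
volumes_both_units <- function(v_mm3) {
  out <- list()
  for (nm in names(v_mm3)) {
    out[[paste0(nm, "_mm3")]] <- unname(v_mm3[[nm]])
    out[[paste0(nm, "_cm3")]] <- unname(v_mm3[[nm]]) / 1000
  }
  out
}
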