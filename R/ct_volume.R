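#' CT volume in calibrated Hounsfield units
#'
#' Container for a 3-D CT voxel grid. Voxel values are Hounsfield units
#' *after* rescale slope/intercept have been applied (exactly once, by the
#' reader). The grid is stored in (x, y, z) order with physical voxel edge
#' lengths in millimetres and the physical position of the centre of the
#' first voxel as origin.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param axes_order axis convention tag; only `"xyz"` is produced by this
#'   package.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      axes_order = "xyz") {
  voxels <- unclass(voxels)
  attributes(voxels) <- list(dim = dim(voxels))
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array, got ", length(dim(voxels)),
         " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("voxel array contains non-finite HU values after calibration")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axes_order = axes_order),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  HU range: [%.1f, %.1f], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Volume of a single voxel in cubic millimetres
#'
#' @param x a `ct_volume` or `voi_mask`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(x) prod(attr_spacing(x))

attr_spacing <- function(x) {
  if (inherits(x, "ct_volume")) x$spacing
  else if (inherits(x, "voi_mask")) attr(x, "spacing")
  else stop("no spacing metadata on object of class ",
            paste(class(x), collapse = "/"))
}

attr_origin <- function(x) {
  if (inherits(x, "ct_volume")) x$origin
  else if (inherits(x, "voi_mask")) attr(x, "origin")
  else stop("no origin metadata on object of class ",
            paste(class(x), collapse = "/"))
}

#' Binary volume-of-interest mask
#'
#' A logical 3-D array on the same grid as its companion [ct_volume()].
#' Masks flagged empty may be carried around but cannot be scored.
#'
#' @param voxels logical (or coercible) 3-D array; nonzero means foreground.
#' @param reference the companion `ct_volume` (grid metadata is copied), or
#'   `NULL` if `spacing`/`origin` are given directly.
#' @param spacing,origin grid metadata, used when `reference` is `NULL`.
#' @return An object of class `voi_mask` (logical array with grid
#'   attributes and an `empty` flag).
#' @export
voi_mask <- function(voxels, reference = NULL, spacing = NULL, origin = NULL) {
  dm <- dim(voxels)
  if (is.null(dm) || length(dm) != 3L)
    stop("mask must be a 3-D array")
  if (!is.null(reference)) {
    if (!inherits(reference, "ct_volume"))
      stop("'reference' must be a ct_volume")
    if (!identical(dm, dim(reference$voxels)))
      stop(sprintf("mask shape (%s) does not match reference shape (%s)",
                   paste(dm, collapse = ","),
                   paste(dim(reference$voxels), collapse = ",")))
    spacing <- reference$spacing
    origin <- reference$origin
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  m <- array(as.vector(voxels) != 0, dim = dm)
  structure(m, spacing = as.numeric(spacing), origin = as.numeric(origin),
            empty = !any(m), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("VOI mask: %s voxels, %d foreground%s\n",
              paste(dim(x), collapse = " x "), sum(x),
              if (attr(x, "empty")) " [EMPTY]" else ""))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a `voi_mask`.
#' @return integer count.
#' @export
n_foreground <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask)
}

# shared grid compatibility check
check_same_grid <- function(a, b, what = "objects") {
  da <- if (inherits(a, "ct_volume")) dim(a$voxels) else dim(a)
  db <- if (inherits(b, "ct_volume")) dim(b$voxels) else dim(b)
  if (!identical(da, db))
    stop(sprintf("%s are on different grids: (%s) vs (%s)", what,
                 paste(da, collapse = ","), paste(db, collapse = ",")))
  sa <- attr_spacing(a); sb <- attr_spacing(b)
  if (max(abs(sa - sb)) > 1e-6)
    stop(sprintf("%s have different voxel spacing: (%s) vs (%s) mm", what,
                 paste(format(sa), collapse = ","),
                 paste(format(sb), collapse = ",")))
  invisible(TRUE)
}
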