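LANDMARK_NAMES <- c("S", "N", "Ba", "ANS", "PNS", "A", "MX_left", "MX_right")

#' Cephalometric landmark set bounding the sinonasal VOI
#'
#' The eight skull reference points used to bound the navigation VOI:
#' S (centre of the sella turcica), N (frontonasal suture), Ba (anterior
#' limit of the foramen magnum), ANS (anterior nasal spine), PNS (posterior
#' hard palate), A (maxillary symphysis below ANS), and the left/right MX
#' points (deepest point between the lateral maxillary wall and the
#' maxillary process of the zygoma). Coordinates are physical millimetres.
#' The six midline points define the midsagittal plane; MX_left and
#' MX_right must lie on opposite sides of it.
#'
#' @param points an 8 x 3 numeric matrix with rownames
#'   `S, N, Ba, ANS, PNS, A, MX_left, MX_right`, or a named list of
#'   length-3 numerics.
#' @return an object of class `landmark_set` (8 x 3 matrix).
#' @export
landmark_set <- function(points) {
  if (is.list(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  if (is.null(rownames(points)))
    stop("landmark points must be named")
  if (!setequal(rownames(points), LANDMARK_NAMES))
    stop("landmarks must be exactly: ", paste(LANDMARK_NAMES, collapse = ", "),
         "; missing: ",
         paste(setdiff(LANDMARK_NAMES, rownames(points)), collapse = ", "))
  points <- points[LANDMARK_NAMES, , drop = FALSE]
  if (ncol(points) != 3L || any(!is.finite(points)))
    stop("each landmark must be a finite 3-D point (mm)")
  check_mx_sides(points)
  structure(points, class = c("landmark_set", "matrix"))
}

# midsagittal plane = best-fit plane through the six midline landmarks;
# MX_left/MX_right must have strictly opposite signed distances
check_mx_sides <- function(points) {
  mid <- points[c("S", "N", "Ba", "ANS", "PNS", "A"), , drop = FALSE]
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warning("midline landmarks are collinear; cannot verify MX laterality")
    return(invisible(FALSE))
  }
  normal <- sv$v[, 3]
  dl <- sum((points["MX_left", ] - ctr) * normal)
  dr <- sum((points["MX_right", ] - ctr) * normal)
  if (dl * dr >= 0)
    stop("MX_left and MX_right must lie on opposite sides of the ",
         "midsagittal plane through the midline landmarks")
  invisible(TRUE)
}

#' Read landmarks from CSV or JSON
#'
#' CSV needs columns `name,x_mm,y_mm,z_mm`; JSON maps each landmark name to
#' a 3-vector.
#'
#' @param path landmark file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(landmark_set(lst))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  m <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- df$name
  landmark_set(m)
}

#' Rasterize the landmark bounding box to a VOI mask
#'
#' The VOI is the axis-aligned bounding box spanning the landmark extremes
#' on each axis. A voxel belongs to the VOI iff its centre lies inside the
#' half-open box `[lo, hi)` (half-open so adjacent boxes partition the grid
#' without double counting).
#'
#' @param landmarks a [landmark_set()].
#' @param grid a [ct_volume()] defining the voxel grid.
#' @return a [voi_mask()].
#' @export
landmarks_to_voi <- function(landmarks, grid) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(grid, "ct_volume"))
  dm <- dim(grid$voxels)
  sp <- grid$spacing
  or <- grid$origin
  # physical extent of the grid: voxel faces, not centres
  ext_lo <- or - sp / 2
  ext_hi <- or + (dm - 0.5) * sp
  for (i in seq_len(nrow(landmarks))) {
    p <- landmarks[i, ]
    if (any(p < ext_lo) || any(p > ext_hi))
      stop("landmark ", rownames(landmarks)[i],
           " lies outside the grid physical extent")
  }
  lo <- apply(unclass(landmarks), 2, min)
  hi <- apply(unclass(landmarks), 2, max)
  if (any(hi - lo <= 0))
    stop("degenerate landmark box: zero extent on axis ",
         paste(which(hi - lo <= 0), collapse = ", "))
  inside_ax <- lapply(1:3, function(a) {
    centers <- or[a] + (seq_len(dm[a]) - 1) * sp[a]
    centers >= lo[a] & centers < hi[a]
  })
  m <- array(FALSE, dm)
  m[inside_ax[[1]], inside_ax[[2]], inside_ax[[3]]] <- TRUE
  voi_mask(m, spacing = sp, origin = or)
}

#' Restrict a region to a container (voxelwise intersection)
#'
#' @param region,container [voi_mask()]s on the same grid.
#' @return a [voi_mask()], possibly empty (flagged).
#' @export
restrict <- function(region, container) {
  stopifnot(inherits(region, "voi_mask"), inherits(container, "voi_mask"))
  check_same_grid(region, container, "region and container masks")
  voi_mask(region & container, spacing = attr(region, "spacing"),
           origin = attr(region, "origin"))
}

#' Region set: total VOI plus optional sub-ROIs
#'
#' Bundles the total sinonasal VOI with optional named per-sinus masks and
#' left/right ostiomeatal-complex masks. Sub-ROIs are intersected with the
#' total VOI at construction so that every sub-ROI is a subset of it.
#' Sinus names must come from the fixed Lund-Mackay vocabulary
#' (`maxillary`, `anterior_ethmoid`, `posterior_ethmoid`, `sphenoid`,
#' `frontal`, each `_left`/`_right`).
#'
#' @param total total VOI [voi_mask()].
#' @param sinus named list of per-sinus masks (may be empty).
#' @param omc list with optional elements `left` and `right`.
#' @return an object of class `region_set`.
#' @export
region_set <- function(total, sinus = list(), omc = list()) {
  stopifnot(inherits(total, "voi_mask"))
  if (attr(total, "empty"))
    stop("total VOI mask is empty")
  if (length(sinus) > 0) {
    bad <- setdiff(names(sinus), LMS_SINUS_NAMES)
    if (length(bad) > 0 || is.null(names(sinus)))
      stop("sinus mask names must be from the Lund-Mackay vocabulary (",
           paste(LMS_SINUS_NAMES, collapse = ", "), "); offending: ",
           paste(bad, collapse = ", "))
    sinus <- lapply(sinus, restrict, container = total)
  }
  if (length(omc) > 0) {
    if (!all(names(omc) %in% c("left", "right")))
      stop("omc masks must be named 'left' and/or 'right'")
    omc <- lapply(omc, restrict, container = total)
  }
  structure(list(total = total, sinus = sinus, omc = omc),
            class = "region_set")
}
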