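#' Hounsfield-unit threshold scheme for tissue classification
#'
#' Three contiguous, non-overlapping HU bands partition the diagnostic range
#' into air, soft tissue and bone. The defaults reproduce the integer
#' convention air -2000..-250, soft -249..+250, bone +251..+2000: because
#' calibrated HU are floats (DICOM rescale slopes are frequently
#' non-integer), the bands split at the half-integers -249.5 and +250.5, so
#' every integer HU lands exactly where the integer convention puts it and
#' every float HU has a unique class. Values outside
#' `[hu_min, hu_max]` are *excluded* (metal artefacts, padding) and always
#' reported, never dropped.
#'
#' @param air_soft HU boundary between air and soft tissue; air is
#'   `[hu_min, air_soft)`, soft is `[air_soft, soft_bone)`.
#' @param soft_bone HU boundary between soft tissue and bone; bone is
#'   `[soft_bone, hu_max]`.
#' @param hu_min,hu_max limits of the in-band HU range.
#' @return an object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(air_soft = -249.5, soft_bone = 250.5,
                             hu_min = -2000, hu_max = 2000) {
  v <- c(hu_min, air_soft, soft_bone, hu_max)
  if (any(!is.finite(v)) || any(diff(v) <= 0))
    stop("threshold scheme must satisfy hu_min < air_soft < soft_bone < hu_max")
  structure(list(hu_min = hu_min, air_soft = air_soft,
                 soft_bone = soft_bone, hu_max = hu_max),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf("HU bands: air [%g, %g), soft [%g, %g), bone [%g, %g]\n",
              x$hu_min, x$air_soft, x$air_soft, x$soft_bone, x$soft_bone,
              x$hu_max))
  invisible(x)
}

# label codes used throughout
LABEL_CODES <- c(outside = 0L, air = 1L, soft = 2L, bone = 3L, excluded = 4L)

#' Classify voxels into air / soft tissue / bone by HU thresholds
#'
#' Every voxel inside the region gets exactly one label: `air`, `soft` or
#' `bone` by the scheme's bands, or `excluded` when its HU lies outside the
#' in-band range. Voxels outside the region are labelled `outside`.
#'
#' @param ct a [ct_volume()].
#' @param region a [voi_mask()] on the same grid (must be nonempty).
#' @param scheme a [threshold_scheme()].
#' @return a `label_volume`: integer array (0 outside, 1 air, 2 soft,
#'   3 bone, 4 excluded) with grid attributes.
#' @export
classify_voxels <- function(ct, region, scheme = threshold_scheme()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(region, "voi_mask"),
            inherits(scheme, "threshold_scheme"))
  check_same_grid(ct, region, "CT and region mask")
  if (attr(region, "empty") || !any(region))
    stop("region mask is empty; nothing to classify")
  hu <- ct$voxels
  lab <- array(LABEL_CODES[["outside"]], dim = dim(hu))
  inm <- as.vector(region)
  h <- hu[inm]
  l <- rep.int(LABEL_CODES[["excluded"]], length(h))
  l[h >= scheme$hu_min & h < scheme$air_soft] <- LABEL_CODES[["air"]]
  l[h >= scheme$air_soft & h < scheme$soft_bone] <- LABEL_CODES[["soft"]]
  l[h >= scheme$soft_bone & h <= scheme$hu_max] <- LABEL_CODES[["bone"]]
  lab[inm] <- l
  structure(lab, spacing = attr_spacing(ct), origin = attr_origin(ct),
            codes = LABEL_CODES, class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- tabulate(as.vector(x) + 1L, nbins = 5L)
  names(tab) <- names(LABEL_CODES)
  cat("Label volume:", paste(dim(x), collapse = " x "), "voxels\n")
  print(tab)
  invisible(x)
}

#' Histogram of HU values inside a region
#'
#' Counts of in-band voxels per 1-HU bin; bin `b` covers `[b, b+1)` HU for
#' `b` in `[hu_min, hu_max)`, with values exactly at `hu_max` counted in the
#' top bin so that the counts sum to the in-band voxel total.
#'
#' @param ct a [ct_volume()].
#' @param region a nonempty [voi_mask()].
#' @param hu_min,hu_max in-band HU range (defaults -2000, +2000).
#' @return data frame with columns `hu` (bin lower edge) and `count`.
#' @export
hu_histogram <- function(ct, region, hu_min = -2000, hu_max = 2000) {
  stopifnot(inherits(ct, "ct_volume"), inherits(region, "voi_mask"))
  check_same_grid(ct, region, "CT and region mask")
  if (!any(region)) stop("region mask is empty")
  h <- ct$voxels[as.vector(region)]
  h <- h[h >= hu_min & h <= hu_max]
  bins <- pmin(floor(h), hu_max - 1) - hu_min + 1
  data.frame(hu = seq.int(hu_min, hu_max - 1),
             count = tabulate(bins, nbins = hu_max - hu_min))
}

#' Patency percentages on the air + soft-tissue denominator
#'
#' The percentage of air and of soft tissue relative to the
#' patency-relevant volume `v_air + v_soft` (the same denominator as the
#' P(ABCD) score). The two percentages always sum to 100.
#'
#' @param v_air,v_soft volumes (any common unit).
#' @return named numeric, `pct_air` and `pct_soft`.
#' @export
patency_percent <- function(v_air, v_soft) {
  denom <- v_air + v_soft
  if (!is.finite(denom) || denom <= 0)
    stop("no patency-relevant volume: v_air + v_soft must be positive")
  c(pct_air = 100 * v_air / denom, pct_soft = 100 * v_soft / denom)
}

#' Volumetric and densitometric profile of a region
#'
#' Classifies the region's voxels and converts label counts into volumes
#' (label count x voxel volume), percentages, first-order HU statistics and
#' the per-HU histogram. Volumes are reported in mm^3 with a cm^3 mirror in
#' serialized records. `pct_air`/`pct_soft` use the patency denominator
#' `v_air + v_soft`; `pct_air_total`/`pct_soft_total` use `v_total`.
#'
#' @param ct a [ct_volume()].
#' @param region a nonempty [voi_mask()].
#' @param scheme a [threshold_scheme()].
#' @return an object of class `densitometric_profile`.
#' @export
densitometric_profile <- function(ct, region, scheme = threshold_scheme()) {
  lab <- classify_voxels(ct, region, scheme)
  counts <- tabulate(as.vector(lab), nbins = 4L)  # air, soft, bone, excluded
  names(counts) <- c("air", "soft", "bone", "excluded")
  if (counts[["air"]] + counts[["soft"]] + counts[["bone"]] == 0L)
    stop("all in-region voxels are outside the diagnostic HU range")
  vv <- voxel_volume(ct)
  v <- counts * vv
  v_total <- sum(v)
  inband <- ct$voxels[as.vector(lab) %in% 1:3]
  pct <- if (counts[["air"]] + counts[["soft"]] > 0)
    patency_percent(v[["air"]], v[["soft"]])
  else c(pct_air = NA_real_, pct_soft = NA_real_)
  structure(list(
    n_voxels = counts,
    v_total = v_total,
    v_air = v[["air"]], v_soft = v[["soft"]], v_bone = v[["bone"]],
    v_excluded = v[["excluded"]],
    pct_air = unname(pct["pct_air"]), pct_soft = unname(pct["pct_soft"]),
    pct_air_total = 100 * v[["air"]] / v_total,
    pct_soft_total = 100 * v[["soft"]] / v_total,
    hu_min = min(inband), hu_max = max(inband), hu_mean = mean(inband),
    histogram = hu_histogram(ct, region, scheme$hu_min, scheme$hu_max),
    scheme = scheme
  ), class = "densitometric_profile")
}

#' @export
print.densitometric_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "Densitometric profile\n",
    "  V_total %.2f mm^3 | V_air %.2f | V_soft %.2f | V_bone %.2f | V_excl %.2f\n",
    "  %% air %.2f  %% soft %.2f  (air+soft denominator)\n",
    "  HU min/mean/max: %.1f / %.1f / %.1f\n"),
    x$v_total, x$v_air, x$v_soft, x$v_bone, x$v_excluded,
    x$pct_air, x$pct_soft, x$hu_min, x$hu_mean, x$hu_max))
  invisible(x)
}

#' @export
as_result_record.densitometric_profile <- function(x) {
  c(list(schema_version = SCHEMA_VERSION, record_type = "densitometric_profile"),
    volumes_both_units(list(v_total = x$v_total, v_air = x$v_air,
                            v_soft = x$v_soft, v_bone = x$v_bone,
                            v_excluded = x$v_excluded)),
    list(pct_air = x$pct_air, pct_soft = x$pct_soft,
         pct_air_total = x$pct_air_total, pct_soft_total = x$pct_soft_total,
         hu_min = x$hu_min, hu_max = x$hu_max, hu_mean = x$hu_mean))
}
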