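#' P(ABCD) patency score
#'
#' The soft-tissue fraction of the patency-relevant volume,
#' `P = V_soft / (V_soft + V_air)`, in `[0, 1]`. 0 means fully aerated
#' sinuses, 1 complete opacification. Accepts either a
#' [densitometric_profile()] or the two volumes directly (any common unit;
#' the score is scale-invariant).
#'
#' @param x a `densitometric_profile`, or the soft-tissue volume `V_soft`.
#' @param v_air the air volume, when `x` is numeric.
#' @return the score, a scalar in `[0, 1]`.
#' @export
pabcd_score <- function(x, v_air = NULL) UseMethod("pabcd_score")

#' @export
pabcd_score.densitometric_profile <- function(x, v_air = NULL) {
  pabcd_score.default(x$v_soft, x$v_air)
}

#' @export
pabcd_score.default <- function(x, v_air = NULL) {
  v_soft <- as.numeric(x)
  v_air <- as.numeric(v_air)
  if (length(v_soft) != 1L || length(v_air) != 1L ||
      !is.finite(v_soft) || !is.finite(v_air) || v_soft < 0 || v_air < 0)
    stop("v_soft and v_air must be single non-negative finite volumes")
  if (v_soft + v_air <= 0)
    stop("no patency-relevant volume in VOI (V_soft + V_air = 0)")
  v_soft / (v_soft + v_air)
}

#' Grade bands of the P(ABCD) score
#'
#' Six grades partition `[0, 1]`: P0 (absence of inflammation) at 0,
#' A (mild) on (0, 0.15), B (moderate) on \[0.15, 0.35), C (advanced) on
#' \[0.35, 0.55), D (severe) on \[0.55, 0.9) and P1 (pansinusitis) on
#' \[0.9, 1\]. Published boundary values are shared between adjacent grades;
#' here each boundary belongs to the upper grade so the map is total and
#' single-valued. P0 tolerates scores up to `zero_tol`.
#'
#' @param score numeric vector of scores in `[0, 1]`.
#' @param zero_tol scores at or below this are P0 (default 1e-9).
#' @param boundaries lower bounds of B, C, D and P1 (defaults 0.15, 0.35,
#'   0.55, 0.9).
#' @return character vector of grades in `{"P0","A","B","C","D","P1"}`.
#' @export
assign_grade <- function(score, zero_tol = 1e-9,
                         boundaries = c(B = 0.15, C = 0.35, D = 0.55, P1 = 0.9)) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("score must lie in [0, 1]")
  if (length(boundaries) != 4L || any(diff(c(0, boundaries, 1)) <= 0))
    stop("grade boundaries must be increasing within (0, 1)")
  out <- character(length(score))
  out[score <= zero_tol] <- "P0"
  out[score > zero_tol & score < boundaries[1]] <- "A"
  out[score >= boundaries[1] & score < boundaries[2]] <- "B"
  out[score >= boundaries[2] & score < boundaries[3]] <- "C"
  out[score >= boundaries[3] & score < boundaries[4]] <- "D"
  out[score >= boundaries[4]] <- "P1"
  out
}

#' Ostiomeatal complex patency score
#'
#' Grades the drainage channel from 0 (patent) to 2 (obstructed) by the
#' soft-tissue fraction of its sub-ROI: 0 when the fraction is below
#' `t_patent`, 2 at or above `t_obstructed`, 1 between (partial
#' involvement). Default thresholds split `[0, 1]` into thirds.
#'
#' @param x a `densitometric_profile` of the OMC sub-ROI, or the soft
#'   fraction directly.
#' @param t_patent,t_obstructed fraction thresholds (defaults 1/3 and 2/3).
#' @return integer score 0, 1 or 2.
#' @export
omc_score <- function(x, t_patent = 1/3, t_obstructed = 2/3) {
  f <- if (inherits(x, "densitometric_profile")) pabcd_score(x) else as.numeric(x)
  if (!is.finite(f) || f < 0 || f > 1)
    stop("OMC soft fraction must lie in [0, 1]")
  if (!(t_patent < t_obstructed))
    stop("t_patent must be below t_obstructed")
  if (f < t_patent) 0L else if (f >= t_obstructed) 2L else 1L
}

#' Lund-Mackay per-sinus score
#'
#' 0 for no opacification, 2 for total opacification, 1 for anything in
#' between — so a 99%-opacified sinus still scores 1. "No" and "total" are
#' read with tolerance `eps` so voxel-level noise cannot deny a visually
#' empty or full sinus.
#'
#' @param opacification_fraction fraction(s) in `[0, 1]` (soft-tissue
#'   fraction of the sinus).
#' @param eps tolerance at the ends of the scale (default 0.005).
#' @return integer score(s) in `{0, 1, 2}`.
#' @export
lms_sinus_score <- function(opacification_fraction, eps = 0.005) {
  f <- as.numeric(opacification_fraction)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("opacification fraction must lie in [0, 1]")
  ifelse(f <= eps, 0L, ifelse(f >= 1 - eps, 2L, 1L))
}

#' Modified (Zinreich) Lund-Mackay per-sinus score
#'
#' Stratifies opacification into 25% intervals on a 0-5 scale: 0 none,
#' 1 for (0, 25%], 2 for (25, 50%], 3 for (50, 75%], 4 for (75, <100%),
#' 5 total. As in [lms_sinus_score()], "none" and "total" carry tolerance
#' `eps`, and a 99%-opacified sinus scores 4, not 5.
#'
#' @inheritParams lms_sinus_score
#' @return integer score(s) in `{0, ..., 5}`.
#' @export
modified_lms_sinus_score <- function(opacification_fraction, eps = 0.005) {
  f <- as.numeric(opacification_fraction)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("opacification fraction must lie in [0, 1]")
  ifelse(f <= eps, 0L,
         ifelse(f >= 1 - eps, 5L, pmin(4L, as.integer(ceiling(f / 0.25)))))
}

LMS_SINUSES <- c("maxillary", "anterior_ethmoid", "posterior_ethmoid",
                 "sphenoid", "frontal")
LMS_SINUS_NAMES <- as.vector(outer(LMS_SINUSES, c("left", "right"),
                                   paste, sep = "_"))

check_score_components <- function(sinus_scores, omc_scores, sinus_max) {
  if (length(sinus_scores) != 10L)
    stop("expected 10 per-sinus scores (5 sinus pairs x 2 sides), got ",
         length(sinus_scores))
  if (length(omc_scores) != 2L)
    stop("expected 2 OMC scores (left, right), got ", length(omc_scores))
  if (any(!sinus_scores %in% 0:sinus_max))
    stop("per-sinus scores must be integers in 0..", sinus_max)
  if (any(!omc_scores %in% c(0L, 2L)))
    stop("OMC scores must be 0 (patent) or 2 (obstructed)")
  if (!is.null(names(sinus_scores)) &&
      !all(names(sinus_scores) %in% LMS_SINUS_NAMES))
    stop("unknown sinus names: ",
         paste(setdiff(names(sinus_scores), LMS_SINUS_NAMES), collapse = ", "))
  invisible(TRUE)
}

#' Lund-Mackay total score
#'
#' Sums ten per-sinus 0/1/2 scores and two OMC 0/2 scores (maximum 24) and
#' normalizes to percent of the scale maximum.
#'
#' @param sinus_scores ten integers in `{0,1,2}`, optionally named from the
#'   fixed sinus vocabulary (`maxillary`/`anterior_ethmoid`/
#'   `posterior_ethmoid`/`sphenoid`/`frontal` x `left`/`right`).
#' @param omc_scores two values in `{0, 2}` (left, right).
#' @return an `lms_result` with components, `total` and `percent`.
#' @export
lms_total <- function(sinus_scores, omc_scores) {
  check_score_components(sinus_scores, omc_scores, 2L)
  total <- sum(sinus_scores) + sum(omc_scores)
  structure(list(sinus_scores = sinus_scores, omc_scores = omc_scores,
                 total = total, max_total = 24L,
                 percent = 100 * total / 24),
            class = "lms_result")
}

#' Modified Lund-Mackay total score
#'
#' Sums ten per-sinus 0-5 scores and two OMC 0/2 scores (maximum 54) and
#' normalizes to percent of the scale maximum.
#'
#' @param sinus_scores ten integers in `{0,...,5}`.
#' @inheritParams lms_total
#' @return a `modified_lms_result` with components, `total` and `percent`.
#' @export
modified_lms_total <- function(sinus_scores, omc_scores) {
  check_score_components(sinus_scores, omc_scores, 5L)
  total <- sum(sinus_scores) + sum(omc_scores)
  structure(list(sinus_scores = sinus_scores, omc_scores = omc_scores,
                 total = total, max_total = 54L,
                 percent = 100 * total / 54),
            class = "modified_lms_result")
}

#' @export
print.lms_result <- function(x, ...) {
  label <- if (inherits(x, "modified_lms_result")) "Modified Lund-Mackay"
           else "Lund-Mackay"
  cat(sprintf("%s score: %d / %d (%.1f%%)\n",
              label, x$total, x$max_total, x$percent))
  invisible(x)
}

#' @export
print.modified_lms_result <- print.lms_result

#' @export
as_result_record.lms_result <- function(x) {
  list(schema_version = SCHEMA_VERSION, record_type = "lms_result",
       sinus_scores = x$sinus_scores, omc_scores = x$omc_scores,
       total = x$total, max_total = x$max_total, percent = x$percent)
}

#' @export
as_result_record.modified_lms_result <- function(x) {
  rec <- as_result_record.lms_result(x)
  rec$record_type <- "modified_lms_result"
  rec
}

#' @export
as_result_record.pabcd_result <- function(x) {
  list(schema_version = SCHEMA_VERSION, record_type = "pabcd_result",
       score = x$score, grade = x$grade,
       omc_left = x$omc_left, omc_right = x$omc_right,
       v_soft_mm3 = x$profile$v_soft, v_soft_cm3 = x$profile$v_soft / 1000,
       v_air_mm3 = x$profile$v_air, v_air_cm3 = x$profile$v_air / 1000)
}

#' @export
print.pabcd_result <- function(x, ...) {
  cat(sprintf("P(ABCD) = %.4f, grade %s", x$score, x$grade))
  if (!is.null(x$omc_left) || !is.null(x$omc_right))
    cat(sprintf("; OMC left %s / right %s",
                x$omc_left %||% "-", x$omc_right %||% "-"))
  cat("\n")
  invisible(x)
}

#' Score a CT volume: P(ABCD), OMC, and (when sub-ROIs exist) LMS / mLMS
#'
#' Runs the full workflow on a calibrated CT and a [region_set()]:
#' classifies voxels in the total VOI, computes the P(ABCD) score and grade,
#' scores each OMC sub-ROI when present, and — when all ten per-sinus masks
#' are present — derives Lund-Mackay and modified Lund-Mackay totals from
#' the per-sinus soft-tissue fractions. For the binary LMS OMC component
#' (defined only as 0 or 2), any more-than-patent involvement
#' (three-level OMC score >= 1) counts as obstructed.
#'
#' @param ct a [ct_volume()].
#' @param regions a [region_set()].
#' @param scheme a [threshold_scheme()].
#' @param omc_thresholds length-2 numeric, `t_patent` and `t_obstructed`
#'   for [omc_score()].
#' @return list with elements `pabcd` (a `pabcd_result`), `lms`, `mlms`
#'   (`NULL` unless all per-sinus masks are present) and `sinus_fractions`.
#' @export
score_ct <- function(ct, regions, scheme = threshold_scheme(),
                     omc_thresholds = c(1/3, 2/3)) {
  stopifnot(inherits(regions, "region_set"))
  prof <- densitometric_profile(ct, regions$total, scheme)
  score <- pabcd_score(prof)
  omc_l <- omc_r <- NULL
  if (!is.null(regions$omc$left))
    omc_l <- omc_score(densitometric_profile(ct, regions$omc$left, scheme),
                       omc_thresholds[1], omc_thresholds[2])
  if (!is.null(regions$omc$right))
    omc_r <- omc_score(densitometric_profile(ct, regions$omc$right, scheme),
                       omc_thresholds[1], omc_thresholds[2])
  pr <- structure(list(score = score, grade = assign_grade(score),
                       omc_left = omc_l, omc_right = omc_r, profile = prof),
                  class = "pabcd_result")

  lms <- mlms <- NULL
  fractions <- NULL
  if (length(regions$sinus) > 0) {
    fractions <- vapply(regions$sinus, function(m)
      pabcd_score(densitometric_profile(ct, m, scheme)), numeric(1))
    if (all(LMS_SINUS_NAMES %in% names(fractions)) &&
        !is.null(omc_l) && !is.null(omc_r)) {
      fr <- fractions[LMS_SINUS_NAMES]
      omc_lms <- c(left = if (omc_l >= 1L) 2L else 0L,
                   right = if (omc_r >= 1L) 2L else 0L)
      s1 <- lms_sinus_score(fr); names(s1) <- LMS_SINUS_NAMES
      s2 <- modified_lms_sinus_score(fr); names(s2) <- LMS_SINUS_NAMES
      lms <- lms_total(s1, omc_lms)
      mlms <- modified_lms_total(s2, omc_lms)
    }
  }
  list(pabcd = pr, lms = lms, mlms = mlms, sinus_fractions = fractions)
}
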