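---
title: "Quantifying sinus opacification on CT: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sinus opacification on CT: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pabcd)
```

## The measurement model

Chronic rhinosinusitis with nasal polyposis replaces sinus air with
soft-tissue-density material (mucosal thickening, polyps, secretions).
On a HU-calibrated CT this is directly measurable: inside a sinonasal
volume of interest (VOI), each voxel is assigned to one of three tissue
classes by attenuation, and disease burden is the soft-tissue share of the
space that could be aerated.

The class bands follow the usual integer convention — air from −2000 to
−250 HU, soft tissue from −249 to +250 HU, bone from +251 to +2000 HU.
Calibrated HU are floats (DICOM rescale slopes are often non-integer), so
the implementation uses contiguous half-open bands split at the
half-integers −249.5 and +250.5. Every float HU then has exactly one
class, and every integer HU lands where the integer convention puts it.
Voxels outside [−2000, +2000] (metal artefacts, padding) are labelled
*excluded* and reported, never dropped: the conservation identity
`v_air + v_soft + v_bone + v_excluded = v_total` holds exactly on every
input and is asserted in the tests.

A region's `densitometric_profile()` converts label counts into volumes
(count × voxel volume, reported in mm³ and cm³), first-order HU statistics
(min/mean/max over in-band voxels) and a histogram with 1-HU bins
(bin *b* covers [*b*, *b*+1); values exactly at +2000 fold into the top
bin so counts still sum to the in-band total).

Two percentage conventions coexist in practice: percent of the total VOI
volume, and percent of the patency-relevant volume `v_air + v_soft`. The
primary outputs `pct_air`/`pct_soft` use the patency denominator — the one
consistent with the score below and with the self-consistent worked
numbers available for checking — while `pct_air_total`/`pct_soft_total`
are also emitted under distinct keys so neither reading is lost.

## The P(ABCD) score and its grades

The patency score is

$$P = \frac{V_{soft}}{V_{soft} + V_{air}} \in [0, 1],$$

deliberately excluding bone from the denominator: bone is anatomy, not
disease, and the score is invariant to how much bony wall the VOI happens
to include. It is scale-invariant and strictly increasing in soft-tissue
volume at fixed air volume (both property-tested).

Grades: P0 (absence) at 0, A mild on (0, 0.15), B moderate on
[0.15, 0.35), C advanced on [0.35, 0.55), D severe on [0.55, 0.9), P1
pansinusitis on [0.9, 1]. The published band edges are shared between
adjacent grades (0.15 ends A and starts B, and so on); for a total,
single-valued map each boundary here belongs to the *upper* grade, P1 is
closed at 0.9, and P0 tolerates scores up to 1e−9 so that an exact zero
survives float arithmetic. Both the tolerance and the boundaries are
arguments of `assign_grade()`.

### Ostiomeatal complex

The OMC — the drainage channel — is scored 0 (patent) to 2 (obstructed)
from the soft fraction *f* of its own sub-ROI. The published account fixes
only the endpoints (0 patent, 2 obstructed) and speaks of the *degree* of
involvement, so the default here is a three-level map with thresholds at
thirds: 0 if *f* < 1/3, 1 in between, 2 if *f* ≥ 2/3 (`omc_score()`,
thresholds configurable). The OMC score is reported alongside the P(ABCD)
score, never added to it — the score's codomain is [0, 1] and the OMC's
soft tissue already flows through `V_soft` when the OMC lies inside the
total VOI.

For the classical LMS, whose OMC component is strictly binary {0, 2}, any
more-than-patent involvement (three-level score ≥ 1) counts as obstructed:
a narrow channel does not need to be packed solid to stop draining. This
binarisation only matters for mid-range OMC fractions.

### Lund-Mackay and modified Lund-Mackay

Per-sinus opacification fractions (the per-sinus soft fraction) map to the
two ordinal scales:

* LMS: 0 if the fraction is ≤ ε, 2 if ≥ 1 − ε, otherwise 1.
* Modified LMS: 0 and 5 at the same tolerant extremes, otherwise the 25%
  stratum — (0, 0.25] → 1, (0.25, 0.5] → 2, (0.5, 0.75] → 3,
  (0.75, 1) → 4. A 99%-opacified sinus scores 1 on LMS and 4 on the
  modified scale, reproducing the scales' documented behaviour.

ε defaults to 0.005: voxel-level noise or a single misclassified voxel
should not deny a visually total (or visually absent) opacification, while
the canonical "99% scores 1" example stays intact. Totals sum ten
per-sinus scores plus two OMC scores (maxima 24 and 54) and are
additionally normalized to percent of the scale maximum — the natural
normalization for comparing the three systems on one axis; the exact
percent conversion used in the original comparison is not documented, so
/24 and /54 are this package's explicit choice.

## The VOI

The navigation VOI is bounded by eight user-supplied cephalometric
landmarks (S, N, Ba, ANS, PNS, A, MX left/right, in mm). The published
workflow uses them as "boundaries" without stating the solid they bound;
here `landmarks_to_voi()` rasterizes the axis-aligned bounding box of the
eight points, including a voxel iff its centre lies in the half-open box
[lo, hi) — half-open so adjacent boxes partition the grid without double
counting. An explicitly supplied mask always wins over landmarks: with
patient data, trimming the box to exclude orbits and brain is the
operator's manual task and out of algorithmic scope. The six midline
landmarks define the midsagittal plane (best-fit by SVD) and the two MX
points must fall on opposite sides of it — a cheap guard against
mislabelled sides.

Sub-ROIs (per-sinus masks, OMC channels) are intersected with the total
VOI at `region_set()` construction, so classification and masking commute:
classifying then restricting gives the same counts as restricting then
classifying (property-tested).

## The phantom

`generate_phantom()` builds a bone-density block containing air cavities
partially filled with soft-tissue material:

* **Geometry.** Default 128³ voxels at 0.5 mm isotropic (a 64 mm cube):
  ten ellipsoidal cavities in five left/right pairs (maxillary, anterior
  and posterior ethmoid, sphenoid, frontal) plus two small cuboid OMC
  channels, placed as a desk-scale caricature of sinonasal topology —
  maxillary low and lateral, frontal high and anterior, ethmoids midline,
  sphenoid posterior, the OMC channel between maxillary and anterior
  ethmoid. Cavities must rasterize to at least one voxel and may not
  overlap (both are errors, not warnings). Grids of 24³ and up resolve
  every default cavity; most tests run at 24³–32³ and the recovery check
  at the full 128³.
* **Fill.** Each cavity fills with soft tissue from its lowest z-extent
  upward (gravity-like, contiguous — mimicking how secretions and
  mucosal thickening actually present, and making partial-volume
  experiments meaningful), taking `round(fill × n)` voxels with the
  deterministic tie-break (z, then y, then x). The realized fraction —
  counted from the label volume, not the nominal request — is recorded in
  the truth record and is exact by construction.
* **HU model.** Per class, HU ~ Gaussian clipped to the class band: air
  N(−1000, 30) clipped to [−2000, −250], soft N(+40, 50) to [−249, +250],
  bone N(+700, 100) to [+251, +2000]. Means and SDs are physiologic CT
  values; the clipping guarantees that threshold classification recovers
  the noise-free labels *exactly*, so the phantom's ground truth is an
  equality, not an approximation.

What the phantom does **not** emulate: partial-volume averaging at
interfaces, beam hardening, HU class overlap (real mucus and mucosa can
flirt with the −250 boundary), anatomy (real sinuses are not ellipsoids),
or acquisition artefacts. Passing the recovery tests therefore
demonstrates that the *pipeline* — rasterization, counting, scoring,
serialization — is correct; it does not certify robustness to real-world
HU ambiguity, which only patient data can test.

## The synthetic cohort

`default_cohort()` emulates a 20-patient paired before/after design in
which each patient is their own control. Baseline fill fractions are
Beta-distributed with mean 0.68 and SD 0.15 — the study conditions for
the effect, with the spread chosen to be consistent with a reported
pooled SD near 0.20 and a score range of roughly 0.28–0.96 once the
treatment shift is folded in. Treatment acts multiplicatively: each
patient draws a response ratio from a Beta scaled to [0, 1.25] with mean
`post/pre` (0.765 at the default 0.68 → 0.52) and SD 0.18, and
`post = min(1, pre × ratio)`. The support above 1 lets a minority
(roughly one patient in ten) worsen, as real cohorts do; the multiplicative
form keeps post fills in range without truncating the bulk of the
distribution. These defaults are the generator's definition of the study
conditions and are not tuned per test. At n = 20 this effect size gives
the Wilcoxon signed-rank test essentially full power (the acceptance suite
demands ≥ 90% over 200 seeded replicates).

## Statistical conventions

* **Wilcoxon signed-rank** (`wilcoxon_signed_rank`): two-sided on
  `post − pre`; zero differences dropped (Wilcoxon's original convention,
  recorded in the output); average ranks for tied magnitudes; exact null
  distribution when the effective n < 13 with no ties, otherwise the
  normal approximation with tie and continuity correction. The exact path
  is validated against full 2ⁿ sign-assignment enumeration in the tests.
* **Friedman** (`friedman_test`): within-subject ranks, tie-corrected
  statistic, χ² reference with k − 1 df. When every subject is completely
  tied across all k samples the tie-corrected statistic is 0/0; by
  convention the test returns statistic 0, p = 1 (no rank information).
* **Bonferroni** (`bonferroni`): `min(1, p × m)`.
* **Bland–Altman** (`bland_altman`): differences are first method minus
  second, with the method names recorded in the report; bias is the mean
  difference, limits of agreement bias ± 1.96 × sample SD (n − 1). The
  report is structurally symmetric about the bias, which the tests assert.

## Numerical choices and degenerate inputs

* HU are stored as doubles after calibration; thresholds compare floats.
  Missing DICOM rescale tags are an error — an identity rescale is never
  assumed. NIfTI follows its own convention that a zero scl slope means
  no scaling.
* Empty masks are flagged on read (warning) but only error at scoring
  time, so plumbing can pass them around.
* A region whose voxels are all HU-excluded cannot be profiled (error), a
  patency denominator of zero cannot be scored (error), and a zero
  baseline has no percent change (error).
* Phantom fills use `round()` (banker's rounding at .5); the realized
  fraction is always recorded, so no consumer needs to reconstruct the
  rounding.
* Test problem sizes: oracle-equivalence suites run 100 random instances
  each (grids up to ~14³ for the per-voxel loop oracle, n ≤ 10 pairs for
  the 2ⁿ enumeration); phantom tests run at 24³–32³; the headline recovery
  check runs once at the default 128³.

## Limitations

The VOI bounding box is a crude anatomical container; real use relies on
operator-supplied masks. Per-sinus LMS/mLMS scoring requires per-sinus
masks, which the phantom provides but patient data may not. The DICOM
reader covers uncompressed 16-bit explicit/implicit little-endian series —
the common CT export — not compressed transfer syntaxes or RTSTRUCT
contours (masks are the exchange format). The phantom's clipped-noise HU
model makes ground truth exact at the cost of realism near class
boundaries, and the cohort generator models a multiplicative treatment
response only.
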