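---
title: "Wall morphometry and segment classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall morphometry and segment classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `esoMorph`. The package operates downstream of esophagus
segmentation: its input contract is a non-contrast chest CT volume plus a
binary esophagus mask on the same grid, and its output is a per-segment and
per-patient cancer call with full measurement provenance. Segmentation
itself is out of scope; `runCase()` accepts any mask, and a pluggable
backend can be wired in front of it.

## Geometry conventions

Voxel grids use the axis order (slice, row, column) = (z, y, x), matching
CT acquisition; spacing and origin are in millimetres in that order, and
voxel centres are the physical reference (the centre of array element
(1,1,1) sits at `origin`). NIfTI files are converted to and from this
convention on read/write. Masks resample nearest-neighbour so labels stay
binary — a threshold-at-0.5 linear alternative was rejected to keep labels
crisp; CT volumes resample trilinearly.

## Wall delineation

The esophagus mask covers wall plus lumen. A voxel is wall iff it is in the
mask and its HU value is at or above the air threshold.

* `hu_threshold` (default **−500 HU**): air is ≈ −1000 HU and any soft
  tissue ≥ −100 HU, so any value in between works; −500 is the midpoint and
  is insensitive to the noise levels seen on routine scans (tens of HU).
  The operation is idempotent and errors on an all-air result rather than
  returning an empty wall.

## Centerline extraction

The organ is tubular but curved and oblique, so per-slice centroids fail
wherever a transverse slice cuts the tube twice. The package instead works
on the 1 mm isotropically resampled mask (5 mm slices are far too coarse
for 3D medial analysis) and computes:

1. the largest 26-connected component;
2. the interior depth field (Euclidean distance transform to background,
   exact, anisotropy-aware, computed in C++ by the separable
   lower-envelope algorithm);
3. the two tube ends, as the farthest voxel pair under a double
   graph-distance sweep with physical edge lengths;
4. the geodesic between them with edge weights
   `length / (mean endpoint depth + 0.5)^2`, which pulls the path onto the
   medial axis — the standard depth-penalized-geodesic alternative to
   explicit 3D thinning, and equally robust on unbranched tubes.

Two post-passes fix the path ends. The raw geodesic endpoints necessarily
sit on the mask surface (e.g. a rim corner of a tube end face), so the path
is trimmed while its depth is below 0.9 × the median path depth, then
extended from each trimmed end along the local end tangent (estimated over
a ~10 mm span) until leaving the mask. On analytic tubes this recovers the
full axis: the arc-length and lateral-deviation oracles in the test suite
(straight cylinder, quarter torus) hold to within one voxel and 5%.

* `iso_mm` (default **1 mm**): resampling step for medial analysis.
* `smooth_window` (default **5 points**): moving-average window applied to
  the voxel path; shrinking windows at the ends avoid endpoint drag.
* Orientation: superior → inferior, taken as ascending slice coordinate.
  The starting point of the segment rule is the superior end; this is a
  package decision, recorded here because the clinical division is stated
  from an unspecified "starting point".

## Straightening

Curved planar reformation samples square planes orthogonal to the
centerline tangent at a fixed arc step. Frames are propagated by parallel
transport (projecting the previous normal off the new tangent) rather than
Frenet frames, which spin freely where curvature vanishes. Masks are
sampled nearest-neighbour, HU volumes trilinearly with a −1000 HU
out-of-volume fill.

* `step_mm` (default **2.5 mm**): cut-plane sampling interval — half the
  routine 5 mm slice thickness; the sampling interval is not clinically
  standardized, so it is exposed in the configuration.
* `plane_half_width_mm` (default **20 mm**), `plane_pixel_mm` (default
  **1 mm**): plane extent and resolution. Planes whose foreground touches
  the border are flagged truncated and surface as QC warnings.

## Cross-section morphometry

Wall thickness is defined area-equivalently: with hole-filled wall area
\(A_f\) and enclosed lumen area \(A_l\),
\(D_{outer} = 2\sqrt{A_f/\pi}\), \(D_{lumen} = 2\sqrt{A_l/\pi}\), and
\(t = (D_{outer} - D_{lumen})/2\). Area-based estimates are robust to the
jagged plane boundaries produced by nearest-neighbour sampling of coarse
grids, which is why this definition is primary. A medial estimate — twice
the mean EDT over ridge pixels (those within half a pixel of the maximum),
minus a half-pixel boundary correction — is recorded as
`thickness_edt_mm`; on analytic rings the two agree within 20% or one
pixel, whichever is larger (EDT thickness is inherently pixel-quantized).
Holes are filled per plane in 2D, not 3D, so open tube ends cannot leak
the fill.

Degenerate cases: a collapsed lumen (no enclosed hole) gives
\(D_{lumen} = 0\) and \(t = D_{outer}/2\) — the esophagus is normally
collapsed, and generalized mural thickening presents exactly this way. A
plane with no background (single-pixel or solid plane) has no EDT estimate
(`NA`). Empty planes are skipped and counted as gaps.

Both the outer and the lumen diameter are recorded; "average diameter" is
ambiguous between the two, so the classifier uses the outer one and the
lumen stays available in the profile.

## Segments and features

From the superior starting point, upper = [0, 50) mm, middle =
[50, 150) mm, lower = [150, L]. Intervals are half-open with the final one
closed — an arc position exactly at a boundary goes to the following
segment — and are clipped for short organs (lower is empty iff
L ≤ 150 mm). An arc landing exactly on L in a clipped organ belongs to the
last non-empty segment.

Per segment the features are: plane count, mean and **sample** variance
(ddof = 1) of outer diameter and wall thickness, and maximum thickness.
Variances are the primary signature (a focal lesion perturbs part of a
segment); means and maxima are included because a uniform generalized
thickening has low variance but a shifted level, and the lesion taxonomy
demands level-sensitive features. Segments with fewer than two measured
planes are flagged missing rather than given degenerate statistics.

* `end_margin_mm` (default **2.5 mm**): planes within this margin of the
  organ ends are excluded from the features. The terminal planes straddle
  the end faces and measure as partial rings (a collapsed-lumen artifact
  of geometry, not anatomy); the margin removes exactly those.

## Decision tree and patient call

A CART tree (Gini impurity, `max_depth` 3, `min_leaf` 5, balanced class
weights, fixed seed) is fitted on the pooled per-segment table with the
segment index (1/2/3, anatomically ordered) available as a feature —
pooling shares statistical strength across segments while letting the tree
specialize per segment if the data demand it; per-segment trees were
considered and rejected for sample-size reasons at typical cohort scales.
The hyperparameters are not clinically prescribed anywhere; a shallow tree
over a 7-column feature space keeps the classifier interpretable, which is
the point of using a tree at all. Training labels are per-segment. The
fitted model is flattened to a heap-numbered node table which is what
prediction traverses; JSON serialization therefore round-trips to an
identical predictor.

A patient is positive iff any non-missing segment is positive
(probability ≥ `threshold`, default 0.5, configurable so ROC curves can be
traced); the patient probability is the maximum segment probability. The
any-positive rule is monotone by construction. Missing segments propagate
as missing — a negative call made with segments missing carries a warning,
and an all-missing case is an error, never a silent negative.

Cross-validation is stratified by patient label and split at patient level
(all segments of a patient share a fold); held-out patient calls are pooled
into a single confusion matrix.

## The phantom: what it emulates, what it does not

`generatePhantom()` builds a curved tube — lumen radius 4 mm, wall 3 mm,
length 250 mm, textbook adult esophagus dimensions — with a sinusoidal
lateral deflection (amplitude 15 mm, period 200 mm) so that centerline
extraction is tested on genuine curvature. Tissue HU values are standard:
air −1000, wall 40 (soft tissue), background −80 (mediastinal fat), plus
Gaussian noise (default sd 10 HU). The grid defaults to
64 × 96 × 96 voxels at (5, 0.8, 0.8) mm — 5 mm slices as on routine chest
CT, reduced in-plane so tests stay fast; clinical 512 × 512 geometry is
one argument away. Tube ends are cut flat so the ground-truth arc length
is exact.

Lesions implement the three CT morphologies of esophageal carcinoma:

* **focal thickening** — added wall thickness with a flat core over the
  central 60% of the extent and a cosine taper to zero;
* **generalized thickening** — constant added thickness over the extent;
* **polypoid** — a hemispherical nodule seated on the inner wall,
  protruding into the lumen.

Ground truth records the analytic centerline, per-segment labels under the
5/10 cm rule (a segment is positive iff a lesion centre falls in it) and
the patient label as their OR. Cohorts draw lesion size from configurable
ranges — added thickness Uniform(2, 6) mm by default, longitudinal extent
Uniform(20, 50) mm, within the range of reported tumour lengths — with
per-case seeds derived deterministically from a master seed.

The phantom deliberately omits: surrounding anatomy (lungs, vertebrae,
heart), scanner physics (beam hardening, reconstruction kernels), contrast
enhancement, peristaltic collapse, and HU texture. Passing the recovery
tests therefore demonstrates that the measurement chain and classifier
recover geometric wall changes at realistic noise and slice thickness — it
does not certify performance on patient data, where segmentation quality
and soft-tissue ambiguity dominate.

## Statistics suite

* Confusion metrics follow the standard identities; zero denominators
  surface as `NA`, never as silent zeros. Report tables round half-up to 3
  decimals, the convention of printed diagnostic tables.
* Binary reader calls are treated as single-operating-point ROCs, so
  AUC = (sensitivity + specificity)/2 (balanced accuracy) — the only
  convention under which a binary rater has an ROC area at all. Continuous
  scores use the rank/Mann–Whitney AUC with half-credit ties, which equals
  the trapezoidal ROC area and, on every instance, an exhaustive
  concordant-pair count (a test enforces exact equality up to n = 50).
* DeLong's paired AUC test uses placement values and a two-sided normal
  approximation. It accepts binary ratings (matching reader-study use)
  with the caveat that coarse ratings make the variance estimate
  rank-deficient and the test conservative; identical ratings return
  z = 0, p = 1 by convention. Calibration (type-I error at α = 0.05 within
  [0.03, 0.07] over 1000 null replicates) is asserted in the acceptance
  suite.
* ICC: the two-way random-effects, absolute-agreement, single-rater form
  ICC(2,1) — the standard choice for inter-rater diagnostic consistency
  when raters are a random sample — with the McGraw–Wong F-based
  confidence interval. The variant tag is recorded in the result. Constant
  ratings are an error (the variance decomposition is undefined).
* Dice is 1 for two empty masks (logged); Hausdorff is computed between
  6-connectivity boundary voxel sets in physical mm, exactly, via the EDT
  of each boundary set.

## Problem sizes and tolerances

The acceptance experiment uses a 100-phantom cohort (50 lesioned at ≥ 3 mm
added thickness, 50 clean) under 5-fold patient-level cross-validation,
1000 null replicates for DeLong calibration, and n = 500 for ICC recovery
— sizes at which the Monte-Carlo error of each check is comfortably inside
its acceptance band. Geometric oracles use one-voxel/one-pixel tolerances
(the resolution limit of the grids involved) and 5% for arc lengths.
Idempotence checks (centerline resampling) use 10⁻⁶ mm.

## Known limitations

* The centerline assumes an unbranched tube; branched skeletons are
  implicitly pruned by the farthest-pair geodesic, but anastomoses or
  segmentation leaks into neighbouring structures would corrupt the path.
* Thickness is area-equivalent per plane; eccentric (one-sided) thickening
  registers with reduced amplitude compared to a local-maximum definition.
  The per-plane maximum-EDT field partially compensates.
* Sub-voxel contouring is out of scope; on 5 mm slices the straightened
  planes inherit nearest-neighbour jaggedness, which the area-based
  definitions average out.
* DICOM series input is not implemented (no DICOM reader in the supported
  dependency set); NIfTI is the interchange format.
* The classifier is a single shallow tree by design; it will saturate on
  subtle, sub-millimetre early-stage disease, which is exactly the regime
  the phantom experiments show is measurement-limited at 5 mm slices.
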