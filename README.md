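# esoMorph

Esophageal cancer often presents on CT as mural thickening — focal, polypoid,
or generalized — yet it is easily missed on the non-contrast chest scans
acquired for routine health checks. `esoMorph` implements the measurement and
classification pipeline that sits downstream of an esophagus segmentation
mask on such scans, for researchers evaluating automated esophageal-cancer
detection: given a CT volume and its binary esophagus mask, it quantifies
the wall geometry along the organ and calls each anatomical segment, and the
patient, cancer-present or not. A synthetic phantom generator and a full
diagnostic-statistics suite make every stage testable without patient data.

## The method

Starting from a CT volume *I* (Hounsfield units) and an esophagus mask *M*
on the same grid:

1. **Wall delineation.** The air-filled lumen is removed by thresholding:
   the wall is `W = M ∩ {I ≥ τ}` with τ = −500 HU, midway between air
   (≈ −1000 HU) and soft tissue.
2. **Centerline.** *M* is resampled to a 1 mm isotropic grid; the
   centerline is the geodesic between the two tube ends (found by a double
   graph-distance sweep over the 26-connected voxel graph), with edges
   penalized by the inverse squared interior Euclidean distance transform so
   the path rides the medial axis. It is smoothed, parameterized by arc
   length *s*, and oriented superior → inferior.
3. **Straightening** (curved planar reformation). Square planes are sampled
   orthogonally to the centerline every 2.5 mm, on parallel-transported
   frames that do not spin in-plane.
4. **Per-plane morphometry.** On each wall cross-section, with hole-filled
   area `A_f` and enclosed lumen area `A_l`:
   `D_outer = 2√(A_f/π)`, `D_lumen = 2√(A_l/π)`, thickness
   `t = (D_outer − D_lumen)/2`; an EDT medial-ridge thickness is computed as
   a cross-check.
5. **Segments.** From the superior starting point: upper = first 5 cm,
   middle = next 10 cm, lower = the remainder. Per segment the pipeline
   records the number of planes and the mean, sample variance and maximum
   of diameter and wall thickness.
6. **Classification.** A CART decision tree (Gini, depth ≤ 3, ≥ 5 cases
   per leaf, balanced class weights) maps each segment's features to a
   cancer probability; a patient is positive iff any segment is
   (probability ≥ 0.5 by default).
7. **Evaluation.** From confusion counts (TP, TN, FP, FN):
   sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
   precision = TP/(TP+FP), FNR = 1 − sensitivity, FPR = 1 − specificity,
   F1 = 2·recall·precision/(recall+precision), accuracy = (TP+TN)/total,
   and for binary calls the single-operating-point AUC
   (sensitivity + specificity)/2. Continuous scores get the rank
   (Mann–Whitney) AUC, paired models DeLong's test, inter-rater agreement
   ICC(2,1), and segmentations Dice and Hausdorff distance (mm).

## Worked example

A 250 mm curved phantom with a focal +4 mm thickening centred at 80 mm
(middle segment), measured with the default configuration:

```r
library(esoMorph)
spec <- phantomSpec(
  lesions = list(lesionSpec("focal_thickening", center_arc_mm = 80,
                            extent_mm = 30, delta_thickness_mm = 4)),
  seed = 7L)
ph  <- generatePhantom(spec)
cfg <- defaultPipelineConfig()
fx  <- caseFeatures(ph$ct, ph$mask, cfg)
fx$features[, c("segment", "n_planes", "mean_thickness_mm",
                "var_thickness_mm2", "max_thickness_mm")]
#>   segment n_planes mean_thickness_mm var_thickness_mm2 max_thickness_mm
#> 1   upper       19              3.14            0.2860             5.11
#> 2  middle       40              4.02            2.9321             7.23
#> 3   lower       39              3.01            0.0364             3.34
```

The middle segment carries the lesion: its thickness variance (2.93 mm²) is
an order of magnitude above the lesion-free segments and its maximum
thickness (7.23 mm) reflects the 3 mm baseline + 4 mm lesion. A 40-phantom
cohort cross-validated end to end:

```r
coh <- generateCohort(20, 20,
                      effect = list(kind = "focal_thickening",
                                    delta_range = c(3, 6),
                                    extent_range = c(20, 50)),
                      seed = 11)
res <- runExperiment(coh, cfg, k = 5)
unlist(res$metrics[c("sensitivity", "specificity", "auc", "f1")])
#> sensitivity specificity         auc          f1
#>           1           1           1           1
res$localization_accuracy
#> [1] 1
```

At these effect sizes (≥ 3 mm added thickness) the tree separates lesioned
from clean phantoms perfectly and localizes every detected lesion to the
correct segment.

A thin CLI over the same functions ships in `inst/cli/esomorph.R`
(subcommands `phantom`, `measure`, `features`, `train`, `predict`,
`evaluate`; global `--config`, `--seed`, `--verbose`).

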