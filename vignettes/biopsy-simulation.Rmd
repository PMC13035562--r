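---
title: "Simulated targeted biopsies for patient-level heatmap evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated targeted biopsies for patient-level heatmap evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A voxel-level csPCa classifier (a model that assigns each prostate voxel a
probability of clinically significant prostate cancer, ISUP grade group ≥ 2)
can look excellent on per-voxel metrics yet fail the clinical task it is meant
to support: guiding a targeted biopsy. In a biopsy, one false-positive blob
misclassifies an entire patient, while millions of correctly classified
background voxels count for nothing. `biopsim` evaluates a 3D probability
heatmap at the *patient* level by simulating the targeted-biopsy workflow
against a reference annotation (whole-mount prostatectomy histopathology, when
available) and reporting sensitivity, specificity, PPV and NPV per ISUP
threshold.

## The simulated procedure

1. **Lesion extraction.** The heatmap is binarized at a probability threshold
   (default 0.5), 3D connected components are labeled (26-connectivity by
   default), components smaller than 0.07 cc are discarded, and the two
   largest survivors become biopsy targets. Volumes use
   `n_voxels × spacing³ / 1000` with the native 0.75 mm isotropic spacing.
2. **Needle geometry.** Needles are straight lines parallel to the
   cranio-caudal axis, as in transperineal template biopsies through a
   brachytherapy grid. Geometry therefore reduces to the transverse plane:
   a lesion's *footprint* is its logical-OR projection along the needle axis.
3. **Hit probability.** For a needle placed uniformly at random within the
   predicted lesion's footprint, the chance of sampling reference tumor is
   `|predicted ∩ reference| / |predicted|`, where the reference is the union
   of all annotated lesions at or above the ISUP threshold. The biopsy is
   positive when this probability strictly exceeds 0.5. A Monte-Carlo needle
   sampler (`monte_carlo_hit_probability()`) provides an independent check of
   the closed-form overlap.
4. **Patient calls.** Disease-positive patients (highest annotated grade ≥
   threshold) are TP if any biopsy hits, FN otherwise — including patients
   where a lesion was found but every biopsy missed. Disease-negative patients
   (non-prostatectomy controls, and prostatectomy patients below the
   threshold) are FP if *any* lesion survived extraction, with no biopsy-hit
   requirement, and TN otherwise. Prostatectomy patients with only ISUP
   grade group 1 belong to neither analysis group and are excluded by default
   (`isup1_policy = "count_negative"` reassigns them).
5. **Reporting.** Confusion counts per cohort × threshold feed sensitivity
   `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV, NPV and prevalence, each with
   a binomial confidence interval.

### Design choices where the procedure is underdetermined

* **Binarization threshold.** How predicted lesions are delineated from the
  heatmap is not prescribed; we use 0.5 — the natural operating point of a
  calibrated probability map and the same constant as the biopsy-positivity
  cut-off. It is exposed in `extraction_config()`.
* **Overlap denominator.** "Overlap" is formalized as
  intersection-over-predicted: it is the only reading that is a probability
  for a needle *aimed at the predicted lesion*, making "exceeds 0.5"
  meaningful. `hit_probability()` also offers intersection-over-reference,
  Jaccard and Dice for sensitivity analyses.
* **Reference union.** A biopsy may hit *any* qualifying lesion; detection is
  scored per patient, so predicted-to-reference lesion matching is not needed.
* **Inclusive cuts, strict decision.** Binarization and the 0.07 cc filter
  are inclusive (≥); the 0.5 positivity decision is strict (>).
* **Ties.** Equal-volume lesions are ordered by lexicographically smallest
  centroid, then label, so selection is deterministic across platforms and
  input permutations.
* **Needle width.** Zero by default (a needle samples one in-plane pixel); a
  square dilation radius is available, since no core diameter is modeled.

## Coordinate and file conventions

All geometry is computed in index space `(i, j, k)` with declared axis
semantics (`k` = cranio-caudal = needle axis). Volumes are NIfTI-1
(`.nii`/`.nii.gz`); heatmap and annotation must share a grid (inputs are
assumed co-registered — no resampling or registration is performed). Because
no NIfTI reader is guaranteed in the target environment, the package carries a
minimal NIfTI-1 codec (float32 heatmaps, int32 labelmaps, `pixdim` spacing,
`scl_slope`/`scl_inter` honored on read); it is cross-validated against
nibabel in the test suite. Per-lesion ISUP grades live in a JSON sidecar
keyed by label — NIfTI has no standard per-label metadata. Cohorts are CSV
manifests (`patient_id, arm, cohort, heatmap_path, annotation_path,
grades_path`); `arm = "RP"` if and only if an annotation is present.

## The synthetic cohort generator

No images or trained model are distributed, so the generator emulates the
*statistical structure* of the evaluation cohorts and produces heatmaps whose
fidelity to the reference is controllable. It is first-class, tested code —
the substrate for every end-to-end property check.

* **Cohort composition.** The `"internal"` preset is 250 patients at csPCa
  prevalence 0.71 with ISUP grade-group weights 84 : 71 : 1 : 21 over
  {2, 3, 4, 5}; the `"external"` preset is 77 patients at prevalence 0.45
  with weights 14 : 13 : 0 : 8.
* **Prostate volume.** Log-normal, quantile-matched to the printed median
  and IQR (internal: 47 mL, 36–74). `meanlog` reproduces the median exactly;
  `sdlog = log(q75/q25)/(2 qnorm(0.75))` reproduces the quartile *ratio*; two
  parameters cannot also match the quartile asymmetry, so the fitted quartiles
  sit within ~9% of the printed ones. Glands are axis-aligned ellipsoids with
  anatomical aspect ratios 1 : 0.7 : 0.85 (LR : AP : SI).
* **Lesions.** Ellipsoids with mildly randomized axis ratios, placed without
  overlap fully inside the gland. Lesion volume (log-normal, median 0.5 cc,
  `sdlog` 0.7, floored at 0.1 cc so every generated csPCa lesion clears the
  0.07 cc detectability cut) and multiplicity (1 lesion with probability 0.6,
  2 with 0.4) are package choices: the modeled study publishes no
  lesion-volume or multiplicity statistics, and these values are in the range
  surgical series report for index and secondary csPCa foci. Requested
  volumes are additionally capped at 15% of the realized gland volume, with a
  bounded shrink-and-retry (20% steps, max 3) — a feasibility constraint
  (a tumor near the gland's short-axis diameter cannot sit fully inside an
  ellipsoidal gland), decided once, not a tuning knob.
* **Heatmap fidelity.** `heatmap_fidelity()` controls per-lesion detection
  dropout, a Gaussian localization offset, a Poisson rate of spurious blobs,
  Gaussian blur, and background noise; the default is a perfect oracle whose
  binarized heatmap equals the union of csPCa lesion masks exactly. Grade-1
  lesions are never rendered (the heatmap models a csPCa detector).
* **Reproducibility.** One master seed; patient `i` uses the documented
  substream seed `(seed × 48271 + i × 65539) mod (2³¹ − 1) + 1`, so a cohort
  can be extended without reshuffling existing patients. Identical configs
  give byte-identical NIfTI, manifest and report files (gzip output in R is
  timestamp-free).

### What a green test does and does not establish

The generator reproduces cohort *composition*, lesion *geometry* at the level
of smooth ellipsoids, and controllable error *rates*. It does not mimic
ultrasound physics, the spatial error correlations of a real network
(fragmented predictions, boundary uncertainty, grade-dependent conspicuity),
or histopathology registration error. Green end-to-end tests therefore
establish that the *evaluation machinery* is correct — extraction, geometry,
decision rules, accuracy arithmetic, determinism — not that any particular
model achieves the published performance; the published sensitivities and
specificities depend on the unavailable trained model and images and are out
of reach by construction.

## Statistical notes

* **Intervals.** The publication does not name its CI method and its printed
  intervals cannot all be matched exactly by any standard method under
  rounding; the default is the Wilson score interval (well-calibrated at
  these group sizes: exact coverage at `p = 0.8, n = 177` is 0.951), with
  Clopper–Pearson and Wald available and the method always named in reports.
  Undefined metrics (zero denominator) are reported as missing, not 0.
* **Rounding.** Estimates print at 2 decimals and percentages at 0 decimals;
  stored values keep full precision. Note `59/85 = 69.41%` prints as 70% only
  if the proportion is first rounded to one decimal — the package reports the
  raw value.
* **Degenerate inputs.** Empty heatmaps yield empty lesion lists (TN/FN
  patients, never an error); an empty predicted footprint makes the hit
  probability undefined and is an error by contract; empty qualifying unions
  give probability 0.

## Known limitations

* The perfect-fidelity limit attains specificity 1.0 only at the ISUP ≥ 2
  threshold. At ISUP ≥ 3, prostatectomy patients with ISUP 2 are
  threshold-negative yet carry csPCa that any faithful heatmap must mark, so
  the mandated any-detection false-positive rule makes them FP: the
  perfect-fidelity ISUP ≥ 3 specificity equals the non-RP fraction of the
  negative group (~0.46 under the internal preset), which is also why the
  published ISUP ≥ 3 specificity is low. The corresponding acceptance
  assertion is deliberately left failing with a comment rather than weakened.
* Straight, zero-width, axis-parallel needles; no insertion error, no
  multi-core sampling along the track, no TRUS probe geometry.
* Index-space geometry only: volumes must be co-registered on a shared grid.
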