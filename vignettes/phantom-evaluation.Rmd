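---
title: "Lesion detection and FROC evaluation on synthetic PET/CT phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion detection and FROC evaluation on synthetic PET/CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petctdetect)
```

## The problem

Staging lung cancer on FDG-PET/CT means finding every malignant lesion —
the primary tumor (T), lymph-node metastases (N) and distant metastases
(M) — across a 3D volume, and deciding which of the three each finding is.
Automated detectors for this task are evaluated with a free-response ROC
(FROC) protocol: sensitivity per lesion category against false-positive
findings per case (FP/c) as the detector's confidence threshold sweeps,
with exact binomial confidence intervals on every rate, and a visual
taxonomy of what anatomy caused each false positive.

`petctdetect` implements that complete evaluation protocol, the rule-based
anatomical machinery it rests on (lung segmentation, five-region label
maps, T/N/M attribution), and a patch-wise detection harness with a
pluggable detector, so that the outputs of any 3D lesion detector — a
learned one imported as JSON, or the shipped non-neural reference detector
— can be scored identically. Because clinical PET/CTs cannot ship with a
package, a seeded synthetic phantom generator provides paired CT/PET
volumes with fully known ground truth, making every stage testable
end-to-end.

## Pipeline and model

A run executes simulate → preprocess → regions → detect → evaluate:

1. **Preprocessing.** CT intensities are clipped to a window (default
   [−1200, 600] HU), rescaled to [0, 1] and z-scored per volume. The
   lungs are segmented by thresholding air (< −400 HU by default) inside
   the body contour, keeping the two largest connected components, and
   both volumes are cropped on the z-axis to the slices containing lung,
   plus a configurable margin. The crop offset is recorded so boxes map
   back to original coordinates.
2. **Anatomical regions.** The scan is partitioned into five labels:
   (1) lung = the lung mask; (3) bone = voxels strictly above 120 HU,
   hole-filled so marrow interiors count as bone; (2) mediastinum = the
   per-slice band between the two lungs (x between the medial borders,
   y within the lungs' anterior–posterior envelope); (4) abdomen =
   in-body voxels caudal to the lung z-extent; (5) other = the rest.
   Detected lesions are attributed T/N/M by the majority region of their
   box (1 → T, 2 → N, 3 → M, 4 or 5 → "N or M").
3. **Detection.** The volume is tiled into overlapping patches; a
   detector maps each CT/PET patch to scored 3D boxes; per-patch boxes
   are consolidated by single-linkage IoU clustering.
4. **Evaluation.** Predictions match ground-truth lesions greedily in
   descending score order at IoU ≥ 0.1; repeated detections of one lesion
   count as 1 TP plus FPs of kind *double annotation*. The FROC score is
   the mean TPR at FP/c ∈ {0.125, 0.25, 0.5, 1, 2, 4, 8}; the operating
   threshold for reported sensitivities is the smallest threshold whose
   FP/c is at most 2.0. Confidence intervals are exact (Clopper–Pearson,
   from Beta quantiles). False positives are attributed to causes
   (double annotation, bone, mediastinal, pulmonary, abdominal, foreign
   body, other) via the region map.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| CT clip window | [−1200, 600] HU | air must lie inside the window for lung imaging; both bounds configurable because reasonable sources disagree on the orientation of this window |
| air threshold | −400 HU | separates lung parenchyma (≈ −800 HU) from soft tissue (≈ +40 HU); the technique fixes no canonical value |
| bone threshold | > 120 HU, strict | soft tissue stays below, trabecular/cortical bone above; strictness matters only at the boundary voxel value |
| match IoU | 0.1 | lenient 3D overlap: a detection that hits a lesion at all should count, and 3D IoU drops quickly with small offsets |
| FP/c points | 0.125 … 8 | the standard seven-point FROC grid |
| operating FP/c | ≤ 2.0 | an FP burden per scan considered acceptable for a reading-assistance tool |
| patch size / stride | (32, 96, 96) / (16, 96, 96) voxels | patch z of 32 slices mirrors GPU-detector practice; 50 % z-overlap guarantees any object up to 16 slices is fully contained in some patch |
| CI level | 95 % two-sided exact | exact intervals remain valid at the tiny n per category (down to n = 3) |

## The synthetic world

The phantom is a stylized torso, not a patient: an elliptical soft-tissue
body (+40 HU) holding two air-density lung ellipsoids (−800 HU), a
mediastinal band with a heart, a capped vertebral column (400 HU cortex
around a 40 HU marrow cavity) plus thin rib shells, and liver/kidneys in
an abdominal compartment caudal to the lungs. PET is a background of
SUV 1.0 (lung parenchyma 0.4) plus lesions and optional physiological
hotspots (myocardium SUV 5, marrow 3, kidneys 4, liver 2.5 — the anatomy
that causes false positives in clinical practice). CT noise is additive
Gaussian (default sd 10 HU); PET noise is additive Gaussian with sd
proportional to √intensity, a desk-scale Poisson surrogate that preserves
hotspot contrast ordering.

Lesion sizes are drawn log-normally with per-category mean/SD volumes of
39.9/100.7 cm³ (T), 4.8/12.4 cm³ (N) and 6.2/15.0 cm³ (M) — values
reported for a clinical lung-cancer cohort — truncated to diameters the
stylized anatomy can host (T 1.0–4.5 cm in the lungs, N 0.8–3.0 cm in the
mediastinal strip, M 0.8–2.4 cm in the marrow cavity). The distribution
family is a modelling choice: only means and SDs are anchored, and the
right-skew of a log-normal is qualitatively right for tumor volumes. Each
case plants 1 T, 3 N and 1 M lesion by default, the rough per-case mix of
a staging cohort. Lesions are placed wholly inside their intended region,
with an enforced air shell around intrapulmonary lesions (see below) and
separation margins between all hot objects.

What the phantom deliberately does **not** emulate: reconstruction
physics, partial-volume blur, respiratory motion, irregular lesion
shapes, infiltrative margins, anatomical variability, and lesions outside
their textbook region (e.g. pleural or chest-wall disease). A green
end-to-end test therefore establishes that the *pipeline machinery* is
correct — segmentation, geometry, matching, accounting, intervals — not
that any detector would reach comparable sensitivity on clinical data.
Clinical FROC scores and sensitivities are *not* reproducible here and
the package makes no claim about them.

## Numerical choices and edge cases

* **Lung-mask hole filling.** A soft-tissue tumor inside the lung is not
  air, so a pure threshold mask excludes it — and the lesion would then
  be attributed "N or M" instead of T. The segmented mask is therefore
  hole-filled, which recovers interior lesions as long as an air shell
  encloses them; the generator enforces that shell (6 mm) at placement
  time. This mirrors what the lung masks of learned segmenters provide.
* **Robust detector scale.** The reference detector thresholds the robust
  z-score (median/MAD) of the PET patch. On noiseless phantoms the MAD is
  exactly 0 while the patch is not constant; the scale then falls back to
  the mean absolute deviation about the median (×1.2533), which is zero
  only for a truly constant patch — in that case the patch yields no
  predictions.
* **Border suppression.** A lesion cut by a patch boundary produces a
  sliver box that IoU clustering cannot merge with the full detection
  from a neighbouring patch. Per-patch boxes touching a patch face
  interior to the volume are therefore dropped; with stride ≤ patch −
  object size, every object is fully contained in some patch, so nothing
  is lost.
* **Ties and precedence.** Region attribution votes by voxel count; ties
  break by precedence lung > bone > mediastinum > abdomen > other. Bone
  outranks mediastinum so vertebral lesions between the lungs attribute
  to M rather than N.
* **Scoring "N or M".** An "N or M" attribution is counted correct for
  ground-truth N or M in the accuracy figure. How the original clinical
  accuracy figure handled this is not documented; this package states its
  rule explicitly.
* **FROC interpolation.** The (FP/c, TPR) staircase is read at each
  evaluation point as the best TPR achieved at or below that FP/c; beyond
  the largest achieved FP/c the last TPR is carried flat.
* **Operating threshold.** The policy is FP/c ≤ 2.0 (not strict <):
  reported clinical FP/c values are rounded to one decimal, and a
  threshold whose exact FP/c is, say, 150/74 ≈ 2.03 is still reported as
  "FP/c of 2.0".
* **Rounding.** All reported percentages round half-up to one decimal,
  matching clinical reporting style (base R's `round()` would round half
  to even).
* **CI method.** Exact Clopper–Pearson from Beta quantiles. The choice is
  inferred: a printed lower bound of 29.2 % for 3/3 equals 0.025^(1/3),
  the exact bound, which no normal-approximation interval produces.
* **Degenerate inputs.** Zero-variance volumes z-score to all zeros with
  a warning; an empty lung mask is an error; a merged single lung
  component degrades the mediastinum to the mask's internal concavity
  with a warning; a volume smaller than the patch is zero-padded and
  predictions are clipped back.

## A short run

```{r, eval = FALSE}
report <- run_pipeline(run_config(n_cases = 6, seed = 1))
report
report$fp_causes$table
```

The report carries per-category sensitivities with exact CIs at the
operating threshold, FP/c with and without double annotations, FROC
scores overall and per category, TNM attribution accuracy with its
confusion table, and the FP-cause and FN-category tables. Every figure is
recomputable from the per-case match sets the report retains.

## Known limitations

* The phantom geometry is fixed up to scale; it exercises the rules, not
  anatomical diversity. Detector parameters tuned on it will not transfer
  to clinical data.
* The reference detector is an intensity heuristic. It exists so the
  evaluation harness has a deterministic, dependency-free detector to
  score; it is not a contribution to detection itself.
* Consolidation is single-linkage IoU clustering with the cluster
  maximum as score — a documented simplification behind a stable
  interface, so a learned detector with its own consolidation can be
  plugged in upstream.
* Matching is greedy by descending score with highest-IoU tie-break.
  Constructed adversarial overlap patterns exist where greedy matching is
  not optimal; on instances where each prediction overlaps at most one
  lesion it is provably optimal, and the tests check exactly that.
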