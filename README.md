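# petctdetect

Automated lung-cancer assessment on FDG-PET/CT, built for people who
develop or validate 3D lesion detectors: the complete FROC evaluation
protocol used in clinical detection studies, the rule-based anatomical
machinery around it, and a synthetic phantom generator so that the whole
pipeline runs and is tested without clinical data.

## What it does

Staging lung cancer means detecting every malignant lesion — primary
tumor (T), nodal (N) and distant (M) metastases — in a co-registered
CT (Hounsfield units) / PET (SUV) volume pair, and scoring a detector
honestly. The package provides:

* **Preprocessing** — CT clipping to [−1200, 600] HU, rescaling to
  [0, 1], per-volume z-scoring; threshold + connected-component lung
  segmentation; z-axis cropping to the lung slices with an invertible
  offset.
* **Five-region anatomy** — lung / mediastinum / bone (> 120 HU,
  hole-filled) / abdomen / other label maps from CT plus the lung mask,
  and majority-vote T/N/M attribution of detected lesions.
* **Detection harness** — overlapping-patch tiling, a pluggable patch
  detector (a robust-z-score reference detector ships; external
  detector outputs import as JSON), and IoU-based consolidation of
  per-patch boxes.
* **Evaluation** — greedy box matching at IoU ≥ 0.1 with the
  double-annotation rule (a lesion detected three times is 1 TP + 2 FP),
  sensitivity per category with exact Clopper–Pearson 95 % CIs, FP/c
  with and without double annotations, the FROC score
  (mean TPR at FP/c ∈ {0.125, 0.25, 0.5, 1, 2, 4, 8}), the operating
  threshold at FP/c ≤ 2.0, FP-cause attribution through the region map,
  and the FN category breakdown.
* **Synthetic phantoms** — seeded, paired CT/PET torso phantoms with
  known region truth, planted T/N/M lesions whose volumes follow
  clinical per-category statistics, and physiological hotspots
  (myocardium, bone marrow, kidneys, liver) that generate realistic
  false positives.

Volumes are exchanged as NIfTI (`.nii` / `.nii.gz`), predictions and
truth as JSON, tables as CSV. Arrays use (z, y, x) axis order; boxes are
0-based, half-open `[min, max)`.

## Worked example

```r
library(petctdetect)
report <- run_pipeline(run_config(n_cases = 6, seed = 1))
report
```

```
<study_report> 6 cases, 30 lesions
  operating threshold: 0.349 (FP/c 2.00; 2.00 excluding double annotations)
  sensitivity overall  100.0% (95% CI: 88.4-100.0%, n = 30/30)
  sensitivity T        100.0% (95% CI: 54.1-100.0%, n = 6/6)
  sensitivity N        100.0% (95% CI: 81.5-100.0%, n = 18/18)
  sensitivity M        100.0% (95% CI: 54.1-100.0%, n = 6/6)
  FROC score (all lesions): 0.943
  TNM attribution accuracy: 100.0% (30/30)
```

Six phantoms with default noise and hotspots: all 30 planted lesions are
found at the operating threshold (the smallest score threshold keeping
FP/c ≤ 2), each is attributed to the correct T/N/M category through the
computed region maps, and the CIs show what n = 6 per category is worth.
The FROC score of 0.943 < 1 reflects hotspot false positives at the two
lowest FP/c points. Where the FPs come from:

```r
report$fp_causes$table
#>               cause n percent
#>   double_annotation 0     0.0
#>                bone 0     0.0
#>         mediastinal 6    50.0
#>           pulmonary 0     0.0
#>           abdominal 6    50.0
#>        foreign_body 0     0.0
#>               other 0     0.0
```

The twelve FPs the operating threshold admits are the myocardium
(mediastinal) and kidney (abdominal) hotspots — one of each per case —
exactly the anatomy planted to cause them.

A thin CLI over the same functions is installed under
`inst/cli/petctdetect.R` with subcommands `simulate`, `preprocess`,
`regions`, `detect`, `evaluate` and `run-all`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch against the installed package:
it simulates a seeded phantom cohort, runs preprocessing, region
segmentation, patch-wise detection and the complete FROC/sensitivity/CI
evaluation, prints the study report, and writes the JSON result file.

## Scope

The package evaluates detectors; it does not train them. The neural
detector whose outputs such a harness would typically score is exactly
what plugs in through `import_external_predictions()`. Clinical
performance figures require clinical data and a trained model, and are
out of scope — see the methods vignette
(`vignettes/phantom-evaluation.Rmd`) for what the phantom world does and
does not establish.
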