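# nervePNI

Rule-flow detection of perineural invasion (PNI) in H&E histology images.

PNI — tumor cells invading in, around, and through a nerve — is an adverse
prognostic feature of oral-cavity squamous cell carcinoma, and one that is
easy to overlook on a gigapixel whole-slide image. `nervePNI` implements a
two-stage detector for pathologists' workflows and for methods work on
per-structure detection:

1. **Segmentation.** A compact multi-resolution encoder–decoder (parallel
   branches at full, 1/2, 1/4, … resolution; stride-2 convolutions down,
   bilinear upsampling up; all branches concatenated ahead of a sigmoid
   head) maps 256 × 256 RGB tiles at 0.23 µm/px to per-pixel probability
   maps — one model for nerve fibers, one for PNI signal. Training (Adam,
   lr 0.001, per-pixel MSE against the binary mask) and tiled
   whole-image inference are included, with the forward/backward passes
   implemented in-package (im2col + GEMM convolutions in C++).
2. **Rule flow.** Domain-knowledge post-processing turns the two maps into
   per-nerve calls:
   - nerve map → Gaussian-pyramid smoothing → threshold → morphological
     opening/closing → nerve structures;
   - PNI map → threshold at `max(0.5, Otsu)` → connected components →
     **size filter** (`area ≤ cutoff` removed) → retained components;
   - a nerve is called PNI iff a retained component lies within a
     Chebyshev adjacency distance (default 5 px) of its pixels.

   The size cutoff is calibrated as the nearest-rank (1−α) quantile of an
   observed sample of spurious "irregular component" areas: at α = 0.10
   the filter removes 90 % of them. At the reference geometry
   (0.23 µm/px, 13.5 µm tumor cells) the calibrated cutoff of 21,632 px²
   corresponds to ~8 cells — the detection limit of the flow:

   cells(area) = area · mpp² / (π (d/2)²).

Evaluation utilities score per-nerve decisions against ground truth
(greedy overlap matching → confusion matrix → sensitivity / specificity /
accuracy with the clinical display conventions), sweep the size-filter
cutoff, and analyze diagnostic-time tables. A seeded synthetic-scene
generator (elliptical nerves with perineurium rings, hex-packed tumor-cell
nests crossing the perineurium, calibration noise blobs, and small
perineural false-signal specks) makes the whole pipeline testable without
clinical data.

## Worked example

```r
library(nervePNI)

spec  <- SceneSpec(seed = 11)          # 960x960 px, 4 nerves, half with PNI
scene <- generateScene(spec)
scene
#> SyntheticScene: 960 x 960 px, 4 nerves (2 PNI), 11 noise objects

# simulate the segmentation stage, then calibrate the size filter on the
# scene's irregular-component areas
maps  <- sceneToProbabilityMaps(scene, blurSigma = 1, noiseSd = 0.05, seed = 2)
calib <- calibrateCutoff(scene@noiseAreas, alpha = 0.10)
calib
#> SizeFilterCalibration: n = 11, alpha = 0.10 -> cutoff 20369.64 px^2
pixelsToCells(calib@cutoffPx2)$cells   # cutoff in tumor-cell equivalents
#> [1] 7.528036

res <- runDecisionFlow(maps$nerve, maps$pni,
                       DecisionConfig(sizeCutoffPx2 = calib@cutoffPx2))
nerveTable(res)[, c("id", "area_px2", "predicted_class", "n_supporting")]
#>   id area_px2 predicted_class n_supporting
#> 1  1     9600             PNI            1
#> 2  2    11823             PNI            1
#> 3  3    16423          normal            0
#> 4  4    11983          normal            0

metrics(matchStructures(res, scene))
#> MetricsReport: sensitivity 100.00%  specificity 100.00%  accuracy 100.00%
```

The decision result also carries every intermediate artifact (masks,
component tables, removed components) for audit. Nine of the thirteen PNI-map
components here were spurious noise below the calibrated cutoff; with the
filter disabled (`sizeCutoffPx2 = 0`) the perineural specks planted by the
generator turn into false-positive calls — the trade-off the cutoff sweep
(`cutoffSweep()`) quantifies.

A command-line interface wrapping the same functions is installed under
`exec/nervepni` (subcommands `simulate`, `tile`, `calibrate`, `decide`,
`evaluate`, `timing`, `train`, `infer`).

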