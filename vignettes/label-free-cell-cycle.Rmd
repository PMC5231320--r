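---
title: "Methods: label-free cell-cycle classification from imaging flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free cell-cycle classification from imaging flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcml)
```

## The problem

Imaging flow cytometers record spatially registered multi-channel images —
bright-field (BF), dark-field/side-scatter (DF/SSC) and optional
fluorescence — for every cell in flow, at tens of thousands of cells per
run. `ifcml` implements an end-to-end, open workflow for one of the
signature applications of such data: predicting the cell-cycle phase of
each cell (interphase `Int` and the mitotic phases `Pro`, `Meta`, `Ana`,
`Telo`) from the label-free BF and DF channels alone, so that no
DNA-binding dye or mitotic antibody is needed at analysis time.

The workflow has five stages, each usable on its own:

1. **Container and tiling** (`write_imageset()`, `pack_montages()`) — a
   portable per-cell multi-page TIFF + CSV manifest container, and lossless
   packing of single-cell frames into large montage tiles (about a
   thousand cells per tile) for image-wise batch processing.
2. **Quality gating** (`apply_gates()`) — keep in-focus cells by a
   gradient-RMS focus score on BF, then keep singlets by mask area and
   aspect ratio.
3. **Segmentation** (`segment_cell_frame()`) — one primary object mask per
   frame from the BF image.
4. **Feature bank** (`extract_feature_table()`) — per cell and channel:
   area/shape (including Zernike moments and Feret diameter), intensity,
   radial distribution, granularity spectrum and GLCM texture, about 95
   features for BF + DF, named `{CHN}_{Family}_{Name}` (`BF_*` /
   `SSC_*`).
5. **Imbalance-aware learning** (`build_training_set()`,
   `train_classifier()`, `cross_validate()`, `score_all()`,
   `confusion_matrix_pct()`, `rank_features()`) — undersampled training
   sets, gradient boosting and random forests, stratified 10-fold
   cross-validation, row-normalised percentage confusion matrices with
   per-class true-positive rates, and feature-importance rankings.

## The classification model

Phase frequencies in an asynchronous culture are proportional to phase
durations, so the class distribution is extremely skewed: thousands of
interphase cells for every anaphase cell. Training on raw frequencies
would let a classifier ignore the mitotic classes entirely. The package
therefore caps every class at `cap` training cells (default 100): abundant
classes are subsampled without replacement, minority classes keep all
members. The test set is every cell *not* in the training set, excluded
by id.

Two tree ensembles are provided:

* **Gradient boosting** — a stage-wise additive ensemble of shallow trees
  (depth 3, 300 stages, learning rate 0.1) fit to the gradient of the
  multiclass log-loss, via xgboost with a single thread and a fixed seed
  so runs are reproducible.
* **Random forest** — 500 bootstrap-bagged deep trees with `sqrt(p)`
  candidate features per split and majority vote.

These hyperparameters are deliberately unremarkable defaults for tabular
morphology features; both algorithms expose per-feature importance (gain
for boosting, mean Gini decrease for the forest), which drives
`rank_features()`.

Evaluation follows the field's convention: entry *(i, j)* of the confusion
matrix is the percentage of class-*i* cells predicted as class *j*; the
diagonal is the per-class true-positive rate (TPR), and rows with zero
support are reported blank and excluded from macro averages. Because the
rare classes sit entirely inside the capped training set, their TPRs are
estimated by stratified 10-fold cross-validation of the training set
(classes smaller than 10 contribute one member to as many folds as they
have cells); the held-out scoring of all remaining cells covers the
abundant classes.

## The synthetic study population

No instrument data ships with the package. Instead, `generate_population()`
draws a synthetic population whose *defaults are the study conditions* used
throughout the tests and the acceptance script:

* counts `Int = 300, Pro = 38, Meta = 16, Ana = 15, Telo = 25` — the rare
  mitotic classes keep literature-scale absolute counts (15 anaphase, 25
  telophase) while the abundant classes are scaled down so a desk-scale
  run preserves the qualitative imbalance (20:1 rather than 2000:1);
* 64-px square frames, additive Gaussian pixel noise of SD 0.01 on both
  channels;
* per-phase geometry: `Int`/`Pro` near-circular disks (radius 9 ± 1 px),
  `Meta` an elongated ellipse (eccentricity 0.88–0.95, area factor 0.7 —
  a condensed metaphase plate), `Ana` a wide-necked dumbbell
  (lobe radius 7 ± 0.6 px, separation 10 px, neck 6 px), `Telo` a
  well-separated dumbbell (radius 6 ± 0.6 px, separation 22 px, neck
  2 px);
* texture: multiplicative speckle on the BF body, with phase-specific
  grain (correlation length) and amplitude — fine, strong speckle for
  `Pro` (condensed chromatin), coarse and weak for `Int`; the DF channel
  is dark outside the cell and inside is proportional to the texture
  amplitude times a flat scattering baseline plus the positive part of
  the speckle field, so DF granularity tracks chromatin texture and a
  zero-amplitude cell produces an exactly dark DF frame.

The defaults were chosen once so that every phase pair differs by at
least three population standard deviations in at least one of
{DF `Granularity_1`, `Eccentricity`, `MaxFeretDiameter`, `Zernike_2_2`}
(measured at 50 cells per phase), mirroring the qualitative separability
that makes label-free classification possible on real data; they are not
claims about any particular cell line's geometry.

Contaminants for QC testing are generated on request as deterministic
fractions (`round(frac * n)`, so tests can assert exact counts): *debris*
(a 2-px disk), *doublets* (two touching disks at the interphase mean
radius — about twice a singlet's area) and *defocused* cells (a normal
cell blurred with a Gaussian of sigma 3 px). A single RNG stream seeded
from the configuration drives the whole population, making containers
byte-identical across runs.

What the generator does **not** emulate: optical point-spread functions,
illumination gradients, camera noise statistics, fluorescence channels,
touching-cell segmentation ambiguity, or true Jurkat morphology
distributions. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that phase-separable morphology is recovered
end-to-end — not that any particular accuracy will be attained on
instrument data.

## Quality gating

The focus score is `sqrt(mean(Gx^2 + Gy^2)) / mean(I)` over
central-difference gradients of interior BF pixels — scale-invariant by
construction, 0 for constant frames by convention. The exact focus metric
used by instrument vendors is unpublished; only monotone agreement with
defocus is claimed, which is what the gate needs.

Gates run in a fixed order — focus, then area (`DEBRIS` below `area_min`,
`TOO_LARGE` above `area_max`), then aspect ratio (`CLUMP`) — and each
rejected cell is annotated with the first gate it failed, mirroring how an
analyst gates sequentially on histograms.

The automatic focus threshold is **half the population median** of the
focus score. A fixed low percentile (the other supported mode) cannot
adapt to the actual contamination level: with 20 % defocused cells a 10th
percentile threshold necessarily splits the defocused mode and misses
half of it, while `0.5 x median` sits in the valley between the sharp and
sigma-3-blurred modes and keeps everything when no defocused mode exists.

Default area bounds are 50–460 px²: debris (~13 px²) falls below, doublets
(~508 px² by construction) above, and the widest legitimate interphase
draws (~415 px²) inside. The default aspect-ratio floor is 0.2 —
deliberately permissive, because metaphase plates at eccentricity 0.95
reach aspect ratios near 0.3 and must survive; doublets (aspect ~0.5) are
caught by the area gate instead.

## Segmentation

BF frames are inverted (cells are darker than background by container
convention; a flag flips this for other instruments), thresholded by
Otsu's criterion on the min–max-scaled frame (hence invariant to linear
intensity rescaling), closed with a disk of radius 2 (bridging thin
telophase midbodies), hole-filled, and reduced to the largest 8-connected
component; components below `min_area` (9 px) signal an empty mask and the
cell is gated out. Ties between equal-sized components resolve to the one
whose first pixel comes earliest in raster order. Otsu over adaptive
thresholding is a deliberate choice: each frame holds one cell on a
near-uniform background, and determinism matters more than local
adaptivity here.

## Feature bank: numerical choices

* **Axis lengths** are `4 * sqrt(eigenvalue)` of the second-central-moment
  matrix of pixel centres; eccentricity derives from their ratio.
* **Perimeter** is the traced boundary chain length (sqrt(2) per diagonal
  step); **Compactness** is `Perimeter^2 / (4 pi Area)`, dimensionless and
  1 for a circle (about 1.06 for a rasterised disk, from chain-length
  overestimation).
* **Zernike magnitudes** (orders 0–9, 30 values) are computed on the unit
  disk centred at the mask centroid with radius equal to the maximum
  centroid-to-pixel distance, normalised by the lattice-point count of
  that disk so a solid disk gives `Zernike_0_0 = 1`. A single-pixel mask
  returns the degenerate spectrum (`Z_0_0 = 1`, rest 0). On a rasterised
  disk the `m` = 4 and 8 harmonics keep residues of a few percent — the
  square lattice itself has 4-fold symmetry — which is why disk-based
  tests anchor `Z_2_2`, not `Z_4_4`.
* **Radial distribution** uses the normalised distance-transform
  coordinate `r = 1 - DT/max(DT)`, which stays well defined for
  non-star-shaped dumbbells where a centroid-ray parameterisation fails.
  Two choices depart from the obvious construction, both because
  rasterisation jitter would otherwise dominate the statistic: wedge
  boundaries are rotated half a wedge off the lattice's axis and diagonal
  rays (pixels lying exactly on those rays would otherwise be assigned
  asymmetrically), and `RadialCV` is the coefficient of variation of
  per-wedge *mean* intensities rather than wedge totals — with totals, a
  perfectly symmetric Gaussian on a disk already shows CV above 5 % in
  the innermost ring purely from unequal wedge pixel counts, while means
  isolate genuine angular asymmetry (CV below 1.5 % on the same fixture).
* **Granularity** is the classic opening-based spectrum: background-correct
  by subtracting the opening with a disk of radius 10, then report the
  percentage of remaining intensity removed by openings of radius 1–8.
  No downsampling is applied (frames are small). An image with zero
  corrected mass returns an all-zero spectrum by convention.
* **GLCM InfoMeas2** quantises masked pixels to 8 equal-width levels over
  the masked min–max range, accumulates a symmetric co-occurrence matrix
  over pairs with *both* pixels in the mask at offset (0, 3) — read from
  the conventional `_3_0` suffix as scale 3, direction 0 degrees — and
  returns `sqrt(1 - exp(-2 (HXY2 - HXY)))`. Degenerate inputs (constant
  intensities, no valid pairs) return 0. Note the statistic's direction:
  it approaches 0 for *independent* pixel pairs (the joint distribution
  factorises, so `HXY2 - HXY` vanishes) and rises toward 1 with
  dependence — perfectly anti-correlated binary stripes at half-period
  offset give exactly `sqrt(1 - exp(-2))` at 1 bit of marginal entropy.
* Non-finite feature values (e.g. an empty ring) are kept as explicit
  `NaN` sentinels and the cell is flagged; tree-ensemble training imputes
  them to 0 deterministically.

Features named `Orientation`, `Location` or `Center` carry no phase
information and are excluded by default before training, mirroring
standard practice.

## Problem sizes and determinism

All shipped experiments run on the default 394-cell population (plus a
394-cell contaminated population for QC and a 300-cell grain-contrast
population for feature-ranking sanity): large enough for stable
estimates of every reported quantity, small enough that the entire test
suite and the acceptance script each complete in about a minute on a
single core. Every stochastic step — simulation, subsampling, fold
assignment, both classifiers — is driven by explicit seeds, and the
pipeline writes byte-identical artifacts when re-run with the same
configuration.

## Known limitations

* Zernike, granularity and texture settings follow common conventions but
  are not bit-compatible with any specific desktop tool's output.
* The Haralick set is limited to InfoMeas2 (the texture feature that
  matters for this classification task); other GLCM statistics are out of
  scope.
* Segmentation assumes one cell per frame; multi-object frames are the
  QC gates' job to reject, not the segmenter's to resolve.
* Random-undersampling boosting variants, probability calibration and
  deep learning are intentionally out of scope.
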