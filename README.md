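# ifcml — label-free cell-cycle classification for imaging flow cytometry

Imaging flow cytometry (IFC) captures spatially registered multi-channel
images — bright-field (BF), dark-field/side-scatter (DF/SSC) and optional
fluorescence — for every cell in flow. `ifcml` is an open R toolkit for
the machine-learning analysis of such data, built around its signature
application: predicting each cell's cell-cycle phase (interphase `Int`
and the mitotic phases `Pro`, `Meta`, `Ana`, `Telo`) from the label-free
BF and DF images alone, with no DNA stain or mitotic marker at analysis
time.

The toolkit covers the full protocol:

1. **Portable container + montage tiling** — per-cell multi-page TIFF
   stacks with a CSV manifest, and lossless packing/unpacking of
   single-cell frames into ~1000-cell montage tiles for image-wise batch
   processing (`write_imageset()`, `pack_montages()`).
2. **Quality gating** — an in-focus gate on the BF gradient-RMS score
   `sqrt(mean(Gx² + Gy²)) / mean(I)`, then singlet gates on mask area and
   aspect ratio, with first-failure reasons (`apply_gates()`).
3. **Segmentation** — Otsu threshold on the inverted BF frame, closing,
   hole filling, largest 8-connected component (`segment_cell_frame()`).
4. **Feature bank** — ~95 features per cell over BF + DF under the
   `{CHN}_{Family}_{Name}` convention (e.g. `SSC_Granularity_1_DF_image`,
   `BF_AreaShape_Zernike_2_2`, `BF_Texture_InfoMeas2_BF_image_3_0`):
   area/shape with Zernike moments and Feret diameter, intensity,
   radial distribution (4 rings), granularity spectrum, GLCM InfoMeas2
   (`extract_feature_table()`).
5. **Imbalance-aware learning** — class-capped undersampled training sets,
   gradient boosting (300 shallow trees, multiclass log-loss) and random
   forests (500 bagged trees, √p features per split), stratified 10-fold
   cross-validation, row-normalised percentage confusion matrices whose
   diagonal is the per-class true-positive rate TPRᵢ = nᵢᵢ/nᵢ, and
   feature-importance rankings (`build_training_set()`,
   `train_classifier()`, `cross_validate()`, `confusion_matrix_pct()`,
   `rank_features()`).

A synthetic-cell generator (`generate_population()`) reproduces the
study conditions at desk scale — five phases with extreme imbalance
(300/38/16/15/25 cells), phase-dependent morphology and texture, plus
debris/doublet/defocus contaminants — so every stage is fully testable
without instrument data. Results are tibbles with `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Run the whole protocol on the default synthetic population (394 cells,
seed 42), with undersampling cap 100 and gradient boosting:

```r
library(ifcml)
res <- run_pipeline(pipeline_config(out_dir = "ifcml_out", seed = 42))
res$cv
#> <ifc_evaluation> (10-fold CV, gradient_boosting, n=194)
#>       Predicted
#> True     Int   Pro Meta    Ana Telo
#>   Int  99.00  1.00    0   0.00    0
#>   Pro   2.63 94.74    0   2.63    0
#>   Meta  0.00  0.00  100   0.00    0
#>   Ana   0.00  0.00    0 100.00    0
#>   Telo  4.00  0.00    4   0.00   92
#> macro TPR: 97.15%  accuracy: 97.42%

head(as.data.frame(res$ranking), 5)
#>   rank                                    feature      score
#> 1    1                  BF_Granularity_1_BF_image 0.29512205
#> 2    2 SSC_Intensity_IntegratedIntensity_DF_image 0.24594287
#> 3    3                     BF_AreaShape_Perimeter 0.21396091
#> 4    4                   BF_AreaShape_Zernike_2_2 0.11755170
#> 5    5               BF_AreaShape_MinorAxisLength 0.09369405
```

Each row of the confusion matrix is one true phase, normalised to 100 %;
the diagonal is that phase's true-positive rate, estimated by 10-fold
cross-validation of the capped training set (the rare anaphase and
telophase classes — 15 and 25 cells — live entirely inside it). Even
under 20:1 imbalance the rare mitotic classes stay detectable (TPR 100 %
and 92 % here), and the top-ranked features are granularity, size and
lobedness descriptors — the morphology that genuinely distinguishes the
phases. `autoplot(res$cv)` draws the confusion heat map;
`ifcml_out/` holds every stage artifact (container, montages, `qc.csv`,
`features.csv`, `confusion.csv`, `top_features.csv`, `pipeline.log`).

A thin command-line front-end is included at `inst/scripts/ifcml.R`
(`run-all`, `simulate`, `features`, `evaluate` subcommands).

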