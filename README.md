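# canopyseg

Pixel-wise segmentation of glasshouse and field plant images for
high-throughput phenotyping, plus chlorophyll (SPAD) estimation from the
segmented canopy.

Plant phenotyping pipelines must first split every image pixel into plant
vs. background. Color-index thresholds — excess green `ExG = 2G − R − B` or
`ExGR = ExG − (1.4R − G)` combined with Otsu's threshold — work on clean
scenes but break on cluttered field backgrounds (straw, stones) and on
leaves that turn yellow-brown under nutrient deficiency. `canopyseg`
implements the learning-based alternative for researchers building such
pipelines:

1. **24-channel color features** — each pixel is described in eight color
   spaces (RGB, HSV, YCbCr, Lab, YUV, Luv, HLS, XYZ), all rescaled to
   [0, 1], with optional gray-card white balance and hue calibration.
2. **Channel selection** — decision-tree recursive feature elimination
   (DT-RFE) ranks the 24 channels by Gini importance; channels above a 0.04
   importance threshold are kept (the packaged default is the 12-channel
   set R, G, H, S, Lab L/a, Luv v, YCbCr Y, YUV U, HLS h/l/s).
3. **Pixel classifiers** — a single-hidden-layer perceptron (20 ReLU
   neurons, logistic output, trained by backpropagation
   `W ← W − a · ∂E/∂W` on binary cross-entropy), plus random-forest
   (200 trees, depth ≤ 20, min leaf 4) and RBF-SVM (C = 0.001, γ = 1)
   baselines, and the ExG / ExGR + Otsu index baselines.
4. **Quality scoring** — `Qseg = |S∩R| / |S∪R|`, `Sr = |S∩R| / |R|`,
   `Es = |S∩¬R| / |R|` against reference masks, and accuracy / recall /
   F-score for pixel labels.
5. **SPAD regression** — eleven color vegetation indices (ExG, ExR, CIVE,
   ERI, DGCI, GR, COM1, …) from the segmented region, Pearson-correlated
   with SPAD readings; the top-5 indices feed a stagewise gradient-boosted
   regression-tree model with histogram split finding, reported with RMSE,
   MAE and adjusted R².
6. **Synthetic scenes** — a seeded generator renders glasshouse and field
   scenes with pixel-exact ground-truth masks, pure 20×20 labeled patches,
   and SPAD-linked cohorts, so the whole pipeline runs and is tested
   without any external image data.

## Worked example

Train the perceptron on synthetic field patches, segment a fresh cluttered
scene, and compare against the ExG + Otsu baseline:

```r
library(canopyseg)

cfg     <- scene_config(scene_type = "field")
patches <- generate_patchset(cfg, n_fg = 80, n_bg = 80, seed = 1)
ds      <- restrict_channels(assemble_patches(patches),
                             default_selected_channels())
parts   <- split_dataset(ds, split_spec(seed = 1))          # 3:1:1
fit     <- train_mlp(parts$train, parts$validation,
                     train_config(seed = 1, epochs = 25))
fit$report
#> <classification_report n=12800 acc=0.9932 P=0.9884 R=0.9981 F=0.9932>

scene <- generate_scene(cfg, seed = 99)
mask  <- segment_image(fit$model, scene$image)
segmentation_quality(mask, scene$truth)
#> <quality_scores 128x128: Qseg 0.978  Sr 0.995  Es 0.018>
segmentation_quality(otsu_mask(index_image(scene$image, "ExG")), scene$truth)
#> <quality_scores 128x128: Qseg 0.879  Sr 0.994  Es 0.131>

cvi_from_region(scene$image, mask)
#> <cvi_record mean RGB (57.5, 130.7, 56.8)>
#>    Green     Blue      ExG      ExR     CIVE      ERI     DGCI       GR
#> 130.7336  56.8158 147.1332 -50.2081 -40.0053 -51.4293   0.6375  73.2154
#>     COM1     GBRG      EGI
#> 304.4692  -1.0000   0.9905
```

The perceptron's validation accuracy is 99.3% on held-out pixels; on the
fresh scene it reaches Qseg 0.978 (foreground intersection-over-union)
with a 1.8% false-positive rate, while the ExG baseline loses a tenth of
its Qseg to straw clutter (Es 0.131). The CVI record holds the region's
mean color and the eleven indices used downstream for SPAD regression
(GBRG is −1 by construction of its literal formula and is excluded from
correlation ranking automatically).

A command-line interface covering the same pipeline
(`synth`, `extract-features`, `select-features`, `train`, `segment`,
`evaluate`, `cvi`, `spad-train`, `spad-predict`) is installed at
`inst/cli/canopyseg`; run it with `Rscript` and `--help` for usage.

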