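# ColonyQuant

Detection and quantification of stem-cell colonies co-cultured on a
feeder layer in phase-contrast microscopy images, plus the analytical
perfusion physics of the parallel-plate culture chamber such cultures
are grown in.

## Who this is for

Labs doing adherent stem-cell process development monitor culture
progress from daily phase-contrast images: how many colonies, how big,
what confluency. Human embryonic stem cell (hESC) colonies sit on a
feeder layer of inactivated fibroblasts, and the two populations differ
in *texture* rather than intensity — colonies are finely granular and
isotropic, the feeder background sparse and stroke-like. ColonyQuant
turns that difference into per-image culture statistics automatically.

## The method

Each pixel is classified colony/background from its local texture:

1. **Greyscale**: luminance = 0.290 R + 0.570 G + 0.140 B, kept in
   double precision; spatial calibration attached (2.86 µm²/pixel for a
   4× objective at 1280×960).
2. **Basic image features (BIFs)**: at scales σ = 0.7·(1, 2, 4, 8) the
   image is filtered with scale-normalised derivative-of-Gaussian
   kernels, and each pixel is assigned one of seven local-symmetry
   classes (flat, slope, dark/light blob, dark/light line, saddle) by
   maximising seven scores built from the filter responses; the flatness
   parameter ε = 0.11.
3. **Features**: a 7-bin class histogram over a 25×25 window per scale,
   concatenated into a 28-element count vector per pixel.
4. **Random forest**: 20 trees, 5 variables per split, majority vote →
   a raw binary colony map.
5. **Cleanup and metrics**: objects < 4000 px discarded, enclosed holes
   < 6000 px filled; components labelled; colony count, total/mean area
   (mm²) and confluency reported.

Masks are scored against reference annotations with the pixel F-score
`F = 2TP / (2TP + FP + FN)` and the confluency-error decomposition
bias / RMSE / precision (= √(RMSE² − bias²)).

Because no public image corpus exists for this assay, the package ships
a procedural generator of two-texture synthetic images with exact
ground-truth masks; the entire pipeline is trained and validated on it.
A separate module computes the perfusion numbers for the culture
chamber: wall shear τ_w = 6µQ/(h²w), shear at height z,
residence time V/Q, media-exchange rate and culture area.

## Worked example

```r
library(ColonyQuant)

# ten synthetic training images; 2e5 balanced labelled pixels
train <- makeTrainingSet(lapply(1:10, function(s) generatorConfig(seed = s)),
                         pixelsPerImage = 20000)
model <- trainColonyClassifier(train, nTrees = 20, mtry = 5, seed = 1)

# segment a held-out frame and compare with its ground truth
sim <- generateColonyImage(generatorConfig(seed = 1001))
res <- segmentImage(sim$image, model)
res$metrics
#> ColonyMetrics: 1 colonies, total 0.1732 mm^2, mean 0.1732 mm^2, confluency 24.2%

fScore(confusionCounts(colonyMask(res$map), sim$mask))
#> [1] 0.9936459
```

The metrics line says one colony was detected covering 24.2% of the
frame (areas are in mm² via the attached 2.86 µm²/px calibration), and
the F-score line says the predicted mask agrees with the generator's
ground truth on 99.4% (harmonic-mean sense) of colony pixels.

Perfusion arithmetic at the chamber's standard operating point:

```r
str(perfusionReport(perfusionConditions()))
#> List of 5
#>  $ wall_shear_Pa      : num 0.000132
#>  $ shear_at_z_Pa      : num 0.000123
#>  $ residence_min      : num 4.68
#>  $ exchange_ml_day_cm2: num 13.8
#>  $ area_cm2           : num 0.52
```

A thin CLI over the same functions is at `inst/scripts/colonyquant`
(verbs `train`, `segment`, `quantify`, `evaluate`, `simulate`,
`perfusion`).

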