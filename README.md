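# ScaffoldQuant

Quantifying osteocyte growth and type I collagen scaffold biodegradation
from stained optical micrographs.

Collagen sponges seeded with stem cells degrade as the cells differentiate
into osteocytes and deposit extracellular matrix. ScaffoldQuant implements
the full quantitative workflow for such experiments, for researchers in
biomaterials and bone tissue engineering:

1. **Texture features.** Every pixel is described by 24 features: for each
   of six colour channels (R, G, B, H, S, B), the raw intensity, the two
   eigenvalues of the smoothed structure tensor
   `J = [⟨fx·fx⟩_w, ⟨fx·fy⟩_w; ⟨fx·fy⟩_w, ⟨fy·fy⟩_w]`, and the local
   Shannon entropy of a circular intensity histogram.
2. **Segmentation.** A seeded probability random forest classifies each
   pixel into one of four regions of interest — background (0), type I
   collagen (1), extracellular matrix (2), nuclei (3) — producing per-class
   probability maps, with a grayscale thresholding baseline and a full
   multiclass validation suite (confusion matrix, per-class TP/FP rates,
   precision, F-measure, MCC, stratified 10-fold CV).
3. **Object features.** 8-connected components of a region yield area (µm²,
   default calibration 300/189 µm/px), contour circularity
   `4π·area/perimeter²`, equivalent-ellipse axes and the grayscale
   histogram mode.
4. **Kinetics and regression.** Percent mass loss over time is fitted with
   a k-component logistic mixture
   `Σ_i A_i / (1 + exp((µ_i − t)/scal_i))` (differential-evolution global
   start, bounded Levenberg–Marquardt refinement, residual-bootstrap CIs),
   a penalized B-spline smooth chosen by GCV, and linear models on
   log-transformed image features with lmg R² decomposition and k-fold
   predictive validation.

A seeded synthetic-micrograph generator with exact ground-truth masks makes
every stage testable without laboratory data.

## Worked example

```r
library(ScaffoldQuant)

## a 96 x 96 synthetic four-class micrograph with ground truth
g     <- generateMicrograph(syntheticImageParams(width = 96, height = 96,
                                                 seed = 7))
stack <- buildFeatureStack(g$micrograph)          # 96 x 96 x 24 features
train <- sampleTrainingPixels(stack, g$mask, nPerClass = 150, seed = 1)
model <- trainClassifier(train, nTrees = 150, seed = 1)
pred  <- classifyPixels(predictProbabilityMaps(model, stack))

confusionAndMetrics(g$mask, pred)$accuracy
#> [1] 0.976888  (fraction of pixels assigned to the correct region)

## extracellular-matrix objects and the per-image summary
obj <- extractObjects(pred == 2, minSizePx = 10)
summarizeImage(obj, g$micrograph, pred == 2, time = 0, group = "CCO")
#>   time_days group n_objects mean_area_um2 mean_circularity gray_mode
#> 1         0   CCO         5      1156.966        0.5843885       166

## kinetic fit: two-component logistic mixture on a noiseless curve
rec <- simulateMassLoss(c(50.223, 1.734, 1.000, 23.463, 16.261, 1.3233),
                        times = 0:44, noiseSd = 0)
fitMixture(rec, k = 2, seed = 1)
#> Logistic mixture fit, k = 2
#>  parameter estimate ...
#>        A_1  50.2230
#>       mu_1   1.7340
#>     scal_1   1.0000
#>        A_2  23.4630
#>       mu_2  16.2610
#>     scal_2   1.3233
#> R-squared (Kvalseth): 1
```

The mixture fit's two components separate overlapping degradation
processes: an early one (inflection near day 2, ~50% of mass) attributable
to cell-independent degradation, and a later one (inflection near day 16,
~23%) associated with cellular activity. `runPipeline(pipelineConfig())`
chains all stages — synthetic series or an image directory in, probability
maps, object tables, metric reports, fitted models and a seeded manifest
out.

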