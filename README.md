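# dermofuse

Melanoma screening from dermoscopy images by **hybrid + deep feature
fusion**. The package implements, end to end and in one place:

* **MADF** — modified anisotropic diffusion despeckling for the
  multiplicative noise model *I = G(1 + η)*, *η ~ N(0, σ²)*. The
  Perona–Malik update *F′ = F + λ Σ c(∇F)∇F*, *c(x) = exp(−(x/κ)²)*,
  runs until the extracted noise *n = (I₀ − F)/F* is Gaussian (excess
  kurtosis *k = m₄/m₂² − 3* inside a tolerance band) **and** the
  noise–estimate correlation ρ_G = corr(F, n) stops decreasing; SNR,
  MSE and the edge-preservation factor (EPF) quantify the result.
* **FBB** — fast bounding box: the below-median darkness map is
  projected on both axes and each axis is bracketed by the shortest
  interval holding 95% of the darkness mass (two-pointer linear scan),
  giving an unsupervised O(n) lesion box.
* **Hybrid features** — HOG (3780), uniform LBP histogram (59), SURF
  det-Hessian keypoints summarized into 13 fixed slots; fused to 3852
  dimensions with an explicit span manifest.
* **Deep features** — a VGG19-topology backbone (16 conv + 3 FC = 19
  weight layers, 5 max-pool stages) with seeded random weights, tapped
  at the first FC layer: 4096 post-ReLU features per image.
* **Fusion + entropy selection** — 3852 + 4096 = 7948 features; each
  column scored by the Shannon entropy (bits) of its 10-bin training
  histogram; the top 1280 are kept deterministically.
* **Classification** — ridge-logistic default head (pluggable decision
  tree / random forest / kNN / SVM / small dense net), confusion matrix
  with melanoma as the positive class, ACC/SEN/SPEC/PREC
  (ACC = (TP+TN)/total, SEN = TP/(TP+FN), SPEC = TN/(TN+FP),
  PREC = TP/(TP+FP)), and stratified 5-fold cross-validation with
  per-fold selector refitting (leak-free by construction).
* **Synthetic dermoscopy generator** — seeded scenes with ground-truth
  masks: darker irregular-border lesions on lighter skin, within-lesion
  texture, illumination ramp, multiplicative speckle. Two classes
  (melanoma / non-melanoma) differing in border irregularity, darkness,
  texture and asymmetry, so the entire pipeline is testable offline.

Who it is for: researchers who want a transparent, dependency-light R
implementation of this despeckle → localize → describe → fuse → select
→ classify pipeline, with every stage unit-tested against closed forms
or brute-force oracles.

## Worked example

```r
library(dermofuse)

## a speckled synthetic lesion and its despeckled version
b <- benchmarkScene(sigma = 0.2, seed = 7)
res <- madfFilter(b$noisy)
res$diagnostics
qualityMetrics(b$clean, res$image, b$noisy)

## localize, crop, featurize
box <- fbbDetect(res$image)
box
patch <- cropBox(res$image, box)
backbone <- buildBackbone(backboneSpec(seed = 1))
fv <- fuseAll(hfeFeatures(patch), extractDeepFeatures(backbone, patch)[1, ])
fv

## end-to-end on a small synthetic corpus
report <- runPipeline(25, pipelineConfig(seed = 1))
report$mean
```

Output (abridged):

```
FilterDiagnostics: 10 iterations, stopped by 'correlation_min'
  final excess kurtosis -0.1895, rho_G 0.08182

     which   snr_db         mse        epf
1 filtered 26.72192 0.001017392 0.53466805
2    noisy 14.65353 0.016380531 0.04573304

BoundingBox rows [21, 75) x cols [20, 77)  (54 x 57 px)

FeatureVector of length 7948
  hfe   [    0,  3852)  (3852 features)
  cnn   [ 3852,  7948)  (4096 features)

   accuracy sensitivity specificity   precision
       0.98        0.96        1.00        1.00
```

Read: despeckling raised SNR from 14.7 dB to 26.7 dB while keeping edge
content correlated with the clean reference (EPF 0.53 vs 0.05 for the
noisy image); the detected box covers the lesion; the fused descriptor
has the documented 3852 + 4096 layout; and on 25 images per class the
cross-validated accuracy is 0.98 with melanoma sensitivity 0.96.

## Command-line interface

`inst/cli/dermofuse.R` exposes the stages as subcommands:

```sh
Rscript inst/cli/dermofuse.R synth --n-per-class 20 --seed 1 --out data/
Rscript inst/cli/dermofuse.R filter data/img_0001.png --out filtered.png --trace trace.csv
Rscript inst/cli/dermofuse.R run --n-per-class 20 --seed 1 --report report.json
```

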