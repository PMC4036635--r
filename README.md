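# lesionCADx

Computer-aided discrimination of malignant versus benign breast lesions from
dynamic contrast-enhanced MRI (DCE-MRI) and two-b-value diffusion-weighted
MRI (DWI), under a **cross-protocol** design: models are trained on a cohort
imaged with one protocol (1.5 Tesla-like) and evaluated on an independent
cohort imaged with another (3.0 Tesla-like). The package is aimed at
radiomics and CAD methodologists who need the whole chain — segmentation,
feature extraction, feature selection, cross-cohort validation — as tested,
reproducible R code.

## What it computes

* **Segmentation** — fuzzy c-means clustering of the first post-contrast
  frame (c = 3, m = 2) refined by a gradient-vector-flow snake
  (Xu–Prince diffusion `v ← v + μ∇²v − (v − ∇f)|∇f|²`; semi-implicit
  active-contour iteration with monotone energy).
* **27 lesion features** in four groups: 11 morphology (compactness,
  spiculation, extent, elongation, solidity, circularity, radial-length
  entropy, fractal dimension, heterogeneity, area, eccentricity), 13 GLCM
  Haralick texture statistics (Ng = 256, distance 1, four directions,
  symmetric), 2 kinetic indices
  `EPE = (I_init − I0)/I0 × 100` and `SER = (I_init − I0)/(I_last − I0)`,
  and the mean apparent diffusion coefficient
  `ADC = ln(S_b0/S_b800)/Δb` (10⁻³ mm²/s) over the Otsu-selected
  high-signal lesion core.
* **Per-feature diagnostics** — independent per-cohort z-normalization;
  best cutoff maximizing (sensitivity+specificity)/2 on the training
  cohort, applied unchanged to the test cohort; empirical and
  maximum-likelihood binormal AUC `Φ(a/√(1+b²))`,
  `a = (μ₁−μ₀)/σ₁`, `b = σ₀/σ₁`; Welch t-test screen for features with
  AUC > 0.5.
* **LHR feature selection** — local-hyperplane RELIEF: margins against
  ridge-regularized projections onto the hyperplanes of the K = 5 nearest
  hits and misses, iterated in the weighted metric, with a z-score noise
  floor and monotone pruning; top-5 subset by weight.
* **Scenario evaluation** — eight feature subsets × three classifiers
  (linear SVM, 5-NN, 500-tree random forest), trained strictly on one
  cohort and tested on the other, reported as specificity / sensitivity /
  accuracy / AUC with per-subset classifier averages.
* **Phantom cohorts** — a synthetic generator producing paired two-protocol
  cohorts (star-convex lesions, correlated texture, enhancement kinetics,
  mono-exponential DWI, cohort gain/noise) so the entire pipeline runs and
  is tested without any patient data.

## Worked example

```r
library(lesionCADx)

spec <- defaultPhantomSpec("train15T", seed = 1)
s <- generateLesion(spec, "malignant", 1)
s
#> LesionStudy 'train15T_m001' (malignant, train15T): 128x128 grid,
#> 10 DCE frames, DWI b = 0/800, mask 286 px

mask <- segmentLesion(s)
diceCoefficient(mask, s@trueMask)
#> [1] 0.997

f <- extractStudyFeatures(s, defaultRunConfig())
round(f[c("area", "circularity", "elongation", "entropy",
          "sum_average", "epe", "ser", "adc")], 3)
#>        area circularity  elongation     entropy sum_average         epe
#>     288.000       1.067       0.991      10.163     322.077     126.379
#>         ser         adc
#>       1.537       1.176
```

The segmented lesion covers 288 mm² and is nearly circular (elongation
0.99). Its enhancement rises 126% in the early phase and washes out
(SER 1.54 > 1), and the mean ADC of the high-signal core is
1.18 × 10⁻³ mm²/s — the washout kinetics and low-ish ADC are exactly the
malignant pattern the generator encodes. A full cross-protocol experiment
(simulate → segment → extract → normalize → ROC → select → evaluate) is one
call:

```r
cfg <- defaultRunConfig(seed = 1)
res <- runPipeline(cfg, outDir = "run1")   # writes CSV/JSON artifacts
res$report                                  # 24 scenario rows + 8 averages
```

A thin command-line wrapper with `simulate`, `segment`-free `extract`,
`roc`, `select`, `evaluate` and `run-all` subcommands is installed at
`inst/scripts/lesioncad.R`.

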