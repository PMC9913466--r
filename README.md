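# radnorm

Benchmarking MR intensity normalization methods for radiomics survival
models, on synthetic multi-scanner brain-phantom cohorts with a known
prognostic ground truth.

## The problem

MR intensities are acquired in scanner-dependent arbitrary units, so
radiomics features extracted from multi-scanner cohorts confound biology
with scanner response. Intensity normalization (IN) is the standard fix,
but many IN methods exist and their effect on downstream survival models
is sequence- and method-dependent. This package is for imaging
methodologists who want to quantify that effect end to end: it implements
the full benchmarking pipeline — normalization, radiomics extraction,
signature selection, survival modelling, method ranking, and a
cross-method feature-robustness screen — and, because multi-scanner
patient cohorts are rarely shareable, exercises it on a synthetic phantom
cohort whose prognostic signal is planted and therefore checkable.

## What is implemented

* **Synthetic cohort** (`generate_cohort`): nested-ellipsoid brain
  phantoms (csf/gm/wm + ventricle) with sequence-correct contrast
  (T1w, T1wce, T2w, FLAIR), a white-matter tumour whose Gaussian-random-
  field texture encodes a latent aggressiveness *a* ~ N(0,1) (amplitude
  and correlation length affine in *a*), per-batch scanner gain/offset +
  bias field + noise, and survival from a proportional-hazards model,
  hazard = lambda0 * exp(beta_a a + beta_age (age - mean) + gamma 1[grade IV]),
  with uniform censoring calibrated to a target rate.
* **15 normalization methods + reference** (`normalize_dataset`,
  `combat_fit_apply`): z-score; nine fuzzy-c-means tissue-mask variants —
  single tissue I/mu_T, two-tissue (I - a)/(b - a), tissue+mode
  I/(mu_T - mode(B)); kernel-density-estimation and Gaussian-mixture
  white-matter peak scaling; Nyul–Udupa histogram matching; white stripe
  (tau = 5%); and feature-level parametric empirical-Bayes ComBat with
  age/grade/gender preserved; plus "nn", the no-normalization reference.
* **IBSI-style radiomics** (`build_feature_table`): 19 first-order,
  16 3D shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM features
  over the original image, 8 undecimated coiflet-1 wavelet sub-bands and
  Laplacian-of-Gaussian images (sigma 2/3/4 mm), at five bin counts —
  1144 columns per bin count (texture matrices in C++).
* **Signature selection** (`stability_select`): Spearman redundancy
  filter (|rs| <= 0.80), then three-method stability selection
  (univariate Cox p < 0.05, survival random forest, lasso Cox) over
  repeated 90% subsamples with a 95% joint-hit threshold.
* **Survival models** (`fit_cph_cv`, `fit_poisson_cv`): Cox PH with
  10-fold CV Harrell concordance (C-I) + AIC, and Poisson survival
  regression (event ~ offset(log time)) with 10-fold CV MSE + AIC.
* **Ranking and robustness** (`ranking_score`,
  `stable_feature_screen`): per-sequence composite score = mean of the
  four oriented z-scores of {C-I, MSE, AIC_cph, AIC_poi} across method
  arms; feature robustness = existence of >= 12 methods pairwise
  Spearman-correlated above 0.8 (exact max-clique); before/after and
  ComBat-combination comparisons on shared folds.

## Worked example

```r
library(radnorm)

cfg <- cohort_config(n_patients = 40, n_batches = 2, sequences = "T1wce",
                     grid_shape = c(32, 32, 32), noise_sd = 5, seed = 7)
cohort <- generate_cohort(cfg)

vols <- normalize_dataset(cohort$volumes$T1wce, cohort$masks, "ws")
v <- vols[[1]]
sprintf("white stripe: peak %.1f, stripe sd %.1f, stripe mass %.3f",
        v$meta$mu_peak, v$meta$sigma_ws, v$meta$stripe_frac)
#> "white stripe: peak 340.4, stripe sd 1.8, stripe mass 0.100"

ft <- build_feature_table(vols, cohort$masks,
                          extraction_config(bin_counts = 32), "ws")
dim(ft)                     # 40 patients x (1 id + 1144 features)
X <- as.matrix(ft[, -1])
probe <- "ws|T1wce|original|glszm|GrayLevelVariance|32"
metrics_record(X[, probe, drop = FALSE], cohort$clinical, k = 5, seed = 1,
               sequence = "T1wce", method = "ws", bin_count = 32)
#>  method cv_cindex   cv_mse  aic_cph  aic_poi
#>      ws   0.65912 1.814614 159.8772 113.1673
cor(X[, probe], cohort$truth$latent_a, method = "spearman")
#> -0.85
```

The white-stripe peak sits on the white-matter intensity (arbitrary
units); after normalization that peak maps to 0 and the stripe holds 10%
of the brain voxels (2 tau). The zone-level gray-variance texture feature
tracks the hidden tumour aggressiveness (Spearman −0.85), and a Cox model
on that single feature reaches a cross-validated concordance of 0.66 —
clearly above the 0.5 chance level, as expected with the planted
log-hazard of 0.8 per unit aggressiveness.

The `analysis/` directory holds the numbered study drivers
(`01_simulate.R` … `06_robustness.R`); each stage reads its
predecessor's outputs under `results/` and prints what it found. Run
them in order from the repository root after installing the package.

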