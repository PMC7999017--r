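# salifinger

Chemometric analysis of surface-enhanced Raman spectra (SERS) of saliva, for
groups searching for a spectral fingerprint of chronic obstructive pulmonary
disease (COPD). The package covers the full workflow a Raman lab applies to a
mapped biofluid cohort — per-spectrum preprocessing, group difference
spectra with band attribution, and a PCA–LDA classification model validated
by spectrum-level leave-one-out cross-validation — plus a synthetic cohort
generator with known ground truth, so the entire pipeline can be exercised
and validated without access to clinical spectra.

## What it computes

* **Preprocessing** (`preprocess_pipeline()`): fifth-degree polynomial
  baseline (79 anchor points, noise from 21-point windows, iterative anchor
  rejection), rescaling on the 1001.5 cm⁻¹ phenylalanine reference band,
  second-degree Savitzky–Golay smoothing, extraction onto a 985-point grid
  at 0.98 cm⁻¹/step, substrate removal, and rejection of fluorescence-
  dominated and de-focused artifact spectra.
* **Differential analysis** (`difference_spectrum()`,
  `assign_differential_peaks()`): group mean ± SD spectra, the COPD − CTRL
  difference with error propagated in quadrature
  (σ<sub>Δ</sub> = √(σ²<sub>COPD</sub> + σ²<sub>CTRL</sub>)), prominence-based peak
  detection, and attribution against a packaged saliva band catalog
  (±4 cm⁻¹; differential bands assigned at |ΔI| ≥ 0.005).
* **Classification** (`fit_pca()`, `fit_lda()`, `loocv()`): PCA truncated to
  15 components, the two-class Fisher discriminant
  w ∝ S<sub>w</sub>⁻¹(μ₁ − μ₂) with the midpoint threshold, leave-one-out
  cross-validation that refits PCA and LDA in every fold, confusion-matrix
  metrics (accuracy, sensitivity, specificity, precision, error rate, MCC),
  ROC/AUC from the held-out canonical scores, hierarchical clustering of
  CV1, and a one-way ANOVA on CV1.
* **Simulation** (`generate_cohort()`): cohorts of Gaussian-band saliva
  spectra with fluorescence-like polynomial backgrounds, a shared substrate
  spectrum, subject-level log-normal variability, noise, cosmic-ray spikes,
  and injectable artifact spectra — all recorded in a ground-truth table.

## Worked example

```r
library(salifinger)

cfg <- strong_separation_config(seed = 1)   # 15 + 15 subjects x 16 spectra
cohort <- generate_cohort(cfg)
substrate <- generate_substrate_spectrum(cfg)

pp <- preprocess_pipeline(cohort$set, substrate = substrate)
pp$counts
#>                 input rejected_fluorescence      rejected_defocus
#>                   480                     5                      5
#>             processed
#>                   470

cv <- loocv(pp$processed, n_pcs = 15)
compute_metrics(cv)
#> Accuracy 1.000 | Sensitivity 1.000 | Specificity 1.000 | Precision 1.000 | ER 0.000% | MCC 1.000 (n = 470)

roc_auc(cv$predictions$score, pp$processed$meta$group)$auc
#> [1] 1
```

480 spectra are generated, the ten injected artifact spectra are screened
out, and in this strongly separated regime (every differential band shifted
by ≥ 5× the within-group SD) the spectrum-level LOOCV classifies all 470
kept spectra correctly — the regime in which clinical studies report
accuracies of 98% and above. A null cohort (`null_cohort_config()`), with no
group structure, classifies at chance (~50% accuracy, AUC ~0.5).

The differential table names the bands driving the separation:

```r
d <- difference_spectrum(group_mean_sd(pp$processed, "COPD"),
                         group_mean_sd(pp$processed, "CTRL"))
head(assign_differential_peaks(d)[, c("shift", "delta", "enriched_group", "assignment")])
```

An end-to-end run with CSV outputs and a markdown report:

```r
run_pipeline(run_config(seed = 1), out_dir = "results/")
```

or from a shell, `Rscript inst/cli/salifinger.R --config run.yaml --out results/`.

## Scope

The package analyzes spectra; it does not model drop-drying morphology or
plasmonics, convert axis units, read proprietary instrument formats, or make
clinical claims. Subject-level (leave-one-patient-out) validation is out of
scope by design — see the methods vignette (`vignettes/salifinger-methods.Rmd`)
for why spectrum-level validation is used and what that does and does not
show.
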