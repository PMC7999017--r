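---
title: "Salivary SERS fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salivary SERS fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`salifinger` implements a complete chemometric workflow for surface-enhanced
Raman spectra (SERS) of saliva, of the kind used to search for a spectral
fingerprint separating patients with chronic obstructive pulmonary disease
(COPD) from healthy controls (CTRL). This vignette is the package's own
account of the science inside it: the models and their assumptions, the
parameters that matter, what the synthetic cohort generator does and does not
emulate, and the places where the design was genuinely open.

## The measurement model

A saliva SERS acquisition is modelled as

$$ y(\nu) \;=\; \sum_p A_p \, G\!\left(\nu; c_p, w_p\right) \;+\; b(\nu)
   \;+\; s(\nu) \;+\; \varepsilon(\nu), $$

where $\nu$ is the Raman shift in cm$^{-1}$, $G$ is a Gaussian band of center
$c_p$ and half-width $w_p$, $b(\nu)$ is a slowly varying fluorescence-like
background, $s(\nu)$ is the reproducible broadband contribution of the
metallic substrate, and $\varepsilon$ is i.i.d. noise with occasional
single-pixel cosmic-ray spikes. The band catalog shipped with the package
(`read_attribution_table()`) lists the saliva bands commonly resolved between
400 and 1600 cm$^{-1}$ — amino-acid, protein-backbone, lipid, nucleotide and
saccharide modes — together with the group in which each differential band is
more abundant (lipid and saccharide bands around 440–590 and 1240–1450
cm$^{-1}$ in CTRL; protein, saccharide and nucleotide bands between 920 and
1200 cm$^{-1}$ in COPD), each matched with a $\pm 4$ cm$^{-1}$ tolerance.

## Preprocessing chain

`preprocess_pipeline()` applies, per spectrum and in this order:

1. **Baseline.** A fifth-degree polynomial is fitted to 79 anchor points
   placed at the local minima of equal axis segments. The local noise is the
   median standard deviation of the linearly detrended signal in consecutive
   21-point windows; anchors lying more than twice the noise above the fit
   (i.e. on bands) are discarded and the fit repeated until stable. The
   anchor-and-reject scheme is this package's construction: 79 interpolation
   points and 21 noise points define *where* the baseline is measured, and
   local minima plus iterative rejection are the standard way to keep a
   polynomial under the bands rather than through them.
2. **Reference-band rescaling.** All intensities are divided by the maximum
   in the 1001.5 $\pm$ 4 cm$^{-1}$ phenylalanine window (band-height
   normalization; band-area normalization is available via
   `norm_mode = "area"`). Height was chosen over area or a vector norm
   because the reference is a single well-resolved band and height is
   insensitive to the window's edges.
3. **Smoothing.** A second-degree Savitzky–Golay filter. The window is not
   dictated by the method itself; the default of 9 points suppresses
   single-pixel spikes while leaving ~8 cm$^{-1}$ bands (10 points at the
   0.8 cm$^{-1}$ acquisition step) essentially untouched. Endpoints use the
   polynomial fitted within the edge window.
4. **Extraction.** Linear interpolation onto a fixed grid of 985 points at
   0.98 cm$^{-1}$/step starting at 400 cm$^{-1}$, i.e. 400–1364.3 cm$^{-1}$.
   A 985-point grid at this step cannot span the full 400–1600 cm$^{-1}$
   acquisition range; the explicit point count and step are honored and the
   grid is anchored at the low end, where most of the catalog lives.
5. **Substrate removal.** The substrate spectrum is itself baseline-corrected,
   smoothed and resampled, then subtracted unscaled (`"unit"` mode, the
   default) or with a non-negative least-squares scale estimated on
   peak-free points (`"lsq"`). Because the degree-5 baseline fit is close to
   linear as an operator, baseline-correcting spectrum and substrate
   separately and subtracting preserves the additive model.
6. **Final rescale.** Smoothing, interpolation and substrate removal each
   perturb the reference window maximum by a small amount, so the reference
   convention (window maximum exactly 1) is re-imposed as the last step.

Artifact screening runs on the raw spectra and removes two kinds of
acquisition failure before any statistics are computed:

* **fluorescence-dominated** spectra, flagged when the baseline-to-peak
  energy ratio exceeds `artifact_baseline_ratio_max` (default 200; clean
  synthetic spectra sit near 10, injected fluorescence artifacts in the
  thousands), and
* **de-focused** spectra, flagged when the maximum baseline-corrected band
  height falls below `artifact_snr_min` times the local noise (default 10;
  clean spectra sit near 100). The band height is measured after removing a
  wide running median, so smooth lack-of-fit of the polynomial baseline is
  not mistaken for a band.

## Differential analysis

`group_mean_sd()` computes pointwise means and sample standard deviations
(n−1), `difference_spectrum()` the COPD − CTRL difference with the error
propagated in quadrature, $\sigma_\Delta = \sqrt{\sigma^2_{\mathrm{COPD}} +
\sigma^2_{\mathrm{CTRL}}}$, from the spectral standard deviations (standard
errors may be preferred for inference, but the propagated SD is what the
grey-band convention of difference-spectrum figures shows). Peaks are local
maxima filtered by topographic prominence; on difference spectra the search
runs on $+\Delta$ and $-\Delta$ separately so each side yields the bands
enriched in one group. `assign_differential_peaks()` keeps peaks with
$|\Delta I| \ge 0.005$ on the normalized scale and attributes each to the
nearest catalog band within $\pm 4$ cm$^{-1}$ (ties toward the lower shift).

## Classification model

The processed spectra (rows) are mean-centered and decomposed by PCA; the
first 15 components feed a two-class Fisher discriminant,
$w \propto S_w^{-1}(\mu_{\mathrm{COPD}} - \mu_{\mathrm{CTRL}})$, with the
decision threshold at the midpoint of the projected class means (equal
priors — the class balance of a mapped cohort is close to 1:1 by design).
Two classes admit exactly one canonical variable (CV1). Performance is
estimated by leave-one-out cross-validation *at the spectrum level*: for
every spectrum the PCA **and** the discriminant are refitted on the other
n−1 spectra, so no information from the held-out spectrum leaks into the
model (a `pca_outside_cv` flag reproduces the common shortcut of fitting PCA
once on everything, for comparison). Held-out CV1 scores are centered on
each fold's threshold to make them comparable across folds; the ROC curve
sweeps those scores and the trapezoidal AUC equals the tie-aware normalized
Mann–Whitney statistic. MCC is defined as 0 when a confusion-matrix marginal
is zero; `accuracy = 1 − ER` holds exactly by construction. CV1 scores are
also clustered hierarchically (Euclidean distance; Ward linkage by default,
because it produces the compact two-cluster structure one inspects for
unsupervised group recovery; complete/average linkage are available) and
compared between groups with a one-way ANOVA implemented from the
sum-of-squares definitions.

Numerical details worth knowing: PCA uses the singular-value route, switching
to the (algebraically identical) Gram-matrix eigendecomposition when there
are more variables than spectra, with a deterministic sign convention
(largest-magnitude loading element positive); the within-class scatter gets
a ridge of $10^{-8}\times$ its mean diagonal only if it is singular; all
operations are deterministic given the input order, and LOOCV predictions
are invariant to that order.

## The synthetic cohort generator

No public salivary SERS cohort exists, so `generate_cohort()` produces one
with known ground truth, following the measurement model above. Its defaults
are the study conditions the analysis assumes:

* 15 subjects per group, ≥25 map spectra each, axis 400–1600 cm$^{-1}$ at
  0.8 cm$^{-1}$/step;
* Gaussian bands (full widths 6–12 cm$^{-1}$) at the catalog positions, the
  1001 cm$^{-1}$ band strongest; line shapes in SERS are closer to Voigt,
  but at these widths the Gaussian core is what every downstream statistic
  sees;
* between-subject variability as a per-subject, per-band log-normal
  multiplier (keeping intensities positive), with a larger spread for CTRL
  (log-SD 0.10 vs 0.05), reproducing the higher standard deviation of
  control average spectra; plus a per-spectrum log-normal intensity jitter
  (log-SD 0.05);
* a random fifth-degree polynomial background per spectrum, one shared
  substrate spectrum (sum of four seed-determined broad Gaussians), i.i.d.
  noise of SD 0.01 (1% of the reference band), Poisson cosmic-ray spikes
  (0.1 per spectrum);
* group effects as amplitude multipliers (default 1.15) on the catalog's
  differential bands. The 1001 cm$^{-1}$ band is kept group-neutral even
  though it is listed among the COPD-enriched bands: normalization divides
  every spectrum by it, so enrichment placed there is unidentifiable and
  would reappear sign-flipped on all other bands;
* one seeded random stream per subject (sub-seed = seed + 100003·group +
  1009·subject), so enlarging a cohort never changes existing subjects.

Artifact spectra are injected by replacement: fluorescence artifacts add a
broad background ten times the signal range; de-focus artifacts keep only the
running-median background plus noise, pushing every band below the noise
floor.

Two presets define the regimes used in validation. The
**strong-separation** preset (multiplier 1.35, subject and jitter log-SDs
0.03, 2% artifacts, 15 × 16 spectra) makes every differential band's
group-mean difference at least five times the within-group standard
deviation — the regime in which a spectrum-level classifier is expected to
approach perfection, as the clinical study reports. The **null** preset
removes the group effect *and* the between-subject effects. The latter is
deliberate and worth a caveat: with subject-level structure present, a
spectrum-level LOOCV can classify a no-group-effect cohort well above chance
by memorizing subjects (the held-out spectrum's map siblings are always in
training). That is a genuine property of spectrum-level validation — the
reason patient-level validation needs larger cohorts — not leakage; a
leakage guard therefore needs labels that are exchangeable at the spectrum
level.

What the generator does **not** emulate: drop-drying ("coffee-ring")
morphology and plasmonic physics, substrate-specific optics, correlated
(pink) noise, band-position shifts between subjects, and Voigt/Lorentzian
tails. Passing tests on synthetic cohorts therefore demonstrate the
correctness and statistical behaviour of the pipeline under its own model
assumptions, not clinical performance on real saliva.

## Problem sizes used in validation

The packaged checks run the full pipeline on cohorts of 480 spectra
(15 × 16 per group) for the strong-separation and null regimes, 750 spectra
for artifact-screening operating characteristics, and 96-spectrum cohorts
across a 0–10× separation sweep; these sizes give Monte-Carlo standard
errors of 2–3 percentage points on rate estimates, small enough for the
bounds being checked.

## Known limitations

* Cosmic-ray spikes are attenuated (to ~26% of their height by the default
  9-point filter) but not removed: a spike landing on a band column can
  corrupt that band's recovered amplitude in roughly 1% of spectra at the
  default spike rate. Dedicated despiking is intentionally out of scope.
* The attribution step reports the nearest catalog band; overlapping bands
  closer than ~11 cm$^{-1}$ merge into one local maximum and are attributed
  to whichever center is nearer.
* The unit-mode substrate subtraction assumes the substrate contribution is
  identical across spectra; spot-to-spot substrate variability would require
  `"lsq"` mode with a peak-free mask.
* Spectrum-level LOOCV estimates the separability of *spectra*, not the
  generalization to new *subjects*; see the null-cohort caveat above.
* A 95% confidence interval for the AUC is not provided beyond what a user
  can bootstrap from the returned per-spectrum scores.
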