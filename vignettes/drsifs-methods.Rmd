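---
title: "Methods: simulating and classifying DRS-IFS breast-tissue spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying DRS-IFS breast-tissue spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`drsifs` implements a complete analysis pipeline for combined diffuse
reflectance spectroscopy (DRS) and intrinsic fluorescence spectroscopy
(IFS) of breast tissue: a physics-informed simulator of the six-channel
fibre-probe instrument, spectral preprocessing with a signal-to-noise
gate, fixed-window feature extraction, Boruta all-relevant feature
selection, and patient-grouped repeated stratified cross-validation of a
gradient-boosted tree classifier. The intended use is method development
and validation: real ex-vivo spectra of this kind are rarely shared, so
the simulator provides datasets with the same hierarchical structure and
controllable class contrast, on which every downstream stage can be
exercised and audited.

## The instrument model

The simulated probe has four reflectance channels at source-detector
separations (SDS) of 0.5, 0.8, 1.6 and 2.8 mm (`DRS05` ... `DRS28`) and
two fluorescence channels excited at 375 and 405 nm (`IFS375`,
`IFS405`), all recording 425-850 nm. Six spectra form one acquisition
set; a sample is measured from both sides at 8-10 rotation positions,
which gives 96-120 spectra per sample.

### Tissue optics

Each sample is described by a `tissue_optical_model`:

* **Absorption** mixes five chromophores linearly,
  $\mu_a(\lambda) = \sum_c c_i\,\varepsilon_i(\lambda) + \mu_{a,0}$,
  over oxy- and deoxy-haemoglobin, lipid, water and beta-carotene, plus
  a small constant floor $\mu_{a,0}$ (default 0.002 cm$^{-1}$) so
  $\mu_a$ is strictly positive. The extinction curves are smooth
  synthetic analogues — Gaussian mixtures placed at the literature band
  positions (Soret and Q bands, the 556/757 nm deoxy features, NIR
  water/lipid bands, carotenoid absorption below ~550 nm) — not
  digitised reference tables. They give the classes realistic spectral
  contrast; absolute units are fixed only by the adipose-tissue anchor
  below.
* **Scattering** follows the Mie-type power law
  $\mu_s'(\lambda) = a\,(\lambda/786)^{-b}$.
* **Anchoring.** The healthy (predominantly adipose) reference model is
  calibrated so that $\mu_a(786\,\mathrm{nm}) = 0.041$ cm$^{-1}$ and
  $\mu_s'(786\,\mathrm{nm}) = 8.5$ cm$^{-1}$, the standard fatty-breast
  values; the haemoglobin concentration is solved analytically from the
  basis at construction time, so the anchor holds exactly whatever the
  basis shapes.
* **Fluorescence** is a weighted sum of unimodal emission bases for
  NADH, FAD, collagen, elastin and lipopigments, with separate weight
  vectors per excitation wavelength, attenuated by
  $e^{-\mu_a(\lambda) d}$ over an effective escape path $d = 0.03$ cm
  (the IFS interrogation depth is shallow), and cut to zero below the
  425 nm long-pass filter edge.

### Spatially resolved reflectance

The ideal DRS spectrum is the steady-state diffusion-dipole
(extrapolated-boundary) closed form for reflectance from a semi-infinite
homogeneous medium at distance $\rho$ from the source:

$$R(\rho) = \frac{1}{4\pi}\left[ z_0\!\left(\mu_\mathrm{eff}+\tfrac1{r_1}\right)\frac{e^{-\mu_\mathrm{eff} r_1}}{r_1^2} + (z_0+2z_b)\!\left(\mu_\mathrm{eff}+\tfrac1{r_2}\right)\frac{e^{-\mu_\mathrm{eff} r_2}}{r_2^2} \right]$$

with $z_0 = 1/(\mu_a+\mu_s')$, $\mu_\mathrm{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$,
$z_b = 2AD$ and the internal-reflection parameter $A$ from the Groenhuis
empirical formula at relative refractive index 1.4. The real instrument's
sampling volumes would be estimated by photon-transport Monte Carlo; the
closed form is used instead because the simulator needs *statistical*
realism (correct monotonicities and inter-channel ordering), not photon
transport fidelity. The tests verify the implementation against an
independent numerical Hankel-transform evaluation of the same Green's
function (Sommerfeld identity) to better than 1%, and the physical sanity
properties: $R$ decreases with $\mu_a$ and with SDS everywhere.

### Detector and noise

`counts = ideal x response(lambda) x t + dark + shot + read`, with a
smooth bell-shaped system response (lamp x fibre x spectrometer), shot
noise of variance `shot_scale * expected_counts` (default `shot_scale = 1`,
i.e. Poisson-like), Gaussian read noise (default SD 8 counts) and a
constant dark offset (120 counts); counts are clipped at zero.
Integration times default to 0.1-0.5 s per channel, longer at larger
SDS. The calibration set mirrors the real workflow: a flat 99%
white standard per DRS channel, a spectrally flat white fluorescent film
per IFS channel, and darks for every channel.

### Class contrast

Class-conditional parameters are the healthy reference times a per-class
multiplier table (`tissue_class_table()`): tumours carry more total
haemoglobin at lower oxygen saturation, more water and collagen
fluorescence, stronger and steeper scattering, and less lipid and
beta-carotene; pCR is modelled as collagen-rich fibrosis with nearly
normal perfusion. The multipliers are applied geometrically scaled by
`class_contrast` (`ratio^contrast`), so `class_contrast = 0` makes all
five classes *identically distributed* — the null configuration used to
calibrate the pipeline — and 1 is the default "realistic contrast"
condition. Within-class biological variability is log-normal (CV 8-30%
depending on the parameter), with shared patient-level factors (CV
8-15%) so that observations cluster by patient, which is exactly what
patient-grouped cross-validation must respect. Histological dye
contamination is simulated as an additive absorber (broad band at
640 nm) on partially/heavily contaminated samples, so quality-stratified
analyses have real signal to detect.

What the generator does **not** emulate: layered or heterogeneous
geometry (each sample is optically homogeneous), freeze-thaw artefacts,
probe-contact pressure effects beyond a small log-normal intensity
jitter, wavelength-dependent detector nonlinearity, and exogenous
tracers. Passing tests therefore demonstrate the *pipeline's*
correctness and statistical calibration, not clinical performance on
real tissue.

## Preprocessing

Stages run in a fixed, contractual order: integration-time correction
(dark counts subtracted, then divided by the integration time), spectral
shape calibration (division by the white-standard or
fluorescence-reference rate; reference bins below $10^{-3}\times$ the
reference maximum are flagged invalid and excluded downstream), the SNR
gate, Savitzky-Golay smoothing (default window 11 points, order 3), and
cubic-spline resampling onto the canonical grid 425-850 nm in 1 nm
steps (426 points, both endpoints included).

The SNR definition is a design choice (the quantity is gated at >= 5 but
otherwise unspecified in this field's workflows):
`SNR = (max(smoothed) - baseline) / sigma_hat`, with baseline the 5th
percentile of the smoothed curve and `sigma_hat` the noise SD estimated
from the smoothing residuals, rescaled by the analytic residual-variance
factor of the SG filter ($\sigma^2(1 - 2h_0 + \sum h^2)$) so it is
unbiased under white noise. SNR is computed *after* calibration
(configurable); a noise-free spectrum returns a large sentinel and
always passes. Under the default noise model essentially all simulated
tissue spectra pass the gate and pure-noise spectra essentially never do
(both verified at the 99% level over 1000 trials in the tests). A failed
gate flags the record rather than raising.

Applying the integration-time correction to IFS channels as well as DRS
is harmless (it is a positive scalar per spectrum) and keeps the code
symmetric; it is an interpretation, recorded here.

## Fixed-window features

Spectra in 450-850 nm are divided into twenty contiguous 20 nm windows.
Windows are half-open `[start, end)` with the last window closed at
850 nm, so every canonical grid point belongs to exactly one window (the
boundary topology is a design choice). Per window, five statistics:
mean, maximum and minimum intensity, and the wavelengths of the maximum
and minimum, ties broken towards the smallest wavelength — 100 features
per spectrum. For a channel combination (default `IFS405 + DRS08 +
DRS28`, the combination this instrument class reports best results
with), features are concatenated per acquisition set, 100 per channel;
sets missing any required channel (failed QC) are dropped and counted.
Features from windows with no valid bin are NA and median-imputed before
classification.

## Boruta feature selection

Boruta is implemented from its published description: each iteration
appends a permuted "shadow" copy of every live feature, fits a random
forest (`ranger`, impurity importance, default 80 trees), and scores a
hit for a real feature whose importance exceeds the *maximum* shadow
importance. Two-sided binomial tests against hit rate 0.5, Bonferroni
corrected over the still-tentative features, confirm or reject at
`alpha = 0.01`; iteration stops when nothing is tentative or at
`max_iter`. The importance engine, alpha and iteration cap are
configurable; they are conventional defaults, not values fixed by the
study design.

Because selection inside the classifier's resampling loop is the only
leakage-free placement, the default evaluation mode fits Boruta on the
training folds of each split (`boruta_mode = "within_fold"` when
selection is requested); a `"global"` mode reproduces the optimistic
alternative for comparison, and `"none"` skips selection. The
calibration experiments below run with `"none"`: with 300 fixed-window
features and XGBoost's own regularisation, selection changes little
while multiplying cost 25-fold, and the null/signal calibration is a
property of the classifier path, not of the selector (which has its own
dedicated experiments).

## Cross-validation and metrics

Evaluation uses repeated stratified k-fold cross-validation *by patient*
(five folds, five repeats): patients are stratified on their majority
class and dealt round-robin into folds after a within-class shuffle, and
every observation of a patient follows its patient. Train/test patient
disjointness is hard-asserted on every split. The classifier is XGBoost
(binary logistic, single thread, fixed seed; defaults `nrounds = 80`,
`max_depth = 4`, `eta = 0.3`) behind a thin interface — deliberately the
one external learner in the pipeline. Metrics per fold: accuracy,
sensitivity and specificity at threshold 0.5 (positive class = tumour
side), AUC via the tie-corrected rank statistic (verified exactly
against an $O(n^2)$ pairwise oracle), and mAP as the average precision
of the positive class. One-class folds (possible for rare classes such
as pCR) yield missing metrics rather than errors and are excluded from
aggregates with a warning. Reports aggregate mean and SD over the 25
fold-repeat entries and pool confusion matrices by summing within
repeats and averaging (rounded) across repeats.

## Calibration experiments and problem sizes

Two experiments calibrate the pipeline statistically, with sizes chosen
so patient-level sampling noise is small relative to the bands being
checked:

* **Null calibration** — full pipeline, healthy-vs-all-cancer, at
  `class_contrast = 0`: the mean aggregate AUC over independent
  replicate datasets of 96 patients each (9 in the acceptance script, 6
  in the test suite) must lie in $0.5 \pm 0.05$. Replication matters:
  because observations cluster within patients and samples, a *single*
  dataset's cross-validated AUC has a null standard deviation near
  $0.59/\sqrt{n_\mathrm{patients}}$ (about 0.06 at 96 patients — the
  folds reuse the same patients, so repeats do not average this away),
  which no reasonable per-dataset band could absorb. Averaging nine
  replicates brings the standard error to about 0.02, making the band a
  ~2.5-sigma unbiasedness check. The replicate-averaged AUC is also the
  quantity that actually measures what the invariant is about: freedom
  from systematic leakage, not single-draw luck.
* **Signal recovery** — 44 patients at `class_contrast = 1`: aggregate
  AUC must reach 0.9 (it typically lands near 0.95).

The Boruta experiments plant one feature (the label plus noise,
SD 0.1) among 50 standard-normal noise features at n = 300 and require
recovery in at least 95 of 100 seeded runs, and bound the null
false-confirmation rate by the alpha regime (<= 5% at alpha = 0.01)
over 100 all-noise runs.

## Known limitations

* The simulator is homogeneous-medium, closed-form optics; it cannot
  validate depth-sensitivity claims or partial-volume effects.
* The extinction/emission bases are synthetic analogues; inverse
  fitting of chromophore concentrations from simulated spectra would
  recover the simulator's own basis, not literature coefficients.
* Absolute classification accuracies on simulated data say nothing
  about accuracy on real tissue; only the *relative* machinery
  (leakage control, metric definitions, selector behaviour, gate
  calibration) transfers.
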