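---
title: "Voxel-wise tissue outcome prediction in acute ischemic stroke: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise tissue outcome prediction in acute ischemic stroke: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The prediction problem

After an acute ischemic stroke, part of the hypoperfused tissue (the
*penumbra*) is still salvageable if blood flow is restored, while the
*ischemic core* is already irreversibly injured. Voxel-wise tissue outcome
prediction asks: given acute multi-parametric MRI (diffusion- and
perfusion-weighted imaging) and clinical covariates, which voxels will be
part of the infarct on follow-up imaging about a week later? Because the
answer depends on whether and how the vessel is recanalized, models are
trained separately per treatment cohort: patients recanalized
intraarterially (IAR), recanalized by intravenous thrombolysis (IVR), and
non-recanalizers (NR).

`voxelfate` implements that study design end to end: a synthetic cohort
generator with known ground truth, the diffusion/perfusion feature
extraction chain, three classifiers crossed with three normalization and
two balancing variants (18 settings), leave-one-patient-out (LOO)
likelihood prediction, Dice-optimal threshold calibration with fixed
morphological post-processing, and full segmentation evaluation including a
single-parameter thresholding baseline.

# The synthetic cohort

Clinical stroke MRI of this kind is not publicly shareable, so the package
ships a parametric generator (`cohort_params()`, `generate_cohort()`) that
emulates the *structure* the pipeline needs rather than anatomy:

* an ellipsoidal brain split by a midline plane into hemispheres;
* ventricular CSF blobs with free-water ADC (~3000e-6 mm^2/s);
* a low-ADC core (mean 400e-6 mm^2/s, below the 550e-6 segmentation
  threshold) nested inside a hypoperfused penumbra in one hemisphere;
* a follow-up lesion equal to the core plus the non-salvaged, core-nearest
  fraction of the penumbra. The salvage fraction is the cohort effect
  (defaults NR 0.1, IVR 0.5, IAR 0.6): non-recanalizers lose nearly the
  whole penumbra, treated cohorts keep most of it. This gives the
  classifiers a learnable, treatment-specific mapping analogous to the
  clinical one;
* a surrogate atlas: nine anatomical region labels by nearest-anchor
  assignment and a smooth white-matter probability field, standing in for
  MNI-atlas registration (out of scope for synthetic grids that share one
  voxel space).

DWI follows the mono-exponential model `S_b = S_0 exp(-b ADC)` at b = 0 and
1000 s/mm^2; PWI follows the dynamic susceptibility contrast model
`S(t) = S_0 exp(-TE C(t))` with TR 1.5 s, TE 45 ms and 40 frames. Tissue
concentration is the indicator-dilution convolution
`C(t) = f (AIF * R)(t - delay)` with a gamma-variate arterial input
function and exponential residue `R`. Per-region perfusion triples (CBF in
mL/100g/min, CBV in mL/100g, delay in s) default to (60, 4, 0) for normal
tissue, (25, 3, 4) for penumbra and (10, 1.5, 8) for core: reduced flow,
prolonged mean transit time and increasing bolus delay toward the core.
Clinical covariates (NIHSS, age, sex, onset-to-imaging time) are drawn per
cohort from the study population's stratified means; the reported
dispersions are standard errors and are scaled back to standard deviations
by the cohort size they were estimated from.

Default problem sizes are chosen for desk-scale reproducibility: 24^3
voxel grids at 2 mm spacing and 8 patients per cohort for the headline
experiments, with the full 90-patient configuration (33/23/34) available
for structural checks on smaller grids. Multiplicative Gaussian signal
noise defaults to 2%.

## What the generator does *not* emulate

Real anatomy and vascular territories, motion and susceptibility
artifacts, slice-timing effects, registration error between acute and
follow-up imaging, partial-volume effects, bilateral strokes, and
rater variability in lesion segmentation. Passing tests on this cohort
therefore validate the *pipeline machinery and its contracts* (exact
feature recovery, calibration logic, metric correctness, directional
effects of balancing and multi-parametric learning), not clinical
performance on real data.

## Numerical design of the forward perfusion model

The analysis chain discretizes the convolution with a rectangle rule on a
1 s grid. To make noise-free recovery exact rather than biased, the
generator is the exact inverse of that chain: tissue concentration is
forward-simulated by the same discrete convolution on an internal 1 s
model grid, and PWI frames at TR = 1.5 s are sampled from it by cubic
spline. The simulated arterial input function is stored on the 1 s model
grid, so known-AIF deconvolution sees a perfectly consistent system.

One subtlety is the residue area: the rectangle-rule sum of
`exp(-t/tau)` on a 1 s grid exceeds its integral by about half a sample,
which would bias CBV and hence MTT by `dt/(2 MTT)` (6-13% at physiologic
MTT). The generator therefore plants the exponential time constant
`tau = -dt / log(1 - dt/MTT)`, whose *discrete* area on the analysis grid
equals the requested MTT exactly. The residue stays exponential; the
planted CBF (residue peak), CBV (area ratio), MTT (central volume
theorem) and Tmax (residue argmax) are all recovered exactly by the
truncation-free chain.

# Perfusion analysis

`compute_perfusion_maps()` runs, per patient: log signal-to-concentration
conversion (`C = -ln(S/S_0)/TE`, baseline `S_0` from the first three
pre-bolus frames), cubic-spline resampling to a uniform 1 s grid,
block-circulant SVD deconvolution, and the four parameter maps

* CBF = `(k_H/rho) max_t k(t)`, scaled to mL/100g/min,
* CBV = `(k_H/rho) \int C dt / \int AIF dt`, scaled to mL/100g,
* MTT = CBV/CBF (central volume theorem), in seconds,
* Tmax = argmax of the deconvolved residue signal, on the 1 s grid,

with `k_H = 0.73` (hematocrit correction) and `rho = 1.04 g/mL` as
conventional constants. The deconvolution builds the `2L x 2L` zero-padded
circulant matrix of the AIF and zeroes singular values below a fraction of
the largest (default 15%, the study pipeline's operating point). The
circulant (rather than triangular) formulation makes the residue peak
position insensitive to bolus delay, which is what makes Tmax meaningful.

Truncation trades noise robustness against bias: on noise-free data the
truncated pseudo-inverse smooths the residue, underestimating its peak by
tens of percent and shifting the argmax by 1-2 s. Validation of the
planted physiology is therefore performed at truncation 0 (where the
noise-free system is exactly invertible), while the classification
pipeline keeps the 15% default — threshold calibration makes the
monotone bias immaterial for prediction. Quadratic (Kjolby-style)
signal-to-concentration correction is available as an opt-in with
user-supplied coefficients; no coefficients are invented by default.

A pre-correction hook (`precorrect`) preserves the stage where motion and
slice-time correction would run on real data; synthetic volumes are clean,
so the default is the identity.

# Features, normalization, balancing

Each voxel of the ipsilateral hemisphere (brain minus CSF, where CSF is
segmented as ADC > 2000e-6 mm^2/s — a conventional free-water cutoff, as
the study does not print its threshold) carries 12 features: ADC, Euclidean
distance to the region-growing core segmentation (in voxel units), white
matter probability, anatomical region label, CBV, MTT, Tmax, CBF, and four
per-patient covariates repeated across voxels (NIHSS, age, sex,
onset-to-imaging minutes). The outcome label is the CSF-excluded follow-up
lesion.

Region growing uses 6-connectivity (conservative against leakage) below
the 550e-6 mm^2/s upper ADC bound, seeded at the core centroid in
synthetic mode; an optional exclusion mask substitutes for interactive
manual correction.

Two normalization variants re-express the five imaging parameters relative
to the contralateral hemisphere (RC) or to a mirrored-lesion reference VOI
(RVO): ratios for ADC/CBF/CBV, subtraction for the temporal parameters
MTT/Tmax. In synthetic mode the reference VOI is the acute core mirrored
across the midline. Stratified balancing keeps all lesion voxels and an
equally sized seeded random subsample of non-lesion voxels per patient.

# Classifiers and cross-validation

Three computationally efficient classifiers are crossed with the
normalization and balancing variants (3 x 3 x 2 = 18 settings), each
trained per cohort and evaluated by leave-one-patient-out cross-validation;
cohort membership is never a feature, so the three cohort models are
independent by construction. Hyperparameters are deliberately conventional
baselines, surfaced in the configuration rather than hard-coded:

* **RDF** — probability random forest, 100 trees, `floor(sqrt(p))`
  features per split, no depth cap; the region label is a native
  categorical split variable.
* **GLM** — binomial logistic regression on one-hot features.
* **kNN** — k = 11 with standardized Euclidean distance (z-scores fitted
  on the training fold; unscaled mixed-unit features would make the metric
  meaningless), likelihood = infarcted fraction of the neighbors.

Fold seeds are derived from the master seed by a stable arithmetic hash
(`derive_seed()`), so stratified sampling and forest construction are
bit-for-bit reproducible and independent of execution order.

# Threshold calibration and post-processing

Likelihoods are relative quantities, so each (patient, setting) pair gets
an absolute decision threshold calibrated *out of sample*: all calibration
patients' likelihood maps (everyone in the cohort except the test patient)
are binarized at 101 thresholds (0.00-1.00, step 0.01, inclusive `>=` so
that 0 is the predict-everything endpoint), post-processed, Dice-scored
against their own truths, and the smallest threshold attaining the highest
mean Dice is applied to the held-out patient. Post-processing is fixed:
morphological closing with a full 3 x 3 x 3 cube (zero-padded borders,
chosen over a 6-connected cross because the kernel is printed as a cube)
followed by removal of 26-connected components under 10 voxels
(26-connectivity matches the closing kernel's neighborhood).

Empty-mask conventions: Dice(empty, empty) = 1, Dice(empty, non-empty)
= 0; surface distances of an empty mask are `NA` sentinels excluded from
aggregation, never silently zero.

# Evaluation and the single-parameter baseline

Per (patient, setting): Dice (primary), sensitivity, specificity, accuracy
and Matthews correlation inside the ipsilateral analysis mask (the
evaluation domain is recorded with the results; the study's printed
accuracy does not state its domain), mean surface distance and Hausdorff
distance between 6-neighborhood border voxels in millimetres, and signed
volume difference in mL.

The single-parameter baseline mirrors the calibration protocol for each of
ADC, CBF, CBV, MTT and Tmax: thresholds sweep 101 pooled quantiles of the
calibration patients' map values (physical parameters have no universal
[0,1] range), predicting infarction where ADC/CBF/CBV are *low* or
MTT/Tmax are *high* — the physiologic directions. The desk-scale
directional comparison runs the baseline on absolute values; the
normalized variants are available through the same function.

# Reproducibility contracts

* Every stochastic step (cohort generation, subsampling, forests) is
  seeded from one master seed via tagged hashes; identical configs produce
  byte-identical results tables.
* The resolved configuration is archived as YAML next to every output
  directory.
* The acceptance script (`scripts/acceptance.R`) regenerates the default
  synthetic cohort and recomputes the headline quantities from scratch at
  desk scale: 8 patients per cohort on 24^3 grids for the classifier
  comparisons (three stratified-sampling seeds), and the structural
  feature/setting counts.

# Known limitations

* Parametric geometry: no real anatomy, vasculature or artifact model, so
  absolute Dice values on synthetic cohorts are far higher than clinically
  realistic ones and only *directional* comparisons are meaningful.
* Single averaged high-b DWI volume; diffusion directions are not
  modelled.
* Absolute CBF/CBV scaling depends on conventional constants; only
  threshold-calibrated (scale-free) decisions are validated.
* The kNN stores its training fold; at clinical voxel counts a spatial
  index would be needed.
* Statistical hypothesis testing across settings (ANOVA families) is out
  of scope; the package exports tidy per-patient metric tables for
  external statistics software.
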