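---
title: "Compartmental segmentation of dual-contrast placental MRI: models and methods"
author: "placseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental segmentation of dual-contrast placental MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placseg)
```

## The problem

The human placenta is not one tissue. Maternal blood pools in the
intervillous space (IVS), fetal and maternal vessels (PV) thread through it
with coherent flow, and the villous parenchyma (PT) fills the rest.
Whole-organ averages of T2* — the effective transverse relaxation time,
which falls with rising deoxyhemoglobin and so serves as an oxygenation
proxy — blur these compartments together and can hide or even reverse
gestational trends. `placseg` implements a compartment-resolved analysis:
it estimates per-voxel T2* and diffusion-tensor metrics from clinically
feasible dual-contrast MRI, clusters voxels into the three physiological
compartments without supervision, flags voxels atypical for *every*
compartment as lesion (PL) candidates, parcellates the placenta into
chorionic-to-basal depth layers, and runs the cohort statistics that relate
compartment oxygenation to gestational age (GA) and to fetal-brain T2*.

## Parametric maps

**T2* relaxometry.** The multi-echo gradient-echo magnitude signal is
modelled as a mono-exponential, `S(TE) = S0 exp(-TE/T2*)`. `fit_t2star()`
solves the log-linear problem with weights proportional to the squared
signal (the variance-stabilizing choice after a log transform) in two
passes: the first uses the observed signals as weights, the second reuses
the predicted decay as weights. The second pass matters: observed-signal
weights correlate with the noise and bias T2* upward by roughly 1.5% at
SNR 25; predicted-signal weights remove that bias while keeping the
estimator closed-form and deterministic. Voxels with fewer than three
positive echoes, a non-positive decay rate, or T2* above a 300 ms
plausibility cap are flagged invalid and excluded downstream — unstable
estimates must not leak into the clustering feature space.

**Diffusion tensor.** `fit_tensor()` fits `ln S = ln S0 - b g'Dg` by the
same two-pass weighted linear least squares, then eigen-decomposes D
(closed-form symmetric 3x3 eigenvalues, sorted descending) and derives
AD = lambda1, RD = (lambda2 + lambda3)/2, ADC = mean(lambda) and
FA = sqrt(3/2) ||lambda - mean|| / ||lambda||. Negative eigenvalues are
clipped to zero and the voxel flagged, mirroring common DTI practice.
Noiseless recovery is exact to numerical precision for both maps, and the
derived metrics are invariant to joint rotation of gradients and tensor.

## The fuzzy mixture model and the lesion rule

The clustering feature vector is (ADC, FA, AD, RD, T2*): diffusivities in
1e-3 mm²/s, FA unitless, T2* in ms. Features are z-scored (they span three
orders of magnitude) and the standardization is stored in the model, so
subjects segmented later are projected consistently. A K = 3 Gaussian
mixture with full covariances is fitted by EM: k-means++ seeding of the
responsibilities, five restarts keeping the best final log-likelihood, a
ridge of `1e-6 tr(Sigma)/5` on each covariance diagonal (ADC is an exact
linear combination of AD and RD, so without the ridge the M-step
covariances are singular), and convergence when the relative
log-likelihood change drops below 1e-6. The log-likelihood trace is stored
so the EM monotonicity guarantee is auditable.

Soft membership is the posterior responsibility
`gamma_k ∝ pi_k N(x; mu_k, Sigma_k)`. Because posteriors over K components
sum to one, they cannot all be small, so a "below threshold for all
clusters" rule cannot operate on posteriors. It is implemented instead on
per-component *typicality*: the upper-tail chi-square(5) probability of the
squared Mahalanobis distance to each component. A voxel whose typicality is
below 0.05 for every physiological component is in the far tail of all of
them and joins the lesion cluster (PL). For data truly generated by a
well-separated fitted mixture of full-rank Gaussians, the flagged fraction
is close to the 0.05 threshold by construction.

One consequence deserves honesty: in real pipelines the five features are
rank-deficient (ADC is determined by AD and RD), so within-compartment
squared distances behave like chi-square with ~4, not 5, degrees of
freedom, and the in-model flag rate sits near
`P(chi2_4 > 11.07) ≈ 0.026` rather than 0.05. Training the mixture on a
pooled healthy cohort (the default for lesion detection) widens the
component covariances by the between-subject variance and pushes the
per-subject false-flag rate down to ~2%, but not to zero: recovered lesion
fractions carry a systematic excess of about +0.02. Small planted fractions
are therefore overestimated by roughly that amount; this is a property of
the five-feature/0.05-threshold design itself, not of the estimation.

Components are mapped to names by their physiology: highest mean FA is PV
(coherent flow), and of the remaining two the higher mean T2* is IVS
(oxygen-rich maternal blood) versus PT. Ties within 1e-6 raise an error
demanding manual mapping rather than guessing. Hard labels take the argmax
posterior among non-PL voxels.

## Depth layers

`compute_depth()` assigns every placental voxel
`depth = d_c / (d_c + d_b)`, where `d_c`, `d_b` are exact Euclidean
distances (mm, anisotropic voxels honoured) to the chorionic and basal
surface masks, computed with a separable squared-distance transform.
`assign_layers()` cuts depth into five equal-width bins labelled B
(chorionic, fetal side) through F (basal, maternal side); depth exactly 1
joins F. Equal-width rather than equal-count bins is a deliberate choice —
it keeps layer geometry comparable across subjects — and the bin count is
configurable. Surface masks are inputs: the phantom provides them, and
clinical use would derive them from manual plate annotations; automatic
plate detection is out of scope.

## Cohort statistics

All tests are two-sided and reported without multiplicity adjustment (an
optional Holm flag is a one-liner away via `p.adjust`); significance tiers
in figures follow the *P* < 0.05 / 0.01 / 0.005 convention.

* `linreg()` — ordinary least squares with the slope t-test, R², and the
  pointwise 95% confidence band of the mean response.
* `mann_whitney()` — U from midranks; exact two-sided p for small samples
  (full enumeration under ties when the combination count is feasible, the
  exact untied U distribution otherwise) and a tie-corrected,
  continuity-corrected normal approximation beyond that. The approximation
  is good to ~0.011 at n = 8 vs 8.
* `ga_binned_comparison()` — GA bins < 25, 25–35, > 35 weeks with closed
  lower edges (GA exactly 25 falls in the middle bin), pairwise U-tests.
* `pl_group_analysis()`, `brain_placenta_correlations()`,
  `layerwise_trend()` — lesion-burden group comparison and regression on GA
  at delivery, brain-vs-compartment T2* regressions ranked by R² (brain
  regressed on placenta; the direction does not change R²), and per-layer
  trend tables.

## The digital phantom

No patient data ships with an analysis method, so validation rests on a
synthetic phantom that reproduces the statistical structure the analyses
assume — and records every generative parameter as ground truth.

**Geometry.** An ellipsoidal slab (default 48 x 48 x 16 voxels of 3 mm)
split in-plane into five cotyledon-like Voronoi lobules. Vessel voxels
concentrate near the chorionic plate and along lobule boundaries, IVS cores
sit at mid-depth lobule centres, tissue fills the rest; compartment voxel
counts match the requested volume fractions exactly (default
IVS/PV/PT = 0.35/0.20/0.45). Lesions are planted as ellipsoids of exactly
the requested voxel count. An optional small sphere outside the placenta
stands in for the fetal brain so volume/T2* summaries can be exercised.

**Feature draws.** Each voxel draws (ADC, FA, AD, RD, T2*) from its
compartment's Gaussian. The diffusion features are not free: the voxel's
tensor takes eigenvalues (AD, RD + delta, RD - delta), sorted, with delta
solved so the tensor's FA equals the drawn FA exactly; ADC is recomputed as
(AD + 2RD)/3 and the drawn ADC discarded (re-drawn if it disagrees by more
than 15% — the tolerance accommodates published lesion parameter sets whose
ADC and eigenvalue averages disagree by up to 12%). Draws with FA below the
feasible minimum, negative tail eigenvalues, or AD < RD are rejected and
re-drawn, so realized compartment means can sit slightly off the nominal
values (the recorded truth is always the realized draw). Principal axes
are uniformly random rotations.

**Signals and noise.** Multi-echo volumes follow `S0 exp(-TE/T2*)` (ten
echoes, 5–90 ms), DWI follows `S0 exp(-b g'Dg)` (b = 0 plus twelve
evenly-spread hemisphere directions at b = 700 s/mm²) — typical of
placental protocols and fully configurable. Rician noise
(`sqrt((S + n1)² + n2²)`) is added at a default SNR of 25 defined at the
shortest echo / b = 0. Identical seeds give bit-identical datasets.

**Cohorts.** `generate_cohort()` draws GA uniformly over a range (default
20–38 weeks), gives each subject compartment T2* means following linear
trends (defaults: IVS -1.5, PV -1.8, PT 0 ms/week around reference values
100/75/55 ms at 30 weeks; between-subject SD 4 ms — magnitudes chosen to
be physiologically plausible at 3 T), couples fetal-brain T2* to the
subject's IVS T2* (coefficient 0.8, residual SD 2.5 ms), plants lesions in
a design-set fraction of subjects (fraction drawn from 0.14–0.38), and
makes GA at delivery decline with lesion burden. These defaults *are* the
study conditions for the package's validation; they are set once and not
tuned per experiment.

**What the phantom does not emulate.** Motion, k-space artifacts,
perfusion (IVIM) signal, partial-volume mixing at compartment borders,
spatial correlation of noise, and between-subject variation in diffusion
features (only T2* varies across subjects). Passing phantom tests
therefore demonstrates correctness of the estimators and the pipeline
logic under the stated generative model — not robustness to everything
clinical data can do.

## Numerical choices and edge cases

* EM ridge `1e-6 tr/5`, restart on singular covariance, error with
  condition numbers if all restarts fail; empty components (fewer than
  p + 1 expected members) abort a restart.
* Mixture fits require at least 50 K rows; `subsample_stability()` refits
  on random subsamples (default 10 000 voxels x 10 repeats) and reports
  per-component coefficients of variation after matching components to the
  full-data fit by minimum-cost permutation.
* T2* decay rate <= 0, T2* above 300 ms, or < 3 positive echoes: voxel
  invalid, never an exception. Tensor: non-positive signal anywhere or a
  clipped negative eigenvalue invalidates the voxel.
* Depth requires disjoint, non-empty surface masks; a voxel at zero
  distance to both surfaces is an error (overlapping masks).
* All randomness flows through explicit integer seeds; restart and
  subject-level streams are derived child seeds, and the caller's RNG
  state is restored afterwards.

## Problem sizes used in the bundled validation

The test-suite phantoms use 24–36 voxel grids (2–11 k placental voxels),
cohorts of 22–27 subjects, mixtures trained on 30–50 k pooled voxels, and
1000-replicate null simulations for the type-I error of the binned
comparison; these sizes make every documented property measurable while
keeping a full run in a few minutes on one core.
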