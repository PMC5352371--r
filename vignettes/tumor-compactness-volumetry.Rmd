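---
title: "Volumetry, tumor compactness and response prediction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetry, tumor compactness and response prediction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compactvol)
```

## The scientific problem

After long-course preoperative chemoradiotherapy (CCRT), roughly one in
five patients with locally advanced rectal cancer (LARC) shows a
pathological complete response (pCR): no residual tumor in the surgical
specimen. Identifying likely complete responders before surgery matters for
organ-preserving ("watch and wait") strategies. Tumor volume measured on
pre-treatment MRI or CT predicts pCR moderately well; this package
implements a volumetry pipeline built around the idea that tumor *shape* —
specifically compactness — carries independent predictive signal, and that
folding it into the volume yields a better predictor.

The quantities computed from a 3D binary segmentation mask are:

* **RTV** (real tumor volume): foreground voxel count times physical voxel
  volume, in cm³.
* **SA_RTV** (surface-area surrogate): the volume of the outermost 1-mm
  layer, obtained by contracting the contour 3-dimensionally by 1 mm and
  subtracting the contracted volume from the full volume. A thin shell's
  volume is (thickness × area), so at fixed thickness it tracks the surface
  area.
* **Tumor compactness**: RTV / SA_RTV^1.5. Spherical tumors score high,
  spiculated ("sea-urchin") tumors low. The formula is applied literally to
  the two volumes in cm³: no √π normalizer and no division by the shell
  thickness, so the score is not dimensionless in a strict unit calculus.
  We preserve that convention deliberately — it is how the feature is
  defined in the clinical radiomics literature this pipeline follows, and
  every downstream use (correlation, regression, ROC) is invariant to a
  global constant anyway.
* **CATV** (cylindrical approximated tumor volume): π(d/2)²L from the
  maximal in-plane diameter d and maximal length L.
* **TCTV** (compactness-corrected tumor volume): RTV / compactness, which
  algebraically equals SA_RTV^1.5. TCTV blends tumor burden and shape into
  a single volume-scale score; the identity is checked to 1e-9 in the test
  suite.

## Contraction numerics: where the care went

The single numerically delicate operation is the 1-mm contraction on a
voxel grid, especially at anisotropic spacings like 0.78 × 1.14 × 5 mm.

A plain morphological erosion, or equivalently a threshold on the
voxel-center-to-voxel-center Euclidean distance transform, systematically
*under*-contracts: the nearest background voxel center sits up to one voxel
beyond the true contour, so the effective depth is about a quarter voxel
short. On a digitized sphere of radius 18.8 mm at 0.5 mm isotropic spacing
that bias produces a shell volume 12% below the closed form
4/3·π(r³−(r−1)³) — far worse than the discretization error of the volume
itself (<0.1%). Measuring instead to the staircase *surface* of the
background voxels over-contracts by a similar margin, because the minimum
distance is always attained at an inward-poking corner of the staircase.

`contract_mask()` therefore measures depth to a *smoothed* interface: the
binary mask is anti-aliased with a Gaussian of σ = half a voxel per axis,
evaluated on a 2× refined lattice, and the 0.5 level set of that field is
taken as the contour. For a flat boundary this surface sits exactly midway
through the boundary voxels wherever the lattice happens to cut it, which
removes the half-voxel bias; the Euclidean distance transform on the
refined lattice (an exact anisotropic Felzenszwalb–Huttenlocher transform
implemented in C++) then gives each voxel's depth. Grid-convergence checks
against analytic spheres give shell volumes within 2.4–2.8% and compactness
within 3.6–4.3% of the closed forms at 0.5 mm isotropic spacing, improving
as the grid refines; a 20 mm cube at 1 mm spacing still contracts to
exactly the interior 18³ voxels, and a single voxel still contracts to
nothing. The test suite pins the implementation against an independent
brute-force reconstruction of the same definition (direct convolution plus
exhaustive distance search) on small masks.

Two limitations follow from the surface model and are left visible rather
than corrected silently:

* structures about one voxel thin fall below the 0.5 level of the smoothed
  field and contract to nothing (their shell then equals their full volume,
  the formula's natural limit, and the feature row is flagged
  `empty_contraction`);
* at 5-mm slice spacing a 1-mm contraction cannot be resolved
  through-plane; `resample_isotropic()` offers nearest-neighbor resampling
  to a fine isotropic grid behind an explicit call, default off, because
  silently resampling would change the measured feature.

Long axis and maximal diameter are Feret diameters computed from the mask
(convex-hull extreme points per slice; their union bounds the 3D hull), an
approximation to manual caliper reads that is recorded as such. For very
large candidate sets the code thins by deterministic direction-extremes,
a documented approximation that does not trigger at clinical mask sizes.

## Dose–response model

The model-assisted comparison scores each patient with an externally
published logistic dose–response (tumor response probability, TRP) model:

logit P = b₀ + b₁·EQD2 + b_size·Y_vol + b_N·Y_N,

with EQD2 the equivalent dose in 2-Gy fractions, EQD2 = D(d + α/β)/(2 +
α/β); Y_vol a tumor volume in cm³; and Y_N = 0 for clinical N0, 1 for
N1–2. The b coefficients are configuration only — the package ships a YAML
schema with clearly-labelled placeholder numbers, never defaults — because
they belong to the external model, not to this pipeline. α/β defaults to
10 Gy, the conventional tumor value, and is likewise configuration.

The model was fitted with CATV as its volume covariate. To substitute RTV
or TCTV, `run_analysis()` first rescales them to share CATV's median
(`normalize_to_reference_median()`): the linear predictor is invariant to
rescaling a covariate only if its coefficient is rescaled inversely, so
median-matching is what makes one set of published coefficients applicable
to all three volume definitions. The median is the standard
midpoint-of-central-order-statistics definition. Because the TRP transform
is monotone in the volume when the other covariates are held fixed, a
volume-only coefficient vector yields exactly the volume's own AUC — a
property the tests assert at 1e-9.

## Statistical machinery

All of the statistics are implemented in the package and cross-checked in
the tests against independent routes (`glm`, `car::vif`, `pROC`, brute
force, bootstrap); the package's own code is always the route that runs.

* **Correlations**: Pearson product-moment r with the t-based p-value;
  Spearman as Pearson on average ranks with the same t approximation (the
  convention of the clinical statistics packages this pipeline mirrors).
* **Logistic regression**: maximum likelihood by IRLS/Newton, convergence
  at score max-norm < 1e-8 within 50 iterations, Wald standard errors from
  the inverse observed information, odds ratios with Wald 95% intervals.
  Complete or quasi-complete separation is detected (runaway coefficients
  together with boundary fitted probabilities) and reported as
  `converged = FALSE` with a diagnostic, never as silently huge estimates.
  The binary endpoint makes the effect measures odds ratios; time-to-event
  quantities play no role anywhere in the pipeline.
* **Nodal coding**: the package codes cN+ = 1 (cN1–2 vs cN0). In the
  reference cohort the pCR rate is *lower* in node-positive patients, so
  this coding gives an OR below 1; the commonly printed value 2.25 is the
  same association in the cN0-vs-cN+ direction. `reference_cohort()`
  reconstructs the 2×2 table from the published counts and both directions
  are reported in the tests and the acceptance script.
* **VIF screen**: VIF_j = 1/(1−R²_j) from the auxiliary OLS regression of
  predictor j on the others; 2.5 ≤ VIF < 10 flags "high", ≥ 10 "severe",
  exact collinearity is reported as infinite. When two volume measures are
  flagged together, `run_analysis()` drops the one named by `vif_drop`
  (default CATV, keeping RTV + compactness) — the screen's purpose is to
  keep one volume-scale predictor, not to pick a winner automatically.
* **ROC/AUC**: Mann–Whitney with half credit for ties; trapezoidal curve.
  `orientation = "auto"` flips a score whose association with the positive
  class is negative (volume-like predictors) and records the flip, so AUCs
  are reported above 0.5 the way clinical ROC software does.
* **DeLong comparison**: paired AUC difference with variance from the
  structural components (per-case placement values), z test, two-sided
  normal p. Identical scores give Δ = 0, p = 1 by convention; zero
  variance with a nonzero difference is a degenerate-case error.
* **ICC**: two-way random effects, absolute agreement, single measure —
  ICC(2,1) — from the two-way ANOVA mean squares. Readers are a sample and
  systematic offsets should count against agreement; the consistency
  variant would hide a constant reader bias. Bands: <0.40 poor, 0.40–0.59
  fair, 0.60–0.74 good, 0.75–1.0 excellent.
* **Multiplicity**: no multiple-testing adjustment is applied anywhere,
  matching the analysis style the pipeline reproduces; all tests are
  two-sided.

## The synthetic-data generator

There is no deposited imaging or cohort data, so the generator is a
first-class module and defines the study conditions for every simulation
in the package.

**Phantoms** (`make_phantom()`): digitized spheres, ellipsoids, and spiky
"sea-urchin" shapes — a base sphere carrying radial Gaussian bumps in
seeded uniform directions. Spheres and ellipsoids have closed-form
volumetry (`analytic_sphere_features()` is the test oracle); the spiky
family exists to span the compact-to-spiculated compactness range, and the
suite asserts the ordering sphere > 3:1 ellipsoid > spiky at comparable
volume. Spherical-harmonic surface perturbations would be a natural
extension but are not needed to exercise the pipeline.

**Cohorts** (`simulate_cohort()`): feature-level simulation is the
default for speed; phantom-level feature extraction feeds the same
analysis when end-to-end runs are wanted. The defaults are calibrated once
to the published summaries of the 122-patient reference cohort and then
frozen:

* RTV ~ lognormal(log 27.75, 0.8) cm³ (median 27.75, 0.4–99.6% range
  3.3–230 vs the published 3.85–289.4);
* compactness ~ gamma(shape 6, rate 6/1.95) (median 1.84, range 0.48–4.7
  vs 0.64–4.62); the published report gives no distributional forms, so
  lognormal/gamma are declared choices, not inferences;
* CATV = RTV · (compactness/1.84)^−0.45 · lognormal(0, 0.45), rescaled to
  median 71.14 — reproducing the published correlation pattern (Pearson
  ≈ 0.8 and Spearman ≈ 0.85 with RTV; Spearman ≈ −0.2 with compactness;
  near-zero RTV–compactness correlation);
* cN 0/1/2 at 31/55/36 per 122; chemotherapy 112:10 FL-based vs
  capecitabine-based; surgery interval 29/57/36 across the three
  categories; dose schedules mixing the five delivered fractionations
  (44/22, 45/25, 50.4/28, 53.2/28 approximating the dose-painting arm,
  54/30), which lands the EQD2 strata at 16.4/32.8/50.8%;
* outcome P(pCR) = logistic(β·x) with default β carrying the published
  multivariate effect directions — volume log(0.966) per cm³, compactness
  log(4.103), cN+ −log(3.701) under the cN+ = 1 coding — and intercept
  −2.5612 solved once so the marginal prevalence is 18.9%.

A single global seed drives every sub-draw, so cohorts and their CSVs are
byte-reproducible. `simulate_reader()` perturbs a mask boundary with a
smooth seeded random field of bounded physical amplitude to emulate
inter-observer contouring variability for ICC studies.

What the generator deliberately does **not** emulate: real lesion
morphology (rectal tumors are annular/curved, not spheres), imaging
physics and noise, modality differences between MRI and CT, reader bias
with structure beyond a smooth boundary field, and any survival endpoint.
Passing tests therefore demonstrate that the *machinery* is correct and
that the qualitative conclusions (TCTV outranking RTV under the calibrated
effect directions) follow from the stated model — not that those
conclusions transfer to any particular clinical dataset.

## Problem sizes and numerical tolerances

The simulations are sized to be decisive yet quick: parameter recovery
uses 200 replicates of n = 2000 (bias within 5% of each true coefficient;
95% CI coverage within [0.92, 0.98]); the AUC-ordering property uses 20
seeded replicates of n = 300; DeLong null calibration uses 1000 replicates
at n = 50 (Kolmogorov–Smirnov distance from uniform < 0.05); the DeLong
variance check compares against a 10,000-draw bootstrap at n = 30 (within
15%). Geometry checks run at 0.5 mm isotropic spacing where the sphere
closed forms are reproduced within 5%.

Observed behavior worth knowing: Wald interval coverage for the RTV
coefficient sits at the low edge (≈92%) of the accepted band — the
lognormal volume covariate produces high-leverage observations for which
Wald intervals are slightly anticonservative. Likelihood-ratio or
profile intervals would tighten this but are out of scope for a pipeline
mirroring Wald-based clinical software output.

Degenerate inputs are errors, not silent results: empty masks, one-class
outcomes, rank-deficient designs, constant rating matrices, zero-variance
correlations, zero medians in the normalizer, and missing TRP coefficients
all raise typed messages naming the problem. Missing covariate rows are
excluded listwise with a logged count. Multi-component masks are accepted
with a warning and a `multi_component` flag, since slice-wise contours can
disconnect.
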