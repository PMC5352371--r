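# compactvol

Shape-aware tumor volumetry from 3D segmentation masks, and the statistics
to turn it into a predictor of pathological complete response (pCR) after
preoperative chemoradiotherapy in locally advanced rectal cancer.

## What it computes

About one in five rectal cancers treated with long-course chemoradiotherapy
regresses completely before surgery. Pre-treatment tumor volume predicts
this moderately; this package implements the hypothesis that tumor *shape*
adds independent signal. From a binary mask with physical voxel spacing it
computes:

| feature | definition |
|---|---|
| RTV | foreground voxels × voxel volume (cm³) |
| SA_RTV | volume of the outermost 1-mm layer: RTV − volume after a 3D 1-mm contraction |
| compactness | RTV / SA_RTV^1.5 — high for spheres, low for spiculated tumors |
| CATV | π(d/2)²·L from maximal diameter and length (cylinder approximation) |
| TCTV | RTV / compactness ≡ SA_RTV^1.5 — volume corrected by shape |

and runs the statistical comparison around them: Pearson/Spearman
correlations, VIF-screened univariate/multivariate logistic regression
(odds ratios with Wald 95% CI), ROC curves with paired DeLong tests, a
logistic EQD2 dose–response (TRP) model with substitutable median-normalized
volume covariates, and ICC(2,1) for inter-observer agreement. A synthetic
module generates digitized phantoms (sphere / ellipsoid / sea-urchin) with
closed-form oracles and simulated cohorts with known effect sizes, so the
whole pipeline is testable without any imaging data.

The contraction — the one numerically delicate step — is an exact
anisotropic Euclidean distance transform (C++) measured against a
half-voxel-Gaussian-smoothed mask interface on a 2× refined lattice; see
the methods vignette (`vignettes/tumor-compactness-volumetry.Rmd`) for why
voxel-center distances are biased by a quarter voxel and how the smoothed
convention fixes it.

## Worked example

```r
library(compactvol)

sphere <- make_phantom(shape_spec("sphere", radius_mm = 15))
urchin <- make_phantom(shape_spec("spiky", radius_mm = 11, spike_count = 30,
                                  spike_amplitude_mm = 6, seed = 4))
dplyr::bind_rows(extract_features(sphere, id = "sphere"),
                 extract_features(urchin, id = "sea-urchin"))
#>           id rtv_cm3 sa_rtv_cm3 compactness tctv_cm3
#> 1     sphere    14.1       2.54         3.5     4.05
#> 2 sea-urchin    12.4       3.09         2.3     5.42
```

The two phantoms have similar volumes (14.1 vs 12.4 cm³) but the spiky one
exposes more surface shell (3.09 vs 2.54 cm³), so its compactness is lower
(2.3 vs 3.5) and its shape-corrected volume TCTV is larger — exactly the
contrast the feature is built to capture.

```r
cohort <- simulate_cohort(cohort_sim_spec(n = 300, seed = 42))
report <- run_analysis(cohort)
report
#> <cohort_analysis>
#>   n = 300 analyzed (0 dropped), pCR prevalence 15.0%
#>   ROC (predefined volumes):
#>     rtv_cm3    AUC 0.652 (0.574-0.730)
#>     catv_cm3   AUC 0.713 (0.638-0.788)
#>     tctv_cm3   AUC 0.771 (0.703-0.839)

report$roc_volume_pairs[, c("score_a", "score_b", "auc_difference", "p_value")]
#>    score_a  score_b auc_difference  p_value
#> 1  rtv_cm3 catv_cm3        -0.0613 3.30e-02
#> 2  rtv_cm3 tctv_cm3        -0.1187 1.66e-05
#> 3 catv_cm3 tctv_cm3        -0.0574 2.95e-02
```

Under the calibrated effect directions (volume harms, compactness helps the
pCR odds), the shape-corrected TCTV discriminates best, and the paired
DeLong test quantifies the gain over raw RTV. `autoplot(report, cohort)`
draws the overlaid ROC curves; `tidy()`/`glance()` work on the logistic and
ROC-comparison objects. A thin CLI over the same functions lives at
`inst/cli/compactvol.R` (subcommands `features`, `simulate-shapes`,
`simulate-cohort`, `analyze`, `roc-compare`).

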