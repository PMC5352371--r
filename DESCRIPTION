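Package: compactvol
Title: Tumor Volumetry, Compactness and Volumetry-Based Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Shape-aware tumor volumetry from 3D binary segmentation masks
    with physical voxel spacing, and the statistical pipeline that turns those
    features into a prediction model for pathological complete response after
    preoperative chemoradiotherapy in locally advanced rectal cancer. Computes
    the real tumor volume (RTV), a contraction-based surface-area surrogate
    (the outermost 1-mm shell), tumor compactness, the cylindrical approximated
    tumor volume (CATV) and the compactness-corrected tumor volume (TCTV);
    generates synthetic phantoms and simulated cohorts with known effect sizes;
    converts fractionation schedules to EQD2 and evaluates a logistic
    dose-response model with substitutable volume covariates; and provides the
    statistical machinery for the comparison: correlations, VIF-screened
    logistic regression, ROC curves with paired DeLong tests, and intraclass
    correlation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
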