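toy_trp <- function() trp_coefficients(-1, 0.05, -0.01, -0.5)

test_that("the report contains every enabled section with finite values", {
  d <- simulate_cohort(cohort_sim_spec(n = 300, seed = 77))
  rep <- run_analysis(d, trp_coefs = toy_trp(), subgroup_col = "chemo")

  expect_s3_class(rep, "cohort_analysis")
  expect_equal(rep$summary$n, 300L)
  expect_setequal(
    rep$volumetry$feature,
    c("rtv_cm3", "compactness", "catv_cm3", "tctv_cm3")
  )
  expect_equal(nrow(rep$correlations), 6L) # 3 pairs x 2 methods
  expect_true(all(is.finite(rep$correlations$estimate)))
  expect_true(all(is.finite(rep$univariate$odds_ratio)))
  expect_true(all(is.finite(rep$vif$vif)))
  expect_true(all(is.finite(rep$multivariate$estimate)))
  expect_equal(nrow(rep$roc_volumes), 3L)
  expect_equal(nrow(rep$roc_volume_pairs), 3L)
  expect_equal(nrow(rep$roc_trp), 3L)
  expect_equal(nrow(rep$roc_trp_pairs), 3L)
  expect_true(all(is.finite(rep$roc_volume_pairs$p_value)))
  expect_true(all(rep$roc_volumes$ci_low <= rep$roc_volumes$auc))
  expect_true(nrow(rep$subgroups) >= 1)
  p <- autoplot(rep, cohort = d)
  expect_s3_class(p, "ggplot")
})

test_that("the VIF screen drops the configured collinear volume measure", {
  d <- simulate_cohort(cohort_sim_spec(n = 400, seed = 78))
  rep <- run_analysis(d)
  # CATV is strongly coupled to RTV in the generator, so both sit in the
  # flag band and the default rule drops CATV, keeping RTV + compactness
  flagged <- rep$vif$predictor[rep$vif$flag != "ok"]
  expect_true(all(c("rtv_cm3", "catv_cm3") %in% flagged))
  expect_identical(rep$vif_dropped, "catv_cm3")
  expect_false("catv_cm3" %in% rep$multivariate$term)
  expect_true(all(c("rtv_cm3", "compactness") %in% rep$multivariate$term))
  expect_true(all(rep$vif_after$vif < 2.5))
})

test_that("model-assisted stage fails loudly without inputs and is monotone-consistent", {
  d <- simulate_cohort(cohort_sim_spec(n = 200, seed = 79))
  expect_error(
    run_analysis(d[, setdiff(names(d), "eqd2_gy")], trp_coefs = toy_trp()),
    "eqd2_gy"
  )

  # with a volume-only model, trp is a monotone transform of the volume, so
  # the trp AUC equals the volume AUC
  co <- trp_coefficients(0, 0, -0.05, 0)
  rep <- run_analysis(d, trp_coefs = co)
  expect_equal(
    rep$roc_trp$auc[rep$roc_trp$score == "trp_rtv"],
    rep$roc_volumes$auc[rep$roc_volumes$score == "rtv_cm3"],
    tolerance = 1e-9
  )
  expect_equal(
    rep$roc_trp$auc[rep$roc_trp$score == "trp_tctv"],
    rep$roc_volumes$auc[rep$roc_volumes$score == "tctv_cm3"],
    tolerance = 1e-9
  )
})

test_that("rows with missing covariates are excluded listwise with a log", {
  d <- simulate_cohort(cohort_sim_spec(n = 120, seed = 80))
  d$compactness[c(3, 50)] <- NA
  expect_message(rep <- run_analysis(d), "excluding 2 row")
  expect_equal(rep$meta$n_analyzed, 118L)
  expect_equal(rep$meta$n_dropped_missing, 2L)
})

test_that("reports serialize to per-table CSVs plus JSON", {
  d <- simulate_cohort(cohort_sim_spec(n = 150, seed = 81))
  rep <- run_analysis(d)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  files <- list.files(dir)
  expect_true(all(c(
    "summary.csv", "volumetry.csv", "correlations.csv",
    "univariate.csv", "multivariate.csv", "roc_volumes.csv",
    "roc_volume_pairs.csv", "report.json"
  ) %in% files))
  back <- readr::read_csv(file.path(dir, "roc_volumes.csv"), show_col_types = FALSE)
  expect_equal(back$auc, rep$roc_volumes$auc)
})

test_that("TCTV outranks RTV in most replicates under the calibrated effects", {
  wins <- vapply(1:20, function(seed) {
    d <- simulate_cohort(cohort_sim_spec(n = 300, seed = 1000 + seed))
    rep <- run_analysis(d)
    a <- rep$roc_volumes
    a$auc[a$score == "tctv_cm3"] > a$auc[a$score == "rtv_cm3"]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("phantom-to-report pipeline runs end to end deterministically", {
  dir <- withr::local_tempdir()
  radii <- c(8, 10, 12, 14)
  for (i in seq_along(radii)) {
    write_mask(
      make_phantom(shape_spec("spiky",
        radius_mm = radii[i], spike_count = 10,
        spike_amplitude_mm = 3, seed = i
      )),
      file.path(dir, sprintf("t%02d.nii.gz", i))
    )
  }
  feats1 <- run_feature_extraction(dir)
  feats2 <- run_feature_extraction(dir)
  expect_equal(as.data.frame(feats1), as.data.frame(feats2))
  # CATV built from the cylinder formula correlates positively with RTV
  # across phantoms of varying size
  expect_gt(correlate(feats1$catv_cm3, feats1$rtv_cm3, "pearson")$estimate, 0)
})
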