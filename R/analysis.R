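#' Batch feature extraction over a directory of masks
#'
#' Reads every mask file in a directory, extracts the full volumetry feature
#' set, and optionally writes a features CSV. Per-file failures (unreadable
#' or empty masks) are collected into flagged rows and logged to stderr; the
#' run continues, and only a run where every file fails is an error.
#'
#' @param dir Directory containing `.nii`, `.nii.gz` or `.nrrd` masks.
#' @param depth_mm Contraction depth in mm (default 1).
#' @param out_csv Optional output CSV path.
#' @param pattern Filename regexp (default NIfTI/NRRD extensions).
#' @return A tibble, one row per file, with the [extract_features()] columns
#'   plus `file`; failed files carry NA features and an `error:` flag.
#' @export
run_feature_extraction <- function(dir, depth_mm = 1, out_csv = NULL,
                                   pattern = "\\.(nii|nii\\.gz|nrrd)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no readable mask files in ", dir, call. = FALSE)
  rows <- purrr::map(files, function(f) {
    res <- tryCatch(
      {
        m <- read_mask(f)
        feats <- extract_features(m, depth_mm = depth_mm, id = basename(f))
        feats$file <- f
        feats
      },
      error = function(e) {
        message("feature extraction failed for ", basename(f), ": ", conditionMessage(e))
        tibble::tibble(
          id = basename(f), rtv_cm3 = NA_real_, sa_rtv_cm3 = NA_real_,
          compactness = NA_real_, long_axis_cm = NA_real_,
          diameter_cm = NA_real_, catv_cm3 = NA_real_, tctv_cm3 = NA_real_,
          n_components = NA_integer_,
          flags = paste0("error:", conditionMessage(e)), file = f
        )
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  if (all(grepl("^error:", out$flags))) {
    stop("feature extraction failed for every file in ", dir, call. = FALSE)
  }
  if (!is.null(out_csv)) readr::write_csv(out, out_csv, progress = FALSE)
  out
}

#' Full volumetry-based response analysis of a cohort
#'
#' Runs the complete statistical comparison on a cohort table with volumetry
#' features and a binary pCR endpoint, in seven stages:
#' \enumerate{
#'   \item volumetry medians/ranges and pairwise Pearson + Spearman
#'     correlations among CATV, RTV and compactness;
#'   \item univariate logistic regression per predictor;
#'   \item a VIF multicollinearity screen — when two or more volume measures
#'     sit in the flag band (VIF >= 2.5) the one named by `vif_drop`
#'     (default CATV) is removed, keeping RTV + compactness;
#'   \item multivariate logistic regression on the retained predictors;
#'   \item ROC curves for RTV, CATV and TCTV with all three pairwise DeLong
#'     comparisons;
#'   \item if `trp_coefs` is supplied, the model-assisted comparison: RTV
#'     and TCTV are median-normalized to CATV's median, each patient is
#'     scored with the dose-response model under each volume definition,
#'     and the three score sets are compared pairwise;
#'   \item optional subgroup reruns of the ROC comparison over the levels of
#'     `subgroup_col`.
#' }
#' Rows with missing model covariates are excluded listwise with a logged
#' count.
#'
#' @param cohort A data frame with `pcr` plus feature columns `rtv_cm3`,
#'   `compactness`, `catv_cm3` (and `tctv_cm3`, derived if absent), and for
#'   the model-assisted stage `eqd2_gy` and `cn_pos`.
#' @param predictors Columns entering the univariate screen and (subject to
#'   the VIF rule) the multivariate model. Defaults to the available ones
#'   among age, nodal status, EQD2, RTV, compactness, CATV.
#' @param trp_coefs Optional [trp_coefficients()] enabling stage 6.
#' @param vif_drop Volume column to drop when the VIF screen flags
#'   collinear volume measures (default `"catv_cm3"`).
#' @param subgroup_col Optional column name for stage 7.
#' @return A `cohort_analysis` object: a list of tibbles (`summary`,
#'   `volumetry`, `correlations`, `univariate`, `vif`, `vif_after`,
#'   `multivariate`, `roc_volumes`, `roc_volume_pairs`, `roc_trp`,
#'   `roc_trp_pairs`, `subgroups`, `meta`).
#' @examples
#' d <- simulate_cohort(cohort_sim_spec(n = 300, seed = 11))
#' rep <- run_analysis(d)
#' rep$roc_volumes
#' @export
run_analysis <- function(cohort,
                         predictors = NULL,
                         trp_coefs = NULL,
                         vif_drop = "catv_cm3",
                         subgroup_col = NULL) {
  if (!"pcr" %in% names(cohort)) {
    stop("configuration error: analysis requires a `pcr` endpoint column", call. = FALSE)
  }
  feat <- c("rtv_cm3", "compactness", "catv_cm3")
  missing_feat <- setdiff(feat, names(cohort))
  if (length(missing_feat)) {
    stop("configuration error: volumetry stage is missing column(s): ",
      paste(missing_feat, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"tctv_cm3" %in% names(cohort)) {
    cohort$tctv_cm3 <- cohort$rtv_cm3 / cohort$compactness
  }
  if (is.null(predictors)) {
    predictors <- intersect(
      c("age", "cn_pos", "eqd2_gy", "rtv_cm3", "compactness", "catv_cm3"),
      names(cohort)
    )
  }

  model_cols <- unique(c("pcr", predictors, feat, "tctv_cm3"))
  complete <- stats::complete.cases(cohort[, model_cols])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("excluding ", n_dropped, " row(s) with missing model covariates (listwise)")
  }
  d <- cohort[complete, ]

  # 1 -- volumetry summary + correlations
  volumetry <- tidyr::pivot_longer(
    d[, c(feat, "tctv_cm3")],
    dplyr::everything(),
    names_to = "feature", values_to = "value"
  ) %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(
      median = stats::median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
  pairs <- utils::combn(feat, 2, simplify = FALSE)
  correlations <- purrr::map_dfr(pairs, function(pr) {
    dplyr::bind_rows(
      correlate(d[[pr[1]]], d[[pr[2]]], "pearson"),
      correlate(d[[pr[1]]], d[[pr[2]]], "spearman")
    ) %>%
      dplyr::mutate(var_a = pr[1], var_b = pr[2], .before = 1)
  })

  # 2 -- univariate logistic per predictor
  univariate <- purrr::map_dfr(predictors, function(pv) {
    fit <- fit_logistic(d[, pv, drop = FALSE], d$pcr)
    tidy(fit) %>%
      dplyr::filter(.data$term != "(Intercept)") %>%
      dplyr::mutate(converged = fit$converged)
  })

  # 3 -- VIF screen with the configured exclusion rule
  numeric_preds <- predictors[vapply(d[predictors], is.numeric, logical(1))]
  vif_before <- if (length(numeric_preds) >= 2) vif(d[, numeric_preds]) else NULL
  retained <- predictors
  dropped <- character(0)
  if (!is.null(vif_before)) {
    vols <- intersect(c("rtv_cm3", "catv_cm3", "compactness", "tctv_cm3"), numeric_preds)
    flagged_vols <- vif_before$predictor[vif_before$flag != "ok" &
      vif_before$predictor %in% vols]
    if (length(flagged_vols) >= 2 && vif_drop %in% retained) {
      retained <- setdiff(retained, vif_drop)
      dropped <- vif_drop
    }
  }
  numeric_after <- retained[vapply(d[retained], is.numeric, logical(1))]
  vif_after <- if (length(numeric_after) >= 2) vif(d[, numeric_after]) else NULL

  # 4 -- multivariate logistic on the retained set
  multi_fit <- fit_logistic(d[, retained, drop = FALSE], d$pcr)
  multivariate <- tidy(multi_fit) %>%
    dplyr::mutate(converged = multi_fit$converged)

  # 5 -- ROC over the three predefined volumes + pairwise DeLong
  roc_volumes <- roc_table(d, c("rtv_cm3", "catv_cm3", "tctv_cm3"))
  roc_volume_pairs <- roc_pair_table(d, c("rtv_cm3", "catv_cm3", "tctv_cm3"))

  # 6 -- model-assisted comparison
  roc_trp <- NULL
  roc_trp_pairs <- NULL
  if (!is.null(trp_coefs)) {
    need <- c("eqd2_gy", "cn_pos")
    if (!all(need %in% names(d))) {
      stop("configuration error: model-assisted stage requires column(s): ",
        paste(setdiff(need, names(d)), collapse = ", "),
        call. = FALSE
      )
    }
    d$trp_catv <- trp(trp_coefs, d$eqd2_gy, d$catv_cm3, d$cn_pos)
    d$trp_rtv <- trp(
      trp_coefs, d$eqd2_gy,
      normalize_to_reference_median(d$rtv_cm3, d$catv_cm3), d$cn_pos
    )
    d$trp_tctv <- trp(
      trp_coefs, d$eqd2_gy,
      normalize_to_reference_median(d$tctv_cm3, d$catv_cm3), d$cn_pos
    )
    trp_cols <- c("trp_catv", "trp_rtv", "trp_tctv")
    roc_trp <- roc_table(d, trp_cols)
    roc_trp_pairs <- roc_pair_table(d, trp_cols)
  }

  # 7 -- subgroup reruns of the direct ROC comparison
  subgroups <- NULL
  if (!is.null(subgroup_col)) {
    if (!subgroup_col %in% names(d)) {
      stop("configuration error: subgroup column not found: ", subgroup_col,
        call. = FALSE
      )
    }
    subgroups <- purrr::map_dfr(
      split(d, d[[subgroup_col]]),
      function(sd) {
        if (length(unique(sd$pcr)) < 2 || nrow(sd) < 10) {
          return(NULL)
        }
        roc_table(sd, c("rtv_cm3", "catv_cm3", "tctv_cm3")) %>%
          dplyr::mutate(
            subgroup = as.character(sd[[subgroup_col]][1]),
            n = nrow(sd), .before = 1
          )
      }
    )
  }

  structure(
    list(
      summary = cohort_summary(d),
      volumetry = volumetry,
      correlations = correlations,
      univariate = univariate,
      vif = vif_before,
      vif_after = vif_after,
      vif_dropped = dropped,
      multivariate = multivariate,
      roc_volumes = roc_volumes,
      roc_volume_pairs = roc_volume_pairs,
      roc_trp = roc_trp,
      roc_trp_pairs = roc_trp_pairs,
      subgroups = subgroups,
      meta = tibble::tibble(
        n_input = nrow(cohort), n_analyzed = nrow(d),
        n_dropped_missing = n_dropped,
        predictors = paste(predictors, collapse = ","),
        retained = paste(retained, collapse = ","),
        model_assisted = !is.null(trp_coefs)
      )
    ),
    class = "cohort_analysis"
  )
}

roc_table <- function(d, cols) {
  purrr::map_dfr(cols, function(cl) {
    auc_ci(d[[cl]], d$pcr) %>%
      dplyr::mutate(score = cl, .before = 1)
  })
}

roc_pair_table <- function(d, cols) {
  prs <- utils::combn(cols, 2, simplify = FALSE)
  purrr::map_dfr(prs, function(pr) {
    tidy(delong_compare(d[[pr[1]]], d[[pr[2]]], d$pcr)) %>%
      dplyr::mutate(score_a = pr[1], score_b = pr[2], .before = 1)
  })
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  cat(sprintf(
    "  n = %d analyzed (%d dropped), pCR prevalence %.1f%%\n",
    x$meta$n_analyzed, x$meta$n_dropped_missing, x$summary$pcr_prevalence_pct
  ))
  cat("  ROC (predefined volumes):\n")
  for (i in seq_len(nrow(x$roc_volumes))) {
    cat(sprintf(
      "    %-10s AUC %.3f (%.3f-%.3f)\n",
      x$roc_volumes$score[i], x$roc_volumes$auc[i],
      x$roc_volumes$ci_low[i], x$roc_volumes$ci_high[i]
    ))
  }
  if (!is.null(x$roc_trp)) {
    cat("  ROC (model-assisted):\n")
    for (i in seq_len(nrow(x$roc_trp))) {
      cat(sprintf(
        "    %-10s AUC %.3f (%.3f-%.3f)\n",
        x$roc_trp$score[i], x$roc_trp$auc[i],
        x$roc_trp$ci_low[i], x$roc_trp$ci_high[i]
      ))
    }
  }
  invisible(x)
}

#' Plot the ROC comparison of a cohort analysis
#'
#' Overlaid ROC curves for the three predefined volumes (or the
#' model-assisted scores when `stage = "trp"`).
#'
#' @param object A `cohort_analysis`.
#' @param stage `"volumes"` or `"trp"`.
#' @param cohort The cohort the analysis was run on (curves are recomputed
#'   from the scores).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_analysis <- function(object, cohort, stage = c("volumes", "trp"), ...) {
  stage <- match.arg(stage)
  cols <- if (stage == "volumes") {
    c("rtv_cm3", "catv_cm3", "tctv_cm3")
  } else {
    c("trp_catv", "trp_rtv", "trp_tctv")
  }
  if (!"tctv_cm3" %in% names(cohort)) {
    cohort$tctv_cm3 <- cohort$rtv_cm3 / cohort$compactness
  }
  curves <- purrr::map_dfr(cols, function(cl) {
    r <- roc(cohort[[cl]], cohort$pcr)
    dplyr::mutate(r$curve, score = sprintf("%s (AUC %.3f)", cl, r$auc))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, color = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Serialize an analysis report
#'
#' Writes the report as one JSON file plus per-table CSVs alongside it.
#'
#' @param report A `cohort_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "cohort_analysis")) {
    stop("`report` must be a cohort_analysis", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- purrr::keep(report, is.data.frame)
  purrr::iwalk(tabs, function(tb, nm) {
    readr::write_csv(tb, file.path(dir, paste0(nm, ".csv")), progress = FALSE)
  })
  json <- jsonlite_if_available(tabs)
  writeLines(json, file.path(dir, "report.json"))
  invisible(dir)
}

# jsonlite ships with the environment's tidyverse stack; fall back to a
# minimal serializer if it is ever absent
jsonlite_if_available <- function(x) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    paste(utils::capture.output(utils::str(x)), collapse = "\n")
  }
}
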