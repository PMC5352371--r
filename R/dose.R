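#' Fractionation schedule
#'
#' A radiotherapy dose scheme under the linear-quadratic model. Either
#' `dose_per_fraction_gy` or `n_fractions` determines the other via the total
#' dose; supplying all three requires consistency.
#'
#' @param total_dose_gy Total physical dose in Gy (> 0).
#' @param n_fractions Number of fractions (positive integer).
#' @param dose_per_fraction_gy Dose per fraction in Gy; defaults to
#'   `total_dose_gy / n_fractions`.
#' @param alpha_beta_gy Tissue alpha/beta ratio in Gy (> 0). 10 Gy is the
#'   conventional tumor value and is configuration, not dogma.
#' @return A `dose_scheme` list.
#' @export
dose_scheme <- function(total_dose_gy, n_fractions,
                        dose_per_fraction_gy = NULL, alpha_beta_gy = 10) {
  if (!is.numeric(total_dose_gy) || total_dose_gy <= 0) {
    stop("`total_dose_gy` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_fractions) || n_fractions <= 0 ||
    abs(n_fractions - round(n_fractions)) > 1e-8) {
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(alpha_beta_gy) || alpha_beta_gy <= 0) {
    stop("`alpha_beta_gy` must be positive", call. = FALSE)
  }
  d <- total_dose_gy / n_fractions
  if (is.null(dose_per_fraction_gy)) {
    dose_per_fraction_gy <- d
  } else if (abs(dose_per_fraction_gy * n_fractions - total_dose_gy) >
    1e-6 * total_dose_gy) {
    stop("inconsistent scheme: total_dose != n_fractions x dose_per_fraction",
      call. = FALSE
    )
  }
  structure(
    list(
      total_dose_gy = total_dose_gy,
      n_fractions = as.integer(round(n_fractions)),
      dose_per_fraction_gy = dose_per_fraction_gy,
      alpha_beta_gy = alpha_beta_gy
    ),
    class = "dose_scheme"
  )
}

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' The linear-quadratic conversion EQD2 = D (d + a/b) / (2 + a/b), where D is
#' the total dose, d the dose per fraction and a/b the tissue alpha/beta
#' ratio. A 2-Gy-per-fraction scheme is a fixed point.
#'
#' @param scheme A [dose_scheme()], or a total dose in Gy when `n_fractions`
#'   is also given.
#' @param n_fractions,alpha_beta_gy Used when `scheme` is a bare total dose.
#' @return EQD2 in Gy.
#' @examples
#' eqd2(dose_scheme(50.4, 28)) # 49.56
#' @export
eqd2 <- function(scheme, n_fractions = NULL, alpha_beta_gy = 10) {
  if (!inherits(scheme, "dose_scheme")) {
    scheme <- dose_scheme(scheme, n_fractions, alpha_beta_gy = alpha_beta_gy)
  }
  ab <- scheme$alpha_beta_gy
  scheme$total_dose_gy * (scheme$dose_per_fraction_gy + ab) / (2 + ab)
}

#' Coefficients of the logistic tumor-response-probability model
#'
#' The externally published dose-response model takes the form
#' logit(P) = b0 + b1 EQD2 + b_tumor_size Y_vol + b_N_stage Y_N, with Y_vol a
#' volume in cm^3 and Y_N = 0 for clinical N0 and 1 for N1-2. No coefficient
#' values are shipped: they are configuration and must be supplied (see the
#' example config in `inst/extdata/trp_config_example.yaml`, a user-supplied
#' schema, not endorsed numbers).
#'
#' @param b0 Intercept.
#' @param b1 Per-Gy EQD2 coefficient.
#' @param b_tumor_size Per-cm^3 volume coefficient.
#' @param b_N_stage Nodal-status coefficient.
#' @return A `trp_coefficients` list.
#' @export
trp_coefficients <- function(b0, b1, b_tumor_size, b_N_stage) {
  vals <- list(
    b0 = b0, b1 = b1,
    b_tumor_size = b_tumor_size, b_N_stage = b_N_stage
  )
  missing <- names(vals)[!vapply(
    vals,
    function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1)
  )]
  if (length(missing)) {
    stop("TRP coefficients must all be supplied as finite numbers; missing/invalid: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(vals, class = "trp_coefficients")
}

#' Read TRP coefficients and alpha/beta from a YAML config
#'
#' @param path Path to a YAML file with top-level keys `trp_coefficients`
#'   (b0, b1, b_tumor_size, b_N_stage) and optionally `alpha_beta_gy` and
#'   `contraction_depth_mm`.
#' @return A list with `coefficients` ([trp_coefficients()]),
#'   `alpha_beta_gy`, and `contraction_depth_mm`.
#' @export
read_trp_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$trp_coefficients)) {
    stop("config error: missing `trp_coefficients` block in ", path, call. = FALSE)
  }
  co <- cfg$trp_coefficients
  list(
    coefficients = trp_coefficients(
      b0 = co$b0, b1 = co$b1,
      b_tumor_size = co$b_tumor_size, b_N_stage = co$b_N_stage
    ),
    alpha_beta_gy = cfg$alpha_beta_gy %||% 10,
    contraction_depth_mm = cfg$contraction_depth_mm %||% 1
  )
}

#' Tumor response probability (TRP)
#'
#' Evaluates the logistic dose-response model
#' P = plogis(b0 + b1 EQD2 + b_tumor_size Y_vol + b_N_stage Y_N).
#' The volume covariate is substitutable: any volume definition can stand in
#' for Y_vol, provided it is first median-normalized to the scale the
#' coefficients were fitted on (see
#' [normalize_to_reference_median()]).
#'
#' @param coefs A [trp_coefficients()]; never defaulted.
#' @param eqd2_gy EQD2 in Gy (vectorized).
#' @param volume_cm3 Volume covariate in cm^3 (vectorized, >= 0).
#' @param n_positive 0 for clinical N0, 1 for N1-2 (vectorized).
#' @return Probabilities strictly in (0, 1).
#' @export
trp <- function(coefs, eqd2_gy, volume_cm3, n_positive) {
  if (!inherits(coefs, "trp_coefficients")) {
    stop("configuration error: `coefs` must be a trp_coefficients object ",
      "(no default coefficients are shipped)",
      call. = FALSE
    )
  }
  if (any(volume_cm3 < 0, na.rm = TRUE)) {
    stop("`volume_cm3` must be >= 0", call. = FALSE)
  }
  if (!all(n_positive %in% c(0, 1))) {
    stop("`n_positive` must be 0 (cN0) or 1 (cN1-2)", call. = FALSE)
  }
  stats::plogis(coefs$b0 + coefs$b1 * eqd2_gy +
    coefs$b_tumor_size * volume_cm3 + coefs$b_N_stage * n_positive)
}

#' Rescale volumes to share a reference median
#'
#' Multiplies every value by `median(reference) / median(values)`, so a
#' volume definition on a different scale (e.g. RTV or TCTV vs CATV) can be
#' substituted into a dose-response model fitted on the reference definition.
#' The median is the standard midpoint-of-central-order-statistics definition
#' (for even n, the mean of the two central values).
#'
#' @param values Numeric volumes to rescale (median > 0).
#' @param reference Numeric volumes defining the target median.
#' @return `values` rescaled so `median(result) == median(reference)`.
#' @examples
#' normalize_to_reference_median(c(1, 2, 3), c(2, 4, 6)) # 2 4 6
#' @export
normalize_to_reference_median <- function(values, reference) {
  if (!length(values) || !length(reference)) {
    stop("`values` and `reference` must be non-empty", call. = FALSE)
  }
  mv <- stats::median(values)
  if (!is.finite(mv) || mv == 0) {
    stop("median of `values` must be non-zero", call. = FALSE)
  }
  values * stats::median(reference) / mv
}
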