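#' Intraclass correlation coefficient for inter-observer agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC — ICC(2,1)
#' in the Shrout-Fleiss taxonomy — estimated from the two-way ANOVA mean
#' squares:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with n cases (rows), k readers (columns). Readers are treated as a random
#' sample and systematic reader offsets count against agreement, which is
#' the appropriate variant when the question is whether independently
#' contoured volumetry agrees in absolute value.
#'
#' The agreement band follows the conventional cut-points: below 0.40 poor,
#' 0.40-0.59 fair, 0.60-0.74 good, 0.75-1.0 excellent.
#'
#' @param ratings A cases x readers numeric matrix (or data frame), >= 5
#'   cases, >= 2 readers, no missing cells.
#' @return A one-row tibble with `icc`, `band`, `n_cases`, `n_readers`,
#'   `ms_rows`, `ms_cols`, `ms_error`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(30)
#' icc(cbind(truth + rnorm(30, 0, 0.2), truth + rnorm(30, 0, 0.2)))
#' @export
icc <- function(ratings) {
  X <- as.matrix(as.data.frame(ratings))
  if (!is.numeric(X)) stop("`ratings` must be numeric", call. = FALSE)
  if (anyNA(X)) stop("`ratings` must have no missing cells", call. = FALSE)
  n <- nrow(X)
  k <- ncol(X)
  if (n < 5L || k < 2L) {
    stop("ICC needs >= 5 cases and >= 2 readers", call. = FALSE)
  }
  if (stats::sd(as.vector(X)) == 0) {
    stop("undefined ICC: ratings matrix is constant", call. = FALSE)
  }
  grand <- mean(X)
  row_m <- rowMeans(X)
  col_m <- colMeans(X)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((X - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  val <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  tibble::tibble(
    icc = val,
    band = icc_band(val),
    n_cases = n, n_readers = k,
    ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e
  )
}

#' Agreement band for an ICC value
#'
#' @param x ICC value(s).
#' @return Character: `"poor"` (< 0.40), `"fair"` (0.40-0.59),
#'   `"good"` (0.60-0.74), `"excellent"` (0.75-1.0).
#' @export
icc_band <- function(x) {
  dplyr::case_when(
    x >= 0.75 ~ "excellent",
    x >= 0.60 ~ "good",
    x >= 0.40 ~ "fair",
    TRUE ~ "poor"
  )
}
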