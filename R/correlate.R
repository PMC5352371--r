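#' Pearson or Spearman correlation with p-value
#'
#' Pearson: product-moment r with the usual t-based p-value on n - 2 degrees
#' of freedom. Spearman: Pearson's r computed on average ranks (so ties are
#' handled), with the same t-based p-value — the large-sample convention of
#' standard clinical-statistics software.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble with `method`, `estimate`, `statistic` (t),
#'   `p_value`, `n`.
#' @examples
#' correlate(1:10, (1:10)^3, method = "spearman")
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("`x` and `y` must be equal-length with >= 3 complete pairs", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in ", if (stats::sd(x) == 0) "x" else "y",
      call. = FALSE
    )
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    method = method, estimate = r, statistic = tstat,
    p_value = p, n = n
  )
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the auxiliary ordinary
#' least-squares regression of predictor j on all the others (with
#' intercept). The flag bands follow the convention used in the pipeline's
#' multicollinearity screen: 2.5 <= VIF < 10 is "high", VIF >= 10 "severe",
#' exact collinearity is reported as infinite with an error flag.
#'
#' @param data A data frame (or matrix) of numeric predictors; >= 2 columns,
#'   more rows than columns + 1.
#' @return A tibble with `predictor`, `vif`, `flag` (`"ok"`, `"high"`,
#'   `"severe"`, `"collinear"`).
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(data) {
  X <- as.matrix(as.data.frame(data))
  if (!is.numeric(X)) stop("all predictors must be numeric", call. = FALSE)
  p <- ncol(X)
  if (p < 2L) stop("VIF needs >= 2 predictors", call. = FALSE)
  if (nrow(X) <= p + 1L) stop("VIF needs n > predictors + 1", call. = FALSE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  out <- purrr::map_dfr(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    tibble::tibble(predictor = nm[j], vif = v)
  })
  out$flag <- dplyr::case_when(
    !is.finite(out$vif) ~ "collinear",
    out$vif >= 10 ~ "severe",
    out$vif >= 2.5 ~ "high",
    TRUE ~ "ok"
  )
  out
}
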