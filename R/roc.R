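#' ROC curve and AUC by the Mann-Whitney convention
#'
#' AUC is the probability that a random positive case scores higher than a
#' random negative one, with ties counting one half — identical to the
#' normalized Mann-Whitney U statistic. The curve is the standard
#' trapezoidal ROC over all score thresholds.
#'
#' With `orientation = "auto"` the score is flipped (negated) when its
#' point-biserial association with the positive class is negative, and the
#' flip is recorded: volume-like predictors of response are naturally
#' decreasing, and reporting AUC >= 0.5 for them matches clinical software.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1 or logical), both classes present.
#' @param orientation `"auto"`, `"as_is"`, or `"reversed"`.
#' @return A `roc_curve` object with elements `auc`, `curve` (tibble of
#'   `fpr`, `tpr`, `threshold`), `reversed`, `n_pos`, `n_neg`.
#' @examples
#' roc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc # 0.75
#' @export
roc <- function(scores, labels, orientation = c("auto", "as_is", "reversed")) {
  orientation <- match.arg(orientation)
  labels <- as.numeric(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("`labels` must be binary 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  reversed <- switch(orientation,
    as_is = FALSE,
    reversed = TRUE,
    auto = {
      assoc <- mean(scores[labels == 1]) - mean(scores[labels == 0])
      assoc < 0
    }
  )
  s <- if (reversed) -scores else scores

  # AUC via midranks (ties get half credit)
  r <- rank(s)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(s >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(s >= t & labels == 0), numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg)
  )

  structure(
    list(
      auc = auc, curve = curve, reversed = reversed,
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> AUC = %.4f (%d positives, %d negatives)%s\n",
    x$auc, x$n_pos, x$n_neg,
    if (x$reversed) " [score reversed]" else ""
  ))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

# DeLong structural components: per-case placement values.
# V10[i] = P(score of negative < scores[i]) + 0.5 P(=), for positives i;
# V01[j] analogous for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  # midrank trick
  all_r <- rank(c(pos, neg))
  pos_r <- rank(pos)
  neg_r <- rank(neg)
  v10 <- (all_r[seq_len(m)] - pos_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two correlated AUCs (DeLong)
#'
#' Compares the AUCs of two scores measured on the same cases using the
#' DeLong structural-component estimator of the variance of the AUC
#' difference: z = (AUC_a - AUC_b) / sqrt(var), with a two-sided normal
#' p-value. Both scores are oriented by `orientation` before comparison, so
#' volume-like (decreasing) and probability-like (increasing) predictors are
#' compared on the same footing.
#'
#' @param scores_a,scores_b Paired numeric scores on identical cases.
#' @param labels Binary outcome, both classes present.
#' @inheritParams roc
#' @return A `roc_comparison` object; `tidy()` gives a one-row tibble with
#'   `auc_a`, `auc_b`, `auc_difference`, `variance`, `statistic`, `p_value`,
#'   `reversed_a`, `reversed_b`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           orientation = c("auto", "as_is", "reversed")) {
  orientation <- match.arg(orientation)
  labels <- as.numeric(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("scores and labels must be paired on identical cases", call. = FALSE)
  }
  ok <- is.finite(scores_a) & is.finite(scores_b) & !is.na(labels)
  scores_a <- scores_a[ok]
  scores_b <- scores_b[ok]
  labels <- labels[ok]
  ra <- roc(scores_a, labels, orientation)
  rb <- roc(scores_b, labels, orientation)
  sa <- if (ra$reversed) -scores_a else scores_a
  sb <- if (rb$reversed) -scores_b else scores_b

  pa <- delong_placements(sa, labels)
  pb <- delong_placements(sb, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc

  if (var_diff <= 0) {
    if (abs(delta) < 1e-12) {
      z <- 0
      p <- 1
      var_diff <- max(var_diff, 0)
    } else {
      stop("degenerate DeLong comparison: zero variance with nonzero AUC difference",
        call. = FALSE
      )
    }
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }

  structure(
    list(
      auc_a = pa$auc, auc_b = pb$auc, auc_difference = delta,
      variance = var_diff, statistic = z, p_value = p,
      reversed_a = ra$reversed, reversed_b = rb$reversed,
      n_pos = ra$n_pos, n_neg = ra$n_neg
    ),
    class = "roc_comparison"
  )
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(
    "<roc_comparison> AUC %.4f vs %.4f, difference %.4f, z = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$auc_difference, x$statistic, x$p_value
  ))
  invisible(x)
}

#' @rdname delong_compare
#' @param x A `roc_comparison`.
#' @param ... Unused.
#' @export
tidy.roc_comparison <- function(x, ...) {
  tibble::tibble(
    auc_a = x$auc_a, auc_b = x$auc_b,
    auc_difference = x$auc_difference,
    variance = x$variance,
    statistic = x$statistic, p_value = x$p_value,
    reversed_a = x$reversed_a, reversed_b = x$reversed_b
  )
}

#' DeLong confidence interval for a single AUC
#'
#' @inheritParams roc
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
auc_ci <- function(scores, labels, orientation = c("auto", "as_is", "reversed"),
                   conf_level = 0.95) {
  orientation <- match.arg(orientation)
  r <- roc(scores, labels, orientation)
  labels <- as.numeric(labels)
  ok <- is.finite(scores) & !is.na(labels)
  s <- scores[ok]
  labels <- labels[ok]
  if (r$reversed) s <- -s
  pl <- delong_placements(s, labels)
  se <- sqrt(stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    auc = r$auc,
    ci_low = max(0, r$auc - zc * se),
    ci_high = min(1, r$auc + zc * se),
    se = se
  )
}
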