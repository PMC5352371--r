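#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits P(y = 1) = plogis(X b) by iteratively reweighted least squares
#' (Newton-Raphson on the log-likelihood), converging when the score norm
#' drops below `tol` (default 1e-8) within `max_iter` iterations (default
#' 50). Standard errors come from the inverse observed information; odds
#' ratios and their 95% intervals are Wald-based, matching the output of the
#' standard clinical-statistics packages.
#'
#' Complete or quasi-complete separation is detected (diverging coefficients
#' or fitted probabilities collapsing to 0/1 at the boundary) and reported
#' via `converged = FALSE` with a diagnostic message, never as silently huge
#' coefficients.
#'
#' @param x Design matrix or data frame of predictors (no intercept column;
#'   one is added unless `intercept = FALSE`).
#' @param y Binary outcome vector (0/1, both classes present).
#' @param intercept Add an intercept column (default TRUE).
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `logistic_fit` object; see [tidy.logistic_fit()] and
#'   [glance.logistic_fit()].
#' @examples
#' d <- simulate_cohort(cohort_sim_spec(n = 300, seed = 1))
#' fit <- fit_logistic(d[, c("rtv_cm3", "compactness")], d$pcr)
#' tidy(fit)
#' @export
fit_logistic <- function(x, y, intercept = TRUE, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (ncol(X) > 0L && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  y <- as.numeric(y)
  if (intercept) X <- cbind(`(Intercept)` = rep(1, length(y)), X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("`x` and `y` sizes differ", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("`y` must contain both classes", call. = FALSE)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("rank-deficient design: drop collinear predictors", call. = FALSE)
  }

  beta <- rep(0, p)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      separated <- TRUE
      break
    }
    # dampen extreme steps to keep the iteration stable
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 1e3) {
      separated <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # complete/quasi-complete separation: the likelihood has no interior
  # maximum, coefficients run away and fitted probabilities hit 0/1
  boundary <- any(mu[y == 1] > 1 - 1e-8) || any(mu[y == 0] < 1e-8)
  if (max(abs(beta)) > 15 && boundary) separated <- TRUE
  if (!converged && (separated || boundary)) separated <- TRUE
  if (separated) converged <- FALSE

  info <- crossprod(X * (mu * (1 - mu)), X)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(cov), 0))
  zcrit <- stats::qnorm(0.975)
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))

  structure(
    list(
      coefficients = stats::setNames(beta, colnames(X)),
      se = stats::setNames(se, colnames(X)),
      vcov = cov,
      odds_ratio = exp(beta),
      or_ci_low = exp(beta - zcrit * se),
      or_ci_high = exp(beta + zcrit * se),
      z = beta / se,
      p_value = 2 * stats::pnorm(-abs(beta / se)),
      log_likelihood = loglik,
      converged = converged && !separated,
      separated = separated,
      n_iterations = iter,
      n = n,
      n_events = sum(y),
      fitted = mu,
      diagnostic = if (separated) {
        "complete or quasi-complete separation: estimates are unusable"
      } else if (!converged) {
        "did not converge within max_iter"
      } else {
        NA_character_
      }
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> n = %d (%d events), logLik = %.3f, %s in %d iterations\n",
    x$n, x$n_events, x$log_likelihood,
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  if (!x$converged) cat("  ", x$diagnostic, "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic fit into a coefficient table
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `odds_ratio`, `or_ci_low`, `or_ci_high`, `statistic` (Wald z),
#'   `p_value`.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$se),
    odds_ratio = unname(x$odds_ratio),
    or_ci_low = unname(x$or_ci_low),
    or_ci_high = unname(x$or_ci_high),
    statistic = unname(x$z),
    p_value = unname(x$p_value)
  )
}

#' One-row model summary of a logistic fit
#'
#' @inheritParams tidy.logistic_fit
#' @return A one-row tibble: `n`, `n_events`, `log_likelihood`, `converged`,
#'   `n_iterations`.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    log_likelihood = x$log_likelihood,
    converged = x$converged, n_iterations = x$n_iterations
  )
}
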