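test_that("correlations: exact cases, rank formula oracle, and base-R cross-check", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  # monotone nonlinearity: spearman 1, pearson below 1
  expect_equal(correlate(x, x^3, "spearman")$estimate, 1)
  expect_lt(correlate(x, x^3, "pearson")$estimate, 1)

  # closed-form rank formula on distinct values
  set.seed(5)
  for (i in 1:10) {
    a <- sample(100, 8)
    b <- sample(100, 8)
    d2 <- sum((rank(a) - rank(b))^2)
    expect_equal(
      correlate(a, b, "spearman")$estimate,
      1 - 6 * d2 / (8 * (8^2 - 1))
    )
  }

  # p-value agrees with cor.test for pearson
  set.seed(6)
  a <- rnorm(40)
  b <- a + rnorm(40)
  ct <- stats::cor.test(a, b)
  res <- correlate(a, b, "pearson")
  expect_equal(res$estimate, unname(ct$estimate))
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)

  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("VIF: orthogonal, correlated and collinear designs", {
  n <- 60
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  v <- vif(data.frame(x1, x2))
  expect_equal(v$vif, c(1, 1))
  expect_identical(v$flag, c("ok", "ok"))

  # constructed pair with sample correlation exactly 0.8
  set.seed(3)
  a <- rnorm(200)
  b <- rnorm(200)
  b <- residuals(lm(b ~ a))
  a <- (a - mean(a)) / sd(a)
  b <- b / sd(b)
  y <- 0.8 * a + sqrt(1 - 0.64) * b
  v2 <- vif(data.frame(a, y))
  expect_equal(v2$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
  expect_identical(v2$flag, c("high", "high"))

  # exact collinearity is reported, not crashed
  v3 <- vif(data.frame(a, a2 = a))
  expect_identical(v3$flag, c("collinear", "collinear"))
  expect_false(any(is.finite(v3$vif)))
})

test_that("VIF agrees with 1/(1-R^2) from correlate and with car::vif", {
  set.seed(8)
  x1 <- rnorm(120)
  x2 <- 0.6 * x1 + rnorm(120)
  r <- correlate(x1, x2, "pearson")$estimate
  v <- vif(data.frame(x1, x2))
  expect_equal(v$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-10)

  x3 <- -0.3 * x1 + 0.5 * x2 + rnorm(120)
  y <- rbinom(120, 1, 0.4)
  ref <- car::vif(lm(y ~ x1 + x2 + x3))
  got <- vif(data.frame(x1, x2, x3))
  expect_equal(got$vif, unname(ref), tolerance = 1e-10)
})

test_that("logistic regression matches closed forms and glm", {
  # intercept-only: log-odds of the event rate (23 events in 122)
  y <- c(rep(1, 23), rep(0, 99))
  fit <- fit_logistic(matrix(0, nrow = 122, ncol = 0), y)
  expect_equal(unname(fit$coefficients), log(23 / 99), tolerance = 1e-8)

  # single binary predictor: OR is the 2x2 cross-product ratio
  grp <- c(rep(1, 31), rep(0, 91))
  out <- c(rep(1, 9), rep(0, 22), rep(1, 14), rep(0, 77))
  fit2 <- fit_logistic(data.frame(cn0 = grp), out)
  expect_equal(unname(fit2$odds_ratio["cn0"]), (9 * 77) / (22 * 14), tolerance = 1e-6)

  # full cross-check against glm on a realistic design
  d <- simulate_cohort(cohort_sim_spec(n = 400, seed = 31))
  X <- d[, c("rtv_cm3", "compactness", "cn_pos")]
  fit3 <- fit_logistic(X, d$pcr)
  ref <- stats::glm(d$pcr ~ rtv_cm3 + compactness + cn_pos,
    data = d, family = stats::binomial()
  )
  expect_true(fit3$converged)
  expect_equal(unname(fit3$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit3$se), unname(summary(ref)$coefficients[, 2]),
    tolerance = 1e-4
  )
  expect_equal(fit3$log_likelihood, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("logistic tidy/glance expose odds ratios and fit metadata", {
  d <- simulate_cohort(cohort_sim_spec(n = 200, seed = 41))
  fit <- fit_logistic(d[, c("rtv_cm3", "compactness")], d$pcr)
  td <- tidy(fit)
  expect_named(td, c(
    "term", "estimate", "std_error", "odds_ratio",
    "or_ci_low", "or_ci_high", "statistic", "p_value"
  ))
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_true(all(td$or_ci_low <= td$odds_ratio & td$odds_ratio <= td$or_ci_high))
  gl <- glance(fit)
  expect_equal(gl$n, 200L)
  expect_true(gl$converged)
})

test_that("separation and degenerate designs are flagged, not reported as fits", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  fit <- fit_logistic(data.frame(x), y)
  expect_false(fit$converged)
  expect_true(fit$separated)
  expect_match(fit$diagnostic, "separation")

  expect_error(
    fit_logistic(data.frame(a = 1:10, b = 2 * (1:10)), rep(c(0, 1), 5)),
    "rank-deficient"
  )
  expect_error(fit_logistic(data.frame(x = 1:10), rep(1, 10)), "both classes")
  expect_error(fit_logistic(data.frame(x = 1:10), c(rep(0:1, 4), 2, 0)), "binary")
})
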