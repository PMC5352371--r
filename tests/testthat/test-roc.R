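test_that("AUC equals brute-force pair counting, ties included", {
  expect_equal(roc(c(1, 3, 2, 4), c(0, 0, 1, 1), "as_is")$auc, 0.75)
  expect_equal(roc(rep(2, 10), rep(c(0, 1), 5), "as_is")$auc, 0.5)
  expect_equal(roc(1:10, c(rep(0, 5), rep(1, 5)), "as_is")$auc, 1)

  set.seed(12)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(rnorm(n), 1)) # coarse values force ties
    expect_equal(
      roc(scores, labels, "as_is")$auc,
      brute_force_auc(scores, labels)
    )
  }
})

test_that("orientation handling: reversal maps AUC to 1 - AUC and auto flips", {
  set.seed(13)
  labels <- rbinom(80, 1, 0.3)
  scores <- rnorm(80) + labels # positively oriented
  a <- roc(scores, labels, "as_is")$auc
  expect_equal(roc(scores, labels, "reversed")$auc, 1 - a)

  r_auto <- roc(-scores, labels, "auto")
  expect_true(r_auto$reversed)
  expect_equal(r_auto$auc, a)
  expect_false(roc(scores, labels, "auto")$reversed)

  expect_error(roc(1:5, rep(1, 5)), "both classes")
})

test_that("ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(14)
  labels <- rbinom(60, 1, 0.35)
  r <- roc(rnorm(60), labels, "as_is")
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})

test_that("DeLong: self-comparison, antisymmetry, and pROC cross-check", {
  set.seed(15)
  labels <- rbinom(50, 1, 0.4)
  s <- rnorm(50) + 0.8 * labels
  self <- delong_compare(s, s, labels)
  expect_equal(self$auc_difference, 0)
  expect_equal(self$p_value, 1)

  s2 <- rnorm(50) + 0.5 * labels
  ab <- delong_compare(s, s2, labels, "as_is")
  ba <- delong_compare(s2, s, labels, "as_is")
  expect_equal(ab$auc_difference, -ba$auc_difference)
  expect_equal(ab$p_value, ba$p_value)
  expect_gte(ab$variance, 0)

  ref <- pROC::roc.test(
    pROC::roc(labels, s, direction = "<", quiet = TRUE),
    pROC::roc(labels, s2, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE
  )
  expect_equal(ab$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ab$statistic, unname(ref$statistic), tolerance = 1e-9)
})

test_that("DeLong variance is close to a bootstrap at n = 30", {
  set.seed(16)
  labels <- rep(c(0, 1), 15)
  a <- rnorm(30) + labels
  b <- 0.6 * a + rnorm(30, sd = 0.8)
  got <- delong_compare(a, b, labels, "as_is")$variance
  boot <- bootstrap_var_auc_diff(a, b, labels, n_boot = 10000, seed = 99)
  expect_lt(abs(got / boot - 1), 0.15)
})

test_that("DeLong null p-values are approximately uniform", {
  set.seed(17)
  n_rep <- 1000
  pvals <- vapply(seq_len(n_rep), function(i) {
    labels <- rep(c(0, 1), 30)
    base <- rnorm(60) + 0.5 * labels
    a <- base + rnorm(60, sd = 0.5)
    b <- base + rnorm(60, sd = 0.5)
    delong_compare(a, b, labels, "as_is")$p_value
  }, numeric(1))
  ks <- max(abs(sort(pvals) - (seq_len(n_rep) - 0.5) / n_rep))
  expect_lt(ks, 0.05)
})

test_that("AUC confidence interval behaves and covers the point estimate", {
  set.seed(18)
  labels <- rbinom(100, 1, 0.3)
  s <- rnorm(100) + labels
  ci <- auc_ci(s, labels, "as_is")
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  ref <- pROC::ci.auc(pROC::roc(labels, s, direction = "<", quiet = TRUE),
    method = "delong"
  )
  expect_equal(ci$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(ci$ci_low, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(ci$ci_high, as.numeric(ref[3]), tolerance = 1e-9)
})
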