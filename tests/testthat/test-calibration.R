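test_that("ratio distributions summarize e/s and report exclusions", {
  r <- ratio_distribution(c(1, 2), c(2, 4))
  expect_equal(r$ratios, c(0.5, 0.5))
  expect_equal(r$mean, 0.5)

  e <- c(0.2, 0.6, 0.4)
  expect_equal(ratio_distribution(e, e)$ratios, rep(1, 3))
  expect_equal(ratio_distribution(e, c(0.4, 0.8, 0.5))$mean,
               mean(c(0.5, 0.75, 0.8)))

  r <- ratio_distribution(c(1, 2, 3), c(0, 1, 1))
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$n, 2L)
  expect_error(ratio_distribution(c(1, 2), c(0, 0)), "zero")
})

test_that("alpha fits recover exact proportionality under both methods", {
  s <- c(0.1, 0.25, 0.4, 0.6)
  for (m in c("mean_ratio", "origin_slope"))
    expect_equal(coef(uq_calibrate(2 * s, s, method = m))[["alpha"]], 2)
  # closed-form origin slope: (1*1 + 2*4) / (1 + 4)
  expect_equal(coef(uq_calibrate(c(1, 4), c(1, 2),
                                 method = "origin_slope"))[["alpha"]], 1.8)
})

test_that("mean-ratio alpha equals the mean of the ratio distribution", {
  set.seed(31)
  s <- runif(40, 0.05, 0.3)
  e <- abs(1.1 * s + rnorm(40, 0, 0.02))
  fit <- uq_calibrate(e, s)
  expect_equal(fit$alpha, ratio_distribution(e, s)$mean)
  expect_equal(fit$n_fit, 40L)
  expect_equal(fit$level, "structure")
})

test_that("zero-uncertainty items are excluded and counted, not dropped silently", {
  fit <- uq_calibrate(c(1, 2, 3), c(1, 2, 0))
  expect_equal(fit$n_excluded, 1L)
  expect_equal(fit$n_fit, 2L)
  expect_equal(fit$alpha, 1)
  expect_error(uq_calibrate(c(1, 2), c(0, 0)), "positive uncertainty")
})

test_that("the formula interface matches the default interface", {
  df <- data.frame(err = c(0.2, 0.3, 0.5), unc = c(0.1, 0.2, 0.25))
  expect_equal(coef(uq_calibrate(err ~ unc, df)),
               coef(uq_calibrate(df$err, df$unc)))
})

test_that("predicted errors are alpha * s with unit and sign checks", {
  fit <- uq_calibrate(c(0.2, 0.4), c(0.1, 0.2))  # alpha = 2
  expect_equal(predict(fit, 0.1), 0.2)
  expect_equal(predict(fit, 0), 0)
  expect_error(predict(fit, -0.1), ">= 0")
  expect_equal(residuals(fit), c(0, 0))
})

test_that("alpha fitted on noisy proportional data recovers predictions", {
  set.seed(32)
  s <- runif(200, 0.05, 0.3)
  e <- 1.3 * s * exp(rnorm(200, 0, 0.1))
  idx <- calibration_split(200, 0.2)
  fit <- uq_calibrate(e[idx], s[idx])
  expect_lt(abs(fit$alpha - 1.3), 0.1)
  held <- setdiff(seq_len(200), idx)
  mad <- mean(abs(predict(fit, s[held]) - e[held]))
  expect_lt(mad, 0.15 * mean(e[held]))
  sm <- summary(fit)
  expect_gt(sm$correlations$pearson, 0.9)
})

test_that("correlation summaries match textbook formulas", {
  e <- c(1, 2, 3, 4, 5)
  s <- c(2, 1, 4, 3, 6)
  cs <- correlation_summary(e, s)
  # hand computation: cov = 10, var_e = 10, var_s = 14.8
  expect_equal(cs$pearson, 10 / sqrt(10 * 14.8))
  # rank d^2 sum = 4 -> 1 - 6*4/(5*24)
  expect_equal(cs$spearman, 1 - 6 * 4 / (5 * 24))

  expect_equal(correlation_summary(e, e), list(pearson = 1, spearman = 1))
  mono <- exp(e)
  cs <- correlation_summary(e, mono)
  expect_equal(cs$spearman, 1)
  expect_lt(cs$pearson, 1)
  expect_error(correlation_summary(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("calibration splits are deterministic or seeded", {
  expect_equal(calibration_split(10, 0.2), 1:2)
  a <- calibration_split(50, 0.2, "random", seed = 5)
  b <- calibration_split(50, 0.2, "random", seed = 5)
  expect_identical(a, b)
  expect_length(a, 10)
  expect_error(calibration_split(3, 0.9), "no evaluation")
})
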