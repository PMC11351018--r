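test_that("sigma distributions have strictly positive support", {
  set.seed(51)
  for (d in list(sigma_invgamma(), sigma_uniform(0.2, 0.9),
                 sigma_constant(0.7)))
    expect_true(all(d$draw(2000) > 0))
  # a truncated normal with substantial mass below zero must redraw
  sim <- simulate_committee(4, 1, 500, sigma_normal(0.3, 0.4), seed = 51)
  expect_gt(sim$n_redraws, 0)
  expect_true(all(sim$structures[[1]]$sigma > 0))
})

test_that("fixed seeds give bitwise-identical simulations", {
  a <- simulate_committee(5, 2, 30, seed = 52)
  b <- simulate_committee(5, 2, 30, seed = 52)
  expect_identical(a$structures, b$structures)
  ra <- ratio_experiment(5, 5, 50, seed = 53)
  rb <- ratio_experiment(5, 5, 50, seed = 53)
  expect_identical(ra$aggregated_ratios, rb$aggregated_ratios)
  expect_identical(ra$individual_ratios, rb$individual_ratios)
})

test_that("constant sigma committees reproduce the c4 std bias", {
  set.seed(54)
  sim <- simulate_committee(6, 1, 4000, sigma_constant(0.8))
  s <- committee_std(sim$structures[[1]]$committee)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.8 * c4_factor(6)), 3 * se)
})

test_that("aggregated ratios match the closed-form sampling expectation", {
  r <- ratio_experiment(10, 40, 200, sigma_invgamma(), seed = 55)
  expect_lt(abs(r$aggregated_ratio_mean - expected_ratio(10, "aggregated")),
            3 * r$aggregated_ratio_se)
  expect_lt(abs(r$individual_ratio_mean - expected_ratio(10, "individual")),
            3 * r$individual_ratio_se)
  expect_equal(r$theoretical_ratio, sqrt(2 / (10 * pi)))
})

test_that("aggregated ratio spread concentrates as 1/sqrt(N_j)", {
  iqr <- vapply(c(10, 100, 1000), function(nj)
    ratio_experiment(10, 100, nj, sigma_constant(1),
                     seed = 56, keep_ratios = FALSE)$aggregated_ratio_spread,
    0)
  expect_lt(iqr[2] / iqr[1], 0.5)   # expected ~ 1/sqrt(10) = 0.32
  expect_gt(iqr[2] / iqr[1], 0.2)
  expect_lt(iqr[3] / iqr[2], 0.5)
  expect_gt(iqr[3] / iqr[2], 0.2)
})

test_that("individual tail exceedances match an independent 1-D simulation", {
  # fraction of components with e > 3 * theoretical * s, against a direct
  # draw of |N(0, 1/sqrt(nc))| vs scaled chi: the same law, simulated
  # without the package's committee machinery
  nc <- 10
  r <- ratio_experiment(nc, 30, 300, sigma_constant(1), seed = 57)
  frac <- mean(r$individual_ratios > 3 * r$theoretical_ratio)
  set.seed(571)
  m <- 2e5
  z <- abs(rnorm(m)) / sqrt(nc)
  s1 <- sqrt(rchisq(m, nc - 1) / (nc - 1))
  frac_oracle <- mean(z / s1 > 3 * sqrt(2 / (pi * nc)))
  se <- sqrt(frac_oracle * (1 - frac_oracle)) *
    sqrt(1 / length(r$individual_ratios) + 1 / m)
  expect_lt(abs(frac - frac_oracle), 4 * se)
})

test_that("ratios fall with committee size towards the theoretical curve", {
  tab <- ratio_vs_committee_size(c(2, 5, 10), n_i = 30, n_j = 150, seed = 58)
  expect_equal(tab$theoretical, sqrt(2 / (pi * c(2, 5, 10))))
  expect_equal(tab$theoretical[1], sqrt(1 / pi))
  expect_true(all(diff(tab$aggregated_ratio) < 0))
  expect_true(all(diff(tab$theoretical) < 0))
})

test_that("invalid Monte Carlo configurations are rejected", {
  expect_error(ratio_experiment(1, 10, 10), ">= 2")
  expect_error(simulate_committee(3, 0, 10), "positive")
})
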