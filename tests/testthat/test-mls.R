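test_that("direct MLS averages the top decile with the printed tail sizes", {
  # control: 2 of 20 animals
  ctrl <- suppressWarnings(mls_direct(c(17.6, 19.3), n_cohort = 20))
  expect_equal(ctrl$value, 18.45)
  expect_equal(ctrl$n_tail, 2L)
  # experimental: 5 of 51 animals
  ex <- mls_direct(c(21.0, 22.5, 22.7, 23.8, 24.2), n_cohort = 51)
  expect_equal(ex$value, 22.84)
  expect_equal(ex$n_tail, 5L)
  expect_equal(round(ex$value, 1), 22.8)
  # degenerate cases
  expect_equal(suppressWarnings(mls_direct(rep(7, 4)))$value, 7)
  expect_warning(mls_direct(c(3, 4), n_cohort = 5), "fewer than 10")
  expect_error(mls_direct(numeric()), "no death ages")
})

test_that("direct MLS is translation-equivariant and at least the cohort mean", {
  set.seed(31)
  for (i in 1:5) {
    ages <- runif(40, 10, 25)
    m <- mls_direct(ages)
    expect_equal(mls_direct(ages + 2.5)$value, m$value + 2.5)
    expect_gte(m$value, mean(ages))
  }
})

test_that("model-tail MLS matches the brute-force Riemann oracle", {
  p <- ref_params()
  m <- mls_model_tail(p)
  oracle <- riemann_tail_mean(p, step = 1e-4)
  expect_equal(m$value, oracle, tolerance = 1e-4 / oracle)
  expect_equal(m$value, 17.3468, tolerance = 1e-4)
  expect_gt(m$value, attr(m, "t_tail"))
  # a second parameter regime
  p2 <- gompertz_params(-8, 0.4)
  m2 <- mls_model_tail(p2)
  expect_equal(m2$value, riemann_tail_mean(p2, span = 35),
               tolerance = 1e-4 / m2$value)
  expect_gt(m2$value, quantile_time(p2, 0.1))
})

test_that("model-tail MLS agrees with the direct estimator on a large simulated cohort", {
  p <- ref_params()
  ages <- sample_lifespans(p, 1e5, seed = 21)
  direct <- mls_direct(ages)
  model <- mls_model_tail(p)
  expect_lt(abs(direct$value - model$value), 0.3)
})

test_that("weighted combination reproduces the published value and is convex", {
  e1 <- mls_estimate(18.45, 2.6, method = "direct")
  e2 <- mls_estimate(17.2, 0.6, method = "model_tail")
  comb <- combine_weighted(e1, e2)
  expect_equal(comb$value, (0.6 * 18.45 + 2.6 * 17.2) / 3.2)
  expect_equal(round(comb$value, 1), 17.4)
  # smaller delta -> larger weight: result nearer e2
  expect_lt(abs(comb$value - e2$value), abs(comb$value - e1$value))
  # convexity over random inputs
  set.seed(9)
  for (i in 1:10) {
    v <- runif(2, 10, 30); d <- runif(2, 0.1, 5)
    cc <- combine_weighted(mls_estimate(v[1], d[1], method = "direct"),
                           mls_estimate(v[2], d[2], method = "model_tail"))
    expect_gte(cc$value, min(v) - 1e-12)
    expect_lte(cc$value, max(v) + 1e-12)
  }
  # equal deltas -> arithmetic mean; zero delta -> that value exactly
  expect_equal(combine_weighted(mls_estimate(20, 1), mls_estimate(10, 1))$value, 15)
  expect_equal(combine_weighted(mls_estimate(20, 0), mls_estimate(10, 1))$value, 20)
  expect_error(combine_weighted(mls_estimate(20, 0), mls_estimate(10, 0)),
               "undefined")
})

test_that("Student-t half-widths follow the standard formula", {
  # hand oracle: t_{4,0.975} * s / sqrt(5) etc.
  expect_equal(student_ci(c(21.0, 22.5, 22.7, 23.8, 24.2)), 1.5573,
               tolerance = 1e-4)
  expect_equal(student_ci(c(17.6, 19.3)), 10.8003, tolerance = 1e-4)
  expect_equal(student_ci(rep(4, 6)), 0)
  expect_error(student_ci(5), "CI undefined")
})

test_that("extension and fold statistics reproduce the published arithmetic", {
  expect_equal(round(extension_percent(22.8, 17.4)), 31)
  expect_equal(extension_percent(20, 16), 25)
  expect_equal(extension_percent(17.4, 17.4), 0)
  expect_error(extension_percent(20, 0), "positive")
  expect_equal(survival_fold(22.8, 17.4, 15), 3.25)
  expect_equal(survival_fold(24, 18, 15), 3)
  expect_equal(survival_fold(18, 18, 15), 1)
  expect_error(survival_fold(22, 14, 15), "fold undefined")
  # monotone in the first argument
  x <- seq(18, 26, by = 2)
  expect_true(all(diff(extension_percent(x, 17.4)) > 0))
})
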