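test_that("survival fraction matches the closed form and its boundary behaviour", {
  p <- ref_params()
  expect_equal(survival_fraction(p, 0), 1)
  # frozen from direct evaluation of exp(-(e^{mu0+mu1 t} - e^{mu0})/mu1)
  expect_equal(survival_fraction(p, 15), 0.5594519, tolerance = 1e-6)
  expect_equal(survival_fraction(p, quantile_time(p, 0.1)), 0.1,
               tolerance = 1e-10)
  expect_error(survival_fraction(p, -1), "nonnegative")
  # strictly decreasing up to numerical underflow (S < 1e-300 past ~25
  # months at these parameters), and vanishing in the limit
  tt <- seq(0, 24, by = 0.25)
  expect_true(all(diff(survival_fraction(p, tt)) < 0))
  expect_lt(survival_fraction(p, 30), 1e-12)
  expect_equal(survival_fraction(p, 60), 0)
})

test_that("paper-literal and proper normalizations agree to the documented bound", {
  p <- ref_params()
  q <- gompertz_params(-11.4, 0.7, "paper_literal")
  tt <- seq(0, 24, by = 0.5)
  # log-survival difference is exactly e^{mu0}/mu1 ~ 1.6e-5
  bound <- exp(p$mu0) / p$mu1
  expect_true(all(abs(log(survival_fraction(p, tt)) -
                      log(survival_fraction(q, tt))) <= bound + 1e-12))
  expect_true(all(abs(survival_fraction(p, tt) -
                      survival_fraction(q, tt)) < 1e-4))
})

test_that("quantile_time inverts survival_fraction and matches a root-finding oracle", {
  p <- ref_params()
  # independent oracle: bisection on survival_fraction
  oracle <- uniroot(function(t) survival_fraction(p, t) - 0.1,
                    c(0, 100), tol = 1e-12)$root
  expect_equal(quantile_time(p, 0.1), oracle, tolerance = 1e-8)
  expect_equal(quantile_time(p, 0.1), 16.96766, tolerance = 1e-5)
  for (q in c(0.9, 0.5, 0.1))
    expect_equal(survival_fraction(p, quantile_time(p, q)), q,
                 tolerance = 1e-10)
  expect_lt(quantile_time(p, 1 - 1e-12), 1e-3)  # q -> 1 limit
  expect_error(quantile_time(p, 0), "inside")
  expect_error(quantile_time(p, 1.2), "inside")
})

test_that("inverse-CDF sampling is deterministic under seed and distributionally exact", {
  p <- ref_params()
  expect_identical(sample_lifespans(p, 5, seed = 99),
                   sample_lifespans(p, 5, seed = 99))
  x <- sample_lifespans(p, 1e5, seed = 12)
  expect_equal(median(x), quantile_time(p, 0.5), tolerance = 0.1 / 15)
  # Kolmogorov–Smirnov distance against the model survival
  ks <- suppressWarnings(
    ks.test(x, function(t) 1 - survival_fraction(p, t))$statistic)
  expect_lt(unname(ks), 0.01)
})

test_that("least-squares fit recovers exact curves to optimizer tolerance", {
  p <- ref_params()
  ages <- seq(2, 24, length.out = 50)
  sc <- step_curve(c(0, ages), c(1, survival_fraction(p, ages)))
  fit <- fit_least_squares(sc)
  expect_lt(abs(fit$mu0 - p$mu0), 0.01)
  expect_lt(abs(fit$mu1 - p$mu1), 0.001)
  expect_lt(attr(fit, "residual"), 1e-10)
})

test_that("fit recovers parameters from large sampled cohorts in two regimes", {
  for (tp in list(ref_params(), gompertz_params(-8, 0.4))) {
    out <- parameter_recovery_experiment(tp, 1e4, seed = 5)
    expect_lt(out$abs_error[["mu1"]], 0.05)
    expect_lt(out$abs_error[["mu0"]], 0.5)
  }
})

test_that("log-hazard regression on simulated deaths recovers the slope", {
  # secondary oracle for the hazard's log-linearity: bin deaths, estimate
  # the per-interval hazard integral as -log(1 - q) with q the discrete
  # death probability, and regress its log on the bin midpoint — the
  # slope equals mu1 exactly for a log-linear hazard
  p <- ref_params()
  x <- sample_lifespans(p, 1e5, seed = 8)
  lo <- 6:15
  mids <- lo + 0.5
  q <- vapply(lo, function(b) sum(x >= b & x < b + 1) / sum(x >= b),
              numeric(1))
  slope <- coef(lm(log(-log(1 - q)) ~ mids))[2]
  expect_equal(unname(slope), p$mu1, tolerance = 0.02)
})

test_that("parameter JSON round-trips", {
  tmp <- withr::local_tempfile(fileext = ".json")
  p <- gompertz_params(-9.3, 0.55, "paper_literal")
  write_params_json(p, tmp)
  expect_equal(read_params_json(tmp), p)
})

test_that("invalid parameters are rejected", {
  expect_error(gompertz_params(-11.4, 0), "positive")
  expect_error(gompertz_params(-11.4, -0.7), "positive")
})
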