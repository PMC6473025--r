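test_that("mortality policy drops sacrifices, relabels embolic deaths, and is idempotent", {
  co <- toy_cohort(c(10, 16, 17), c("natural", "embolic", "sacrificed"))
  out <- apply_mortality_policy(co)
  expect_equal(nrow(out$records), 2L)
  expect_setequal(out$records$event, "natural")
  expect_setequal(out$records$age_months, c(10, 16))
  # original untouched
  expect_equal(co$records$event, c("natural", "embolic", "sacrificed"))
  # identity on clean cohorts, idempotent in general
  clean <- toy_cohort(c(5, 8))
  expect_equal(apply_mortality_policy(clean)$records, clean$records)
  expect_equal(apply_mortality_policy(out)$records, out$records)
  expect_error(apply_mortality_policy(toy_cohort(numeric())), "empty cohort")
})

test_that("policy on a study-sized cohort keeps embolic deaths and removes the sacrificed", {
  events <- c(rep("natural", 42), rep("embolic", 9), rep("sacrificed", 5))
  co <- toy_cohort(seq(10, 24, length.out = 56), events,
                   group = "experimental")
  out <- apply_mortality_policy(co)
  expect_equal(nrow(out$records), 51L)
  expect_true(all(out$records$event == "natural"))
})

test_that("empirical survival drops k/n at tied deaths and censors alive records", {
  # single animal
  sc1 <- empirical_survival(toy_cohort(10))
  expect_equal(sc1$breakpoints$age_months, c(0, 10))
  expect_equal(sc1$breakpoints$fraction_surviving, c(1, 0))
  expect_equal(step_at(sc1, c(0, 9.99, 10, 11)), c(1, 1, 0, 0))
  # ties drop together
  sc2 <- empirical_survival(toy_cohort(c(1, 1, 2, 3)))
  expect_equal(sc2$breakpoints$fraction_surviving, c(1, 0.5, 0.25, 0))
  # alive records inflate n but never drop the curve
  sc3 <- empirical_survival(toy_cohort(c(1, 2, 5), c("natural", "natural", "alive")))
  expect_equal(sc3$breakpoints$age_months, c(0, 1, 2))
  expect_equal(sc3$breakpoints$fraction_surviving, c(1, 2 / 3, 1 / 3))
  expect_error(empirical_survival(toy_cohort(5, "alive")), "no events")
  expect_error(empirical_survival(toy_cohort(5, "sacrificed")), "policy")
})

test_that("the fraction after the penultimate control death is 1/n", {
  ages <- c(seq(8, 16, length.out = 18), 17.6, 19.3)
  sc <- empirical_survival(toy_cohort(ages))
  expect_equal(step_at(sc, 17.6), 1 / 20)
  expect_equal(step_at(sc, 19.3), 0)
})

test_that("empirical survival is a nonincreasing [0,1] curve whose total drop is deaths/n", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(5:60, 1)
    ages <- round(runif(n, 1, 30), 1)
    events <- sample(c("natural", "alive"), n, replace = TRUE,
                     prob = c(0.8, 0.2))
    if (!any(events == "natural")) events[1] <- "natural"
    sc <- empirical_survival(toy_cohort(ages, events))
    f <- sc$breakpoints$fraction_surviving
    expect_true(all(diff(f) <= 0))
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(1 - f[length(f)], sum(events == "natural") / n)
  }
})

test_that("cohort CSV round-trips and reports offending rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_study(study_design(seed = 3))
  co <- apply_mortality_policy(sim$cohort)
  write_cohort_csv(co, tmp)
  back <- read_cohort_csv(tmp, co$t_intervention)
  expect_equal(back$records, co$records)
  expect_equal(back$t_intervention, co$t_intervention)

  one <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,age_months,event",
               "m1,control,17.6,natural"), one)
  expect_equal(nrow(read_cohort_csv(one)$records), 1L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,age_months,event",
               "m1,control,17.6,dead"), bad)
  expect_error(read_cohort_csv(bad), "row 2.*unknown event 'dead'")
  writeLines(c("animal_id,group,age_months,event",
               "m1,control,17.6,natural",
               "m2,control,-2,natural"), bad)
  expect_error(read_cohort_csv(bad), "row 3")
  writeLines(c("animal_id,group,age_months,event",
               "m1,control,17.6,natural",
               "m1,control,18,natural"), bad)
  expect_error(read_cohort_csv(bad), "duplicate animal_id 'm1'")
})

test_that("empirical curve converges uniformly to the generating survival function", {
  # Glivenko–Cantelli check at n = 1e4
  p <- ref_params()
  ages <- sample_lifespans(p, 1e4, seed = 11)
  sc <- empirical_survival(toy_cohort(ages))
  grid <- seq(0, 30, by = 0.05)
  gap <- max(abs(step_at(sc, grid) - survival_fraction(p, grid)))
  expect_lt(gap, 0.03)
})
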