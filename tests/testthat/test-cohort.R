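test_that("visit schedules follow the age-dependent spacing rules", {
  expect_equal(visit_schedule(10, 26), c(0, 6, 12, 24))
  expect_equal(visit_schedule(1, 9), c(0, 3, 6, 9))
  expect_equal(visit_schedule(3, 18), c(0, 6, 12, 18))
  expect_equal(visit_schedule(20, 0), 0)
  # an infant ages into the 6-monthly regime during follow-up
  expect_equal(visit_schedule(1.5, 24), c(0, 3, 6, 12, 18, 24))
  expect_error(visit_schedule(5, -1), "non-negative")
})

test_that("simulated cohorts honour the configured composition", {
  ds <- simulate_cohort(cohort_config(seed = 5))
  tab <- table(ds$patients$genotype)
  expect_equal(as.integer(tab[["MTM1"]]), 44)
  expect_equal(as.integer(tab[["DNM2"]]), 15)
  expect_equal(nrow(ds$patients), 59)

  # age strata counts (baseline age)
  mtm1 <- ds$patients[ds$patients$genotype == "MTM1", ]
  counts <- table(cut(mtm1$baseline_age, c(0, 2, 6, 16, Inf), right = FALSE))
  expect_equal(as.integer(counts), c(12, 10, 13, 9))

  s <- ds$observations$scaled_value
  expect_true(all(s > 0 & s < 1))
  expect_true(all(table(ds$observations$patient_id) >= 1))

  # determinism
  ds2 <- simulate_cohort(cohort_config(seed = 5))
  expect_identical(ds$observations, ds2$observations)
  ds3 <- simulate_cohort(cohort_config(seed = 6))
  expect_false(identical(ds$observations$scaled_value,
                         ds3$observations$scaled_value))
})

test_that("misallocated strata or sexes are configuration errors", {
  expect_error(
    cohort_config(age_strata = list(
      MTM1 = c(`0-2` = 12, `2-6` = 10, `6-16` = 13, `>16` = 10),
      DNM2 = c(`0-2` = 0, `2-6` = 1, `6-16` = 1, `>16` = 13))),
    "summing to 44")
  expect_error(
    cohort_config(sex_counts = list(MTM1 = c(M = 40, F = 3),
                                    DNM2 = c(M = 6, F = 9))),
    "sum to 44")
})

test_that("a flat generating slope yields a flat pooled logit trend", {
  # large-sample oracle: with zero population slope and negligible slope
  # variability, the pooled regression of logit(y) on time is flat
  params <- model_parameters(pop_slope = 0, re_sd_slope = 1e-8)
  big <- cohort_config(
    n_mtm1 = 800, n_dnm2 = 0,
    age_strata = list(MTM1 = c(`0-2` = 200, `2-6` = 200, `6-16` = 200,
                               `>16` = 200),
                      DNM2 = c(`0-2` = 0, `2-6` = 0, `6-16` = 0, `>16` = 0)),
    sex_counts = list(MTM1 = c(M = 800, F = 0), DNM2 = c(M = 0, F = 0)),
    generating_params = params, seed = 9)
  ds <- simulate_cohort(big)
  expect_gt(nrow(ds$observations), 3000)
  m <- lm(qlogis(scaled_value) ~ time_months, data = ds$observations)
  se <- sqrt(sandwich::vcovCL(m, cluster = ds$observations$patient_id)[2, 2])
  expect_lt(abs(coef(m)[["time_months"]]), 3 * se)
})

test_that("future simulation matches the generator and the null identity", {
  params <- model_parameters()
  # zero-effect spec is exactly the null generator under the same seed
  y0 <- simulate_future(0.3, -0.002, c(2, 4, 6), params, seed = 21)
  y1 <- simulate_future(0.3, -0.002, c(2, 4, 6), params,
                        effect = treatment_effect(0, 0, 0), seed = 21)
  expect_identical(y0, y1)

  # moment match: sample mean converges to the logit mean
  set.seed(33)
  y <- simulate_future(rep(0.3, 1e4), -0.002, rep(6, 1e4), params)
  mu <- logit_mean(0.3, -0.002, 0, 6)
  expect_lt(abs(mean(y) - mu), 3 * sd(y) / sqrt(1e4))

  # a +5 logit step pushes essentially all futures above the untreated mean
  yT <- simulate_future(rep(0.3, 500), -0.002, rep(6, 500), params,
                        effect = treatment_effect(5, 0, 0), seed = 3)
  expect_true(all(yT > mu))

  expect_equal(simulate_future(0.3, 0, numeric(0), params), numeric(0))
  expect_error(treatment_effect(onset_time = -1), "non-negative")
})

test_that("slope shifts accrue with time since onset", {
  params <- model_parameters(precision_nu = 1e7)  # noise-free check
  eff <- treatment_effect(intercept_shift = 0.5, slope_shift = 0.1,
                          onset_time = 2)
  y <- simulate_future(0, 0, c(1, 2, 4), params, effect = eff, seed = 1)
  expect_equal(qlogis(y), c(0, 0.5, 0.5 + 0.1 * 2), tolerance = 0.01)
})
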