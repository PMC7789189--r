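test_that("a point-mass posterior at Beta(1, 1) yields a uniform predictive", {
  eff <- data.frame(patient_id = "p1", alpha = 0, beta = 0)
  pd <- population_draws(model_parameters(
    pop_intercept = 0, pop_slope = 0, re_sd_intercept = 0, re_sd_slope = 0,
    precision_nu = 2, patient_effects = eff), n_draws = 20000)
  pred <- predict_individual(pd, "p1", c(2, 4, 6), n_draws = 20000, seed = 4)
  expect_true(all(pred$trajectories > 0 & pred$trajectories < 1))
  iv <- prediction_intervals(pred, 0.95)
  expect_lt(max(abs(iv$lower - 0.025)), 0.012)
  expect_lt(max(abs(iv$upper - 0.975)), 0.012)
  expect_equal(mean(pred$trajectories), 0.5, tolerance = 0.01)
})

test_that("predictive means agree with the posterior mean of mu", {
  fit <- cached_fit()
  id <- fit$patient_ids[3]
  t <- c(3, 9)
  pred <- predict_individual(fit, id, t, n_draws = 5000, seed = 9)
  mu <- sapply(t, function(tt)
    plogis(pred$effects$alpha + pred$effects$beta *
             (fit$centering_constant + tt)))
  for (j in seq_along(t)) {
    resid <- pred$trajectories[, j] - mu[, j]
    expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(nrow(mu)))
  }
})

test_that("edge cases: unknown patient, empty times, bad levels", {
  fit <- cached_fit()
  expect_error(predict_individual(fit, "ghost", c(2, 4)), "unknown patient")
  pred0 <- predict_individual(fit, fit$patient_ids[1], numeric(0), seed = 1)
  expect_equal(ncol(pred0$trajectories), 0)
  expect_equal(nrow(prediction_intervals(pred0)), 0)
  pred <- predict_individual(fit, fit$patient_ids[1], c(2, 4), seed = 1)
  expect_error(prediction_intervals(pred, 1), "strictly inside")
  expect_error(predict_individual(fit, fit$patient_ids[1], c(4, 2)),
               "strictly increasing")
})

test_that("intervals widen monotonically with level and stay inside (0, 1)", {
  fit <- cached_fit()
  pred <- predict_individual(fit, fit$patient_ids[2], c(2, 4, 6), seed = 2)
  w <- sapply(c(0.5, 0.8, 0.95, 0.99), function(l) {
    iv <- prediction_intervals(pred, l)
    iv$upper - iv$lower
  })
  expect_true(all(diff(t(w)) >= 0))
  iv <- prediction_intervals(pred, 0.999)
  expect_true(all(iv$lower > 0 & iv$upper < 1))
})

test_that("the joint improvement probability matches independence oracles", {
  set.seed(8)
  n <- 50000
  traj <- cbind(runif(n), runif(n), runif(n))
  pred <- manual_predictive(traj, c(2, 4, 6))

  # independent coordinates at the 0.9 quantiles: product rule gives 0.1^3
  jp <- joint_improvement_probability(pred, rep(0.9, 3), "increase")
  expect_lt(abs(jp - 0.001), 3 * sqrt(0.001 * 0.999 / n))
  expect_equal(attr(jp, "mc_se"), sqrt(jp * (1 - jp) / n),
               ignore_attr = TRUE)

  # decrease direction mirrors it
  jp_dec <- joint_improvement_probability(pred, rep(0.1, 3), "decrease")
  expect_lt(abs(jp_dec - 0.001), 3 * sqrt(0.001 * 0.999 / n))

  # observations below the support minimum are always exceeded
  expect_equal(as.numeric(
    joint_improvement_probability(pred, rep(-0.1, 3), "increase")), 1)

  # marginally unremarkable observations can still be jointly extreme:
  # each 0.96 quantile sits inside its central 95% interval, yet the
  # joint probability is far below the 0.01 responder cut-off
  jp96 <- joint_improvement_probability(pred, rep(0.96, 3), "increase")
  expect_lt(as.numeric(jp96), 0.01)

  expect_error(joint_improvement_probability(pred, c(0.5, 0.5), "increase"),
               "3 times")
})

test_that("the joint statistic is calibrated in the comonotone limit", {
  # when trajectories are perfectly dependent across times the joint tail
  # statistic is exactly uniform under the null, so P(jp <= q) = q
  set.seed(14)
  n_draws <- 2000; n_rep <- 2000
  u <- runif(n_draws)
  traj <- cbind(u, 0.5 + u / 2, u^2)  # increasing transforms of one uniform
  pred <- manual_predictive(traj, 1:3)
  v <- runif(n_rep)
  jp <- vapply(v, function(vi)
    as.numeric(joint_improvement_probability(
      pred, c(vi, 0.5 + vi / 2, vi^2), "increase")), numeric(1))
  for (q in c(0.05, 0.2)) {
    frac <- mean(jp <= q)
    expect_lt(abs(frac - q), 3 * sqrt(q * (1 - q) / n_rep) + 1 / n_draws)
  }
})

test_that("run-in predictions need data and fall back to the population", {
  fit <- cached_fit()
  expect_error(predict_run_in(fit, NULL, c(2, 4)), "population-only")
  expect_error(predict_run_in(fit, data.frame(time_months = numeric(0),
                                              scaled_value = numeric(0)),
                              c(2, 4)), "population-only")

  # with zero random-effect variance every importance weight is equal
  # (the no-information limit), so the run-in predictive equals the
  # population-marginal predictive in distribution
  pd <- population_draws(model_parameters(
    pop_intercept = 0, pop_slope = 0, re_sd_intercept = 0, re_sd_slope = 0,
    precision_nu = 2), n_draws = 20000)
  ri <- data.frame(time_months = c(0, 2), scaled_value = c(0.4, 0.6))
  p_run <- predict_run_in(pd, ri, 6, n_draws = 20000, seed = 3)
  p_pop <- predict_population(pd, 6, n_draws = 20000, seed = 4)
  expect_equal(attr(p_run, "ess"), 20000)
  q <- seq(0.05, 0.95, by = 0.1)
  expect_equal(quantile(p_run$trajectories[, 1], q),
               quantile(p_pop$trajectories[, 1], q), tolerance = 0.02)
})

test_that("observing a patient narrows the predictive relative to the population", {
  # the population-marginal predictive knows nothing about the patient;
  # conditioning on any observed history must narrow the interval
  params <- model_parameters()
  pd <- population_draws(params, n_draws = 3000)
  narrower <- logical(20)
  for (r in seq_len(20)) {
    set.seed(500 + r)
    eff <- cnmbayes:::draw_effects(1, params)
    tt <- c(0, 6, 12, 24, 26)
    mu <- plogis(eff$alpha + eff$beta * tt)
    obs <- data.frame(
      time_months = tt,
      scaled_value = rbeta(length(tt), mu * params$precision_nu,
                           (1 - mu) * params$precision_nu))
    p_pat <- suppressWarnings(predict_run_in(pd, obs, 32, n_draws = 3000,
                                             seed = 900 + r))
    p_pop <- predict_population(pd, 32, n_draws = 3000, seed = 900 + r)
    w <- function(p) {
      iv <- prediction_intervals(p, 0.95)
      iv$upper - iv$lower
    }
    narrower[r] <- w(p_pat) < w(p_pop)
  }
  expect_true(all(narrower))
})

test_that("longer run-ins do not widen the predictive", {
  params <- model_parameters()
  pd <- population_draws(params, n_draws = 3000)
  med_width <- sapply(c(2, 8), function(nv) {
    widths <- numeric(20)
    for (r in seq_len(20)) {
      set.seed(700 + r)
      eff <- cnmbayes:::draw_effects(1, params)
      tt <- seq(0, by = 2, length.out = nv)
      mu <- plogis(eff$alpha + eff$beta * tt)
      obs <- data.frame(
        time_months = tt,
        scaled_value = rbeta(nv, mu * params$precision_nu,
                             (1 - mu) * params$precision_nu))
      p <- suppressWarnings(predict_run_in(pd, obs, max(tt) + 6,
                                           n_draws = 3000, seed = 800 + r))
      iv <- prediction_intervals(p, 0.95)
      widths[r] <- iv$upper - iv$lower
    }
    median(widths)
  })
  expect_lte(med_width[2], med_width[1])
})

test_that("predictive trajectories export to long CSV", {
  fit <- cached_fit()
  pred <- predict_individual(fit, fit$patient_ids[1], c(2, 4), seed = 1,
                             n_draws = 50)
  path <- file.path(withr::local_tempdir(), "pred.csv")
  write_predictive_csv(pred, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 100)
  expect_equal(back$value[back$draw == 7 & back$time == 4],
               pred$trajectories[7, 2], ignore_attr = TRUE)
})
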