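test_that("responder calls use the inclusive cut-off and relevance margin", {
  des <- trial_design()
  ep <- endpoint_fev1()
  expect_true(call_responder(0.01, 2, des, ep)$is_responder)
  expect_false(call_responder(0.011, 2, des, ep)$is_responder)
  rc <- call_responder(0.005, 9, des, ep)
  expect_true(rc$clinically_relevant)
  expect_false(call_responder(0.005, 7.9, des, ep)$clinically_relevant)
  # for a decreasing endpoint the margin applies to the decrease
  vent <- endpoint_spec("vent", 0, 24, "decrease", 2)
  expect_true(call_responder(0.5, -3, des, vent)$clinically_relevant)
  expect_false(call_responder(0.5, 3, des, vent)$clinically_relevant)
})

test_that("the analytic null responder rate follows the product-of-uniforms law", {
  # P(prod of k uniforms <= q) = exp(-x) * sum_{i<k} x^i / i!, x = -ln q
  x <- -log(0.01)
  expect_equal(null_responder_rate(k = 1, cutoff = 0.01), 0.01)
  expect_equal(null_responder_rate(k = 3, cutoff = 0.01),
               exp(-x) * (1 + x + x^2 / 2))
  # cross-check by direct simulation
  set.seed(2)
  sim <- replicate(2e5, prod(runif(3)))
  p <- mean(sim <= 0.01)
  expect_lt(abs(null_responder_rate(k = 3, cutoff = 0.01) - p),
            3 * sqrt(p * (1 - p) / 2e5))
})

test_that("shortcut null trials reproduce binomial facts", {
  des <- trial_design()
  nulls <- simulate_null_trials(des, n_sim = 50000, seed = 3,
                                null_prob = 0.01)
  counts <- unclass(nulls)
  p_any <- mean(counts >= 1)
  expect_lt(abs(p_any - (1 - 0.99^12)), 3 * sqrt(p_any * (1 - p_any) / 5e4))
  expect_lt(abs(mean(counts) - 0.12), 3 * sd(counts) / sqrt(5e4))
})

test_that("responder-rate posteriors are conjugate", {
  post <- posterior_responder_rate(3, 12)
  expect_equal(post$shape1, 4)
  expect_equal(post$shape2, 10)
  expect_equal(posterior_responder_rate(0, 12)$shape2, 13)
  # posterior mean lies between prior mean and the empirical rate
  pr <- c(2, 6)
  post2 <- posterior_responder_rate(9, 12, prior = pr)
  m <- post2$shape1 / (post2$shape1 + post2$shape2)
  expect_true(m > pr[1] / sum(pr) && m < 9 / 12)
})

test_that("the rate-difference probability matches closed-form oracles", {
  same <- beta_dist(3, 5)
  p_eq <- prob_rate_difference_positive(same, same, n_mc = 2e5, seed = 1)
  expect_lt(abs(p_eq - 0.5), 3 * attr(p_eq, "mc_se"))

  # degenerate null: P = 1 - I_{0.15}(4, 10), the incomplete-beta oracle
  p_deg <- prob_rate_difference_positive(beta_dist(4, 10),
                                         degenerate_dist(0.15),
                                         n_mc = 2e5, seed = 2)
  oracle <- 1 - pbeta(0.15, 4, 10)
  expect_lt(abs(p_deg - oracle), 3 * attr(p_deg, "mc_se"))

  # stochastic dominance pushes the probability below one half
  p_dom <- prob_rate_difference_positive(beta_dist(2, 8), beta_dist(8, 2),
                                         n_mc = 5e4, seed = 3)
  expect_lt(as.numeric(p_dom), 0.5)
})

test_that("threshold calibration agrees with exhaustive enumeration on the binomial toy model", {
  # toy model: responder counts exactly Binomial(12, 0.01), uniform rate
  # prior, beta null-rate distribution fitted to the simulated rates
  des <- trial_design()
  nulls <- simulate_null_trials(des, n_sim = 20000, seed = 5,
                                null_prob = 0.01)
  cal_mc <- calibrate_threshold(nulls, des, n_mc = 4e5, seed = 7)
  cal_ex <- calibrate_threshold(nulls, des, method = "exact")

  # independent enumeration oracle with exact binomial weights
  rd <- cal_ex$rate_dist
  qk <- vapply(0:12, function(k)
    integrate(function(y) dbeta(y, 1 + k, 13 - k) *
                pbeta(y, rd$shape1, rd$shape2), 0, 1,
              rel.tol = 1e-10)$value, numeric(1))
  w <- dbinom(0:12, 12, 0.01)
  grid <- seq(0.01, 0.99, by = 0.01)
  t1 <- vapply(grid, function(c) sum(w[qk > c]), numeric(1))
  c_oracle <- grid[min(which(t1 <= des$alpha))]

  expect_equal(cal_ex$threshold, c_oracle)
  expect_equal(cal_mc$threshold, c_oracle)
  expect_lte(cal_mc$type1_estimate, des$alpha)

  # degenerate grid: alpha = 1 admits the smallest grid threshold
  cal_triv <- calibrate_threshold(nulls, des, alpha = 1, method = "exact")
  expect_equal(cal_triv$threshold, des$threshold_grid_step)
})

test_that("fresh-sample Type I error stays within the bound", {
  des <- trial_design()
  p0 <- 0.11  # realistic per-patient null responder rate
  nulls <- simulate_null_trials(des, n_sim = 20000, seed = 11,
                                null_prob = p0)
  cal <- calibrate_threshold(nulls, des, seed = 11)
  fresh <- simulate_null_trials(des, n_sim = 20000, seed = 12,
                                null_prob = p0)
  t1 <- type1_error(cal, fresh)
  expect_lte(as.numeric(t1), des$alpha + 3 * attr(t1, "mc_se"))
})

test_that("assurance curves behave structurally", {
  des <- trial_design()
  oc <- assurance_curve(des, effect_grid = seq(0, 0.6, by = 0.1),
                        n_set = c(12, 24), null_prob = 0.11,
                        n_sim = 4000, seed = 21)
  cv <- oc$curve
  for (n in c(12, 24)) {
    s <- cv[cv$n == n, ]
    # assurance at zero effect is exactly the Type I estimate
    expect_equal(s$power[s$delta == 0],
                 oc$calibrations[[as.character(n)]]$type1_estimate)
    expect_lte(s$power[s$delta == 0], des$alpha)
    # non-decreasing in the effect, up to Monte-Carlo noise
    expect_true(all(diff(s$power) > -0.02))
  }
  # larger trials are at least as powerful, pointwise up to MC noise
  p12 <- cv$power[cv$n == 12]; p24 <- cv$power[cv$n == 24]
  expect_true(all(p24 - p12 > -0.03))
  # saturation when the effect pushes the rate to one
  expect_warning(
    oc_sat <- assurance_curve(des, effect_grid = 0.99, n_set = 12,
                              null_prob = 0.11, n_sim = 500, seed = 3),
    "clipped")
  expect_gt(oc_sat$curve$power, 0.99)
})

test_that("full-pipeline null trials agree with the shortcut at the estimated rate", {
  des <- trial_design()
  params <- model_parameters()
  full <- simulate_null_trials(des, n_sim = 30, seed = 31, mode = "full",
                               params = params, n_draws = 1500)
  p_hat <- as.numeric(cached_null_rate())
  counts <- unclass(full)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 12 * p_hat), 3 * se + 0.05)
})

test_that("operating characteristics round-trip through CSV and JSON", {
  oc <- assurance_curve(trial_design(), effect_grid = c(0, 0.3),
                        n_set = 12, null_prob = 0.11, n_sim = 1000,
                        seed = 2)
  dir <- withr::local_tempdir()
  write_operating_characteristics(oc, file.path(dir, "oc.csv"),
                                  file.path(dir, "oc.json"))
  back <- read.csv(file.path(dir, "oc.csv"))
  expect_equal(back$power, oc$curve$power)
  meta <- jsonlite::read_json(file.path(dir, "oc.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$thresholds[["12"]], oc$calibrations[["12"]]$threshold)
})
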