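test_that("logit mean reproduces closed forms and centering", {
  expect_equal(logit_mean(0, 0, 5, 17), 0.5)
  expect_equal(logit_mean(log(3), 0, 0, 0), 0.75)
  expect_equal(logit_mean(0, 0.1, -10, 10), 0.5)  # chi = 0 by centering
})

test_that("logit mean is monotone in intercept and, per sign of slope, in time", {
  a <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(logit_mean(a, 0.1, 0, 6)) > 0))
  t <- seq(0, 48, by = 6)
  expect_true(all(diff(logit_mean(0.2, 0.05, -12, t)) > 0))
  expect_true(all(diff(logit_mean(0.2, -0.05, -12, t)) < 0))
  expect_true(all(diff(logit_mean(0.2, 0, -12, t)) == 0))
})

test_that("beta shapes give the stated mean and variance", {
  expect_equal(beta_shape(0.5, 10), list(a = 5, b = 5))
  expect_equal(beta_shape(0.8, 20), list(a = 16, b = 4))
  # moment identities E = mu, Var = mu(1-mu)/(1+nu), against sampling
  set.seed(1)
  sh <- beta_shape(0.3, 25)
  y <- rbeta(2e5, sh$a, sh$b)
  expect_lt(abs(mean(y) - 0.3), 4 * sd(y) / sqrt(2e5))
  expect_lt(abs(var(y) - 0.3 * 0.7 / 26), 0.0005)
  expect_error(beta_shape(0, 10), "strictly inside")
  expect_error(beta_shape(0.5, 0), "positive")
})

test_that("model log-likelihood matches an independent density oracle", {
  ep <- endpoint_fev1()
  # single uniform observation: Beta(1, 1) has log-density zero
  obs <- data.frame(patient_id = "p1", time_months = 0, age_years = 10,
                    raw_value = 50, scaled_value = 0.5)
  pat <- data.frame(patient_id = "p1", genotype = "MTM1", sex = "M",
                    baseline_age = 10)
  ds1 <- longitudinal_dataset(obs, pat, ep, centering_constant = 0)
  pars <- model_parameters(
    precision_nu = 2,
    patient_effects = data.frame(patient_id = "p1", alpha = 0, beta = 0))
  expect_equal(log_likelihood(ds1, pars), 0)

  # additivity: two identical observations double the log-likelihood
  obs37 <- transform(obs, scaled_value = 0.37, raw_value = 37)
  ds1b <- longitudinal_dataset(obs37, pat, ep, centering_constant = 0)
  ds2 <- longitudinal_dataset(rbind(obs37, obs37), pat, ep,
                              centering_constant = 0)
  pars2 <- model_parameters(
    precision_nu = 7,
    patient_effects = data.frame(patient_id = "p1", alpha = 0.4, beta = 0))
  expect_equal(log_likelihood(ds2, pars2), 2 * log_likelihood(ds1b, pars2))

  # random configurations against the log-gamma oracle
  set.seed(7)
  for (r in 1:20) {
    np <- sample(2:5, 1)
    ids <- paste0("p", seq_len(np))
    eff <- data.frame(patient_id = ids, alpha = rnorm(np, 0, 1),
                      beta = rnorm(np, 0, 0.02))
    nu <- runif(1, 2, 100)
    Tc <- runif(1, -24, 0)
    rows <- do.call(rbind, lapply(ids, function(id) {
      t <- sort(sample(0:48, sample(1:4, 1)))
      data.frame(patient_id = id, time_months = t, age_years = 20,
                 raw_value = NA_real_,
                 scaled_value = runif(length(t), 0.05, 0.95))
    }))
    rows$raw_value <- unscale_score(rows$scaled_value, ep)
    pat <- data.frame(patient_id = ids, genotype = "MTM1", sex = "M",
                      baseline_age = 20)
    ds <- longitudinal_dataset(rows, pat, ep, centering_constant = Tc)
    pars <- model_parameters(precision_nu = nu, patient_effects = eff)

    i <- match(ds$observations$patient_id, eff$patient_id)
    mu <- plogis(eff$alpha[i] + eff$beta[i] * (Tc + ds$observations$time_months))
    oracle <- sum(beta_logpdf_oracle(ds$observations$scaled_value,
                                     mu * nu, (1 - mu) * nu))
    expect_equal(log_likelihood(ds, pars), oracle, tolerance = 1e-10)
  }
})

test_that("missing patient effects raise a key error", {
  ds <- cached_data()
  pars <- model_parameters(
    patient_effects = data.frame(patient_id = "nobody", alpha = 0, beta = 0))
  expect_error(log_likelihood(ds, pars), "no patient effects")
})
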