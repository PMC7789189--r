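# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small cohort configuration used wherever a full 59-patient cohort is
# unnecessary
small_config <- function(seed = 11, params = model_parameters()) {
  cohort_config(n_mtm1 = 8, n_dnm2 = 4, generating_params = params,
                seed = seed)
}

# one small fitted model, reused across test files
cached_fit <- function() {
  if (is.null(.fixtures$fit)) {
    ds <- simulate_cohort(small_config(seed = 11))
    .fixtures$data <- ds
    .fixtures$fit <- suppressWarnings(
      fit_mcmc(ds, n_iter = 600, n_adapt = 300, n_burn = 300, seed = 42))
  }
  .fixtures$fit
}

cached_data <- function() {
  cached_fit()
  .fixtures$data
}

# full-pipeline estimate of the per-patient null responder rate under the
# default generating model; moderately expensive, so computed once
cached_null_rate <- function() {
  if (is.null(.fixtures$null_rate)) {
    .fixtures$null_rate <- suppressWarnings(estimate_null_responder_rate(
      model_parameters(), trial_design(), n_patients = 2000,
      n_draws = 4000, seed = 101))
  }
  .fixtures$null_rate
}

# hand-built predictive object with given trajectory matrix
manual_predictive <- function(traj, times = seq_len(ncol(traj))) {
  structure(
    list(patient_id = "manual", future_times = times, trajectories = traj,
         source = "nhs", effects = NULL, T_center = 0),
    class = "cnm_predictive")
}

# independent beta log-density oracle, written directly from the
# log-gamma form rather than dbeta
beta_logpdf_oracle <- function(y, a, b) {
  (a - 1) * log(y) + (b - 1) * log1p(-y) -
    (lgamma(a) + lgamma(b) - lgamma(a + b))
}
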