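#' Individual predictive distribution of untreated evolution
#'
#' Simulates, for each posterior draw, the patient's future scores at the
#' requested times from that draw's `(alpha_i, beta_i, nu)`, so the
#' trajectories carry both parameter uncertainty and beta observation
#' noise. Only pre-treatment (natural-history) data enter the fit these
#' draws come from; nothing observed after treatment influences the
#' prediction.
#'
#' @param draws A `cnm_draws` object (from [fit_mcmc()] or
#'   [population_draws()]) containing effects for `patient_id`.
#' @param patient_id Patient to predict for.
#' @param future_times Strictly increasing times in months on the patient's
#'   visit time scale; may be empty.
#' @param n_draws Number of predictive trajectories (posterior rows are
#'   resampled with replacement if necessary).
#' @param seed Integer seed.
#' @return An object of class `cnm_predictive`: `patient_id`,
#'   `future_times`, `trajectories` (`n_draws` x times matrix in (0, 1)),
#'   `source` (`"nhs"`), and the effect draws used.
#' @export
predict_individual <- function(draws, patient_id, future_times,
                               n_draws = 4000, seed = 1L) {
  stopifnot(inherits(draws, "cnm_draws"))
  patient_id <- as.character(patient_id)
  if (is.null(draws$alpha) || !(patient_id %in% colnames(draws$alpha)))
    stop("unknown patient: ", patient_id)
  check_future_times(future_times)
  set.seed(seed)
  idx <- resample_rows(nrow(draws$pop), n_draws)
  new_predictive(patient_id, future_times,
                 alpha = draws$alpha[idx, patient_id],
                 beta = draws$beta[idx, patient_id],
                 nu = draws$pop[idx, "precision_nu"],
                 T_center = draws$centering_constant, source = "nhs")
}

#' Population-marginal predictive for a new patient without data
#'
#' Draws new-patient random effects from each posterior draw's population
#' distribution and simulates futures, i.e. the predictive for a patient
#' about whom nothing is known beyond membership of the modelled
#' population. This is the explicit "no run-in data" prediction;
#' [predict_run_in()] requires at least one observation.
#'
#' @inheritParams predict_individual
#' @return A `cnm_predictive` with `source = "population"`.
#' @export
predict_population <- function(draws, future_times, n_draws = 4000,
                               seed = 1L) {
  stopifnot(inherits(draws, "cnm_draws"))
  check_future_times(future_times)
  set.seed(seed)
  idx <- resample_rows(nrow(draws$pop), n_draws)
  eff <- draw_new_effects(draws$pop[idx, , drop = FALSE])
  new_predictive("<new>", future_times, eff$alpha, eff$beta,
                 draws$pop[idx, "precision_nu"],
                 draws$centering_constant, source = "population")
}

#' Predictive distribution for a run-in-only patient
#'
#' Patients enrolled without natural-history follow-up contribute only a
#' short run-in before treatment. Their predictive borrows strength from
#' the modelled population: for each posterior draw a candidate new-patient
#' effect pair is drawn from that draw's population distribution, the
#' candidates are importance-reweighted by the beta likelihood of the
#' run-in observations, and trajectories are simulated from the resampled
#' candidates. An effective-sample-size guard warns when the run-in
#' likelihood concentrates on too few candidates for the importance
#' approximation to be trusted; `refit = TRUE` provides the exact (slow)
#' alternative of re-running the MCMC with the run-in patient included.
#'
#' @inheritParams predict_individual
#' @param run_in Data frame with columns `time_months` and `scaled_value`
#'   (times from the patient's first run-in visit); at least one row.
#' @param min_ess Warn if the importance effective sample size falls below
#'   this.
#' @param refit If `TRUE`, refit the model on the fitted dataset augmented
#'   with the run-in observations instead of reweighting (requires `draws`
#'   to be a full [fit_mcmc()] result). Much slower; used as a gold
#'   standard.
#' @param patient_id Label for the run-in patient.
#' @return A `cnm_predictive` with `source = "run_in"` and attributes
#'   `ess` (importance effective sample size) and `weights`.
#' @export
predict_run_in <- function(draws, run_in, future_times, n_draws = 4000,
                           seed = 1L, min_ess = 200, refit = FALSE,
                           patient_id = "run-in") {
  stopifnot(inherits(draws, "cnm_draws"))
  if (is.null(run_in) || nrow(run_in) == 0L)
    stop("no run-in observations; request a population-only prediction ",
         "explicitly with predict_population()")
  stopifnot(all(c("time_months", "scaled_value") %in% names(run_in)))
  if (any(run_in$scaled_value <= 0 | run_in$scaled_value >= 1))
    stop("run-in scaled values must lie strictly inside (0, 1)")
  check_future_times(future_times)

  if (refit) return(predict_run_in_refit(draws, run_in, future_times,
                                         n_draws, seed, patient_id))
  set.seed(seed)
  idx <- resample_rows(nrow(draws$pop), n_draws)
  pop <- draws$pop[idx, , drop = FALSE]
  cand <- draw_new_effects(pop)
  nu <- pop[, "precision_nu"]
  lw <- numeric(n_draws)
  for (j in seq_len(nrow(run_in))) {
    mu <- plogis(cand$alpha + cand$beta *
                   (draws$centering_constant + run_in$time_months[j]))
    lw <- lw + dbeta(run_in$scaled_value[j], mu * nu, (1 - mu) * nu,
                     log = TRUE)
  }
  w <- exp(lw - max(lw))
  ess <- sum(w)^2 / sum(w^2)
  if (ess < min_ess)
    warning(sprintf(
      "importance effective sample size %.0f below %d; consider refit = TRUE",
      ess, min_ess), call. = FALSE)
  ridx <- sample.int(n_draws, n_draws, replace = TRUE, prob = w)
  out <- new_predictive(patient_id, future_times,
                        cand$alpha[ridx], cand$beta[ridx], nu[ridx],
                        draws$centering_constant, source = "run_in")
  attr(out, "ess") <- ess
  attr(out, "weights") <- w / sum(w)
  out
}

# exact slow path: refit including the run-in patient, then predict
predict_run_in_refit <- function(draws, run_in, future_times, n_draws,
                                 seed, patient_id) {
  if (is.null(draws$dataset))
    stop("`refit = TRUE` requires draws from fit_mcmc() with a stored dataset")
  ds <- draws$dataset
  ep <- ds$endpoint
  add_obs <- data.frame(patient_id = patient_id,
                        time_months = run_in$time_months,
                        age_years = NA_real_,
                        raw_value = unscale_score(run_in$scaled_value, ep),
                        scaled_value = run_in$scaled_value,
                        stringsAsFactors = FALSE)
  add_pat <- data.frame(patient_id = patient_id, genotype = "MTM1",
                        sex = "M", baseline_age = NA_real_,
                        stringsAsFactors = FALSE)
  obs <- rbind(ds$observations[names(add_obs)], add_obs)
  pat <- rbind(ds$patients[names(add_pat)], add_pat)
  aug <- longitudinal_dataset(obs, pat, ep,
                              centering_constant = ds$centering_constant)
  cfg <- draws$config
  refit <- suppressWarnings(fit_mcmc(
    aug, priors = draws$priors, n_chains = cfg$n_chains,
    n_iter = cfg$n_iter, n_adapt = cfg$n_adapt, n_burn = cfg$n_burn,
    thin = cfg$thin, seed = draws$seed))
  out <- predict_individual(refit, patient_id, future_times, n_draws, seed)
  out$source <- "run_in"
  out
}

new_predictive <- function(patient_id, future_times, alpha, beta, nu,
                           T_center, source) {
  n <- length(alpha)
  traj <- matrix(numeric(0), nrow = n, ncol = length(future_times))
  for (j in seq_along(future_times)) {
    mu <- plogis(alpha + beta * (T_center + future_times[j]))
    traj[, j] <- rbeta(n, mu * nu, (1 - mu) * nu)
  }
  colnames(traj) <- if (length(future_times)) paste0("t", future_times)
  structure(
    list(patient_id = patient_id, future_times = future_times,
         trajectories = traj, source = source,
         effects = list(alpha = alpha, beta = beta, nu = nu),
         T_center = T_center),
    class = "cnm_predictive")
}

check_future_times <- function(times) {
  stopifnot(is.numeric(times))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`future_times` must be strictly increasing")
  invisible(times)
}

resample_rows <- function(n_avail, n_draws) {
  if (n_draws == n_avail) seq_len(n_avail)
  else sample.int(n_avail, n_draws, replace = TRUE)
}

#' @export
print.cnm_predictive <- function(x, ...) {
  cat(sprintf("<cnm_predictive> %s (%s): %d trajectories at %s months\n",
              x$patient_id, x$source, nrow(x$trajectories),
              paste(x$future_times, collapse = ", ")))
  invisible(x)
}

#' Central prediction intervals from a predictive distribution
#'
#' Equal-tailed empirical quantile intervals of the predictive trajectories
#' at each future time.
#'
#' @param pred A `cnm_predictive`.
#' @param level Nominal central probability, strictly inside (0, 1).
#' @return Data frame with columns `time`, `level`, `lower`, `upper`,
#'   `median`.
#' @export
prediction_intervals <- function(pred, level = 0.95) {
  stopifnot(inherits(pred, "cnm_predictive"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must lie strictly inside (0, 1)")
  if (length(pred$future_times) == 0L)
    return(data.frame(time = numeric(0), level = numeric(0),
                      lower = numeric(0), median = numeric(0),
                      upper = numeric(0)))
  lo <- (1 - level) / 2
  q <- apply(pred$trajectories, 2, stats::quantile,
             probs = c(lo, 0.5, 1 - lo), names = FALSE)
  data.frame(time = pred$future_times, level = level,
             lower = q[1, ], median = q[2, ], upper = q[3, ])
}

#' Joint predictive probability of the observed improvement
#'
#' Monte-Carlo estimate of the orthant probability that a predictive
#' trajectory is at least as extreme as the observed post-treatment values
#' at all times simultaneously: componentwise `>=` the observations for
#' endpoints that improve by increasing, `<=` for endpoints that improve by
#' decreasing. Individual observations can each sit inside their marginal
#' 95% interval while this joint probability still falls below the 0.01
#' responder cut-off. Ties ("at least as extreme") are inclusive, which is
#' immaterial for continuous draws.
#'
#' @param pred A `cnm_predictive`.
#' @param observed Numeric vector of observed scaled values, one per future
#'   time.
#' @param direction `"increase"` or `"decrease"`.
#' @return The probability estimate in \[0, 1\], with attribute `mc_se`
#'   (binomial Monte-Carlo standard error).
#' @export
joint_improvement_probability <- function(pred, observed,
                                          direction = c("increase",
                                                        "decrease")) {
  stopifnot(inherits(pred, "cnm_predictive"))
  direction <- match.arg(direction)
  if (length(observed) != length(pred$future_times))
    stop(sprintf("`observed` has %d values but the predictive has %d times",
                 length(observed), length(pred$future_times)))
  traj <- pred$trajectories
  hit <- if (direction == "increase") {
    rowSums(traj >= rep(observed, each = nrow(traj))) == ncol(traj)
  } else {
    rowSums(traj <= rep(observed, each = nrow(traj))) == ncol(traj)
  }
  p <- mean(hit)
  structure(p, mc_se = sqrt(p * (1 - p) / length(hit)))
}

#' Export predictive trajectories to long-format CSV
#'
#' One row per (draw, time) with the simulated scaled value, suitable for
#' plotting fans or further summaries outside R.
#'
#' @param pred A `cnm_predictive`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_predictive_csv <- function(pred, path) {
  stopifnot(inherits(pred, "cnm_predictive"))
  n <- nrow(pred$trajectories)
  long <- data.frame(
    patient_id = pred$patient_id,
    draw = rep(seq_len(n), times = length(pred$future_times)),
    time = rep(pred$future_times, each = n),
    value = as.vector(pred$trajectories), stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

# one new-patient effect pair per posterior draw (row of the pop matrix)
draw_new_effects <- function(pop) {
  n <- nrow(pop)
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- pop[, "re_correlation"]
  list(alpha = pop[, "pop_intercept"] + pop[, "re_sd_intercept"] * z1,
       beta = pop[, "pop_slope"] +
         pop[, "re_sd_slope"] * (rho * z1 + sqrt(1 - rho^2) * z2))
}
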