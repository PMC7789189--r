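#' Logit-linear mean trajectory
#'
#' The disease-progression model places each patient's mean on a line on the
#' logit scale, `chi = alpha + beta * (T + t)`, and maps it to the unit
#' interval with the inverse logit, `mu = 1 / (1 + exp(-chi))`. `T` is a
#' constant that centres time so the intercept is interpretable at the
#' centre of the observation window.
#'
#' @param alpha Patient-level intercept on the logit scale.
#' @param beta Patient-level slope on the logit scale, per month.
#' @param T_center Centering constant in months (often minus the mean
#'   observation time).
#' @param t Time in months since the patient's first visit.
#'
#' @return Mean value(s) in (0, 1). Arguments are recycled as usual.
#' @examples
#' logit_mean(0, 0, 0, 12)        # 0.5
#' logit_mean(log(3), 0, 0, 0)    # 0.75
#' @export
logit_mean <- function(alpha, beta, T_center, t) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            is.numeric(T_center), is.numeric(t))
  plogis(alpha + beta * (T_center + t))
}

#' Beta distribution shapes from mean and precision
#'
#' Converts the mean/precision parameterisation of the beta distribution to
#' the standard shapes: `a = mu * nu`, `b = (1 - mu) * nu`. Under this
#' parameterisation the distribution has mean `mu` and variance
#' `mu * (1 - mu) / (1 + nu)`; `nu` acts as a prior "sample size", with
#' larger values giving less visit-to-visit variability.
#'
#' @param mu Mean in the open interval (0, 1).
#' @param nu Precision ("sample size"), strictly positive.
#' @return A list with numeric components `a` and `b`.
#' @examples
#' beta_shape(0.5, 10)   # a = b = 5
#' beta_shape(0.8, 20)   # a = 16, b = 4
#' @export
beta_shape <- function(mu, nu) {
  stopifnot(is.numeric(mu), is.numeric(nu))
  if (any(mu <= 0 | mu >= 1))
    stop("`mu` must lie strictly inside (0, 1); squeeze boundary values first")
  if (any(nu <= 0)) stop("`nu` must be strictly positive")
  list(a = mu * nu, b = (1 - mu) * nu)
}

#' Population and patient-level model parameters
#'
#' Collects the parameters of the hierarchical beta/logit model: the
#' population means of the random intercept and slope, the random-effect
#' standard deviations and their correlation, the beta precision `nu`, and
#' (optionally) realised per-patient effects.
#'
#' @param pop_intercept,pop_slope Population means of the patient intercepts
#'   and slopes on the logit scale (slope per month).
#' @param re_sd_intercept,re_sd_slope Standard deviations of the bivariate
#'   normal random effects, strictly positive unless the object describes a
#'   degenerate (point-mass) population, in which case zero is allowed.
#' @param re_correlation Correlation between intercept and slope, in
#'   \[-1, 1\].
#' @param precision_nu Beta precision, strictly positive.
#' @param patient_effects Optional data frame with columns `patient_id`,
#'   `alpha`, `beta` giving realised per-patient effects.
#'
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(pop_intercept = 0.2, pop_slope = -0.002,
                             re_sd_intercept = 0.8, re_sd_slope = 0.01,
                             re_correlation = 0, precision_nu = 60,
                             patient_effects = NULL) {
  stopifnot(is.finite(pop_intercept), is.finite(pop_slope),
            re_sd_intercept >= 0, re_sd_slope >= 0,
            abs(re_correlation) <= 1, precision_nu > 0)
  if (!is.null(patient_effects)) {
    stopifnot(is.data.frame(patient_effects),
              all(c("patient_id", "alpha", "beta") %in% names(patient_effects)))
    patient_effects$patient_id <- as.character(patient_effects$patient_id)
  }
  structure(
    list(pop_intercept = pop_intercept, pop_slope = pop_slope,
         re_sd_intercept = re_sd_intercept, re_sd_slope = re_sd_slope,
         re_correlation = re_correlation, precision_nu = precision_nu,
         patient_effects = patient_effects),
    class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  population intercept %g, slope %g /month (logit scale)\n",
              x$pop_intercept, x$pop_slope))
  cat(sprintf("  random-effect sds (%g, %g), correlation %g\n",
              x$re_sd_intercept, x$re_sd_slope, x$re_correlation))
  cat(sprintf("  beta precision nu = %g\n", x$precision_nu))
  if (!is.null(x$patient_effects))
    cat(sprintf("  %d realised patient effects\n", nrow(x$patient_effects)))
  invisible(x)
}

#' Prior specification for the hierarchical model
#'
#' Diffuse, weakly-informative priors: zero-centred normals with large scale
#' on the population intercept and slope, half-Cauchy priors on the
#' random-effect standard deviations, a uniform prior on the correlation,
#' and a wide log-normal prior on the beta precision `nu`.
#'
#' @param intercept_loc,intercept_scale Normal prior on the population
#'   intercept (logit scale).
#' @param slope_loc,slope_scale Normal prior on the population slope.
#' @param re_sd_scale Scale of the half-Cauchy priors on both random-effect
#'   standard deviations.
#' @param nu_log_loc,nu_log_scale Normal prior on `log(nu)`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_loc = 0, intercept_scale = 10,
                       slope_loc = 0, slope_scale = 10,
                       re_sd_scale = 5,
                       nu_log_loc = 0, nu_log_scale = 5) {
  stopifnot(intercept_scale > 0, slope_scale > 0,
            re_sd_scale > 0, nu_log_scale > 0)
  structure(
    list(intercept_loc = intercept_loc, intercept_scale = intercept_scale,
         slope_loc = slope_loc, slope_scale = slope_scale,
         re_sd_scale = re_sd_scale,
         nu_log_loc = nu_log_loc, nu_log_scale = nu_log_scale),
    class = "prior_spec")
}

#' Log-likelihood of the beta/logit progression model
#'
#' Sums the beta log-density over all observations of a longitudinal
#' dataset, with each observation's mean given by [logit_mean()] evaluated
#' at the patient's effects and the shapes given by [beta_shape()].
#'
#' @param dataset A [longitudinal_dataset()].
#' @param params A [model_parameters()] whose `patient_effects` covers every
#'   patient in the dataset.
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, params) {
  stopifnot(inherits(dataset, "cnm_data"), inherits(params, "model_parameters"))
  eff <- params$patient_effects
  if (is.null(eff)) stop("`params$patient_effects` is required")
  obs <- dataset$observations
  idx <- match(obs$patient_id, eff$patient_id)
  if (anyNA(idx)) {
    missing <- unique(obs$patient_id[is.na(idx)])
    stop("no patient effects for: ", paste(missing, collapse = ", "))
  }
  mu <- logit_mean(eff$alpha[idx], eff$beta[idx],
                   dataset$centering_constant, obs$time_months)
  sh <- beta_shape(mu, params$precision_nu)
  sum(dbeta(obs$scaled_value, sh$a, sh$b, log = TRUE))
}
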