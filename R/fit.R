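#' Fit the hierarchical beta/logit progression model by MCMC
#'
#' Fits, by Gibbs/Metropolis sampling through JAGS, the hierarchical model
#' \deqn{y_{ij} \sim Beta(\mu_{ij}\nu, (1-\mu_{ij})\nu), \quad
#'       logit(\mu_{ij}) = \alpha_i + \beta_i (T + t_j),}
#' with patient effects \eqn{(\alpha_i, \beta_i)} bivariate normal with
#' unstructured covariance, and the priors of [prior_spec()]. One precision
#' `nu` is shared across observations.
#'
#' The fit is deterministic given `seed` and the run configuration: chain
#' RNGs are seeded from `seed`, so two identical calls return identical
#' draws. Convergence is assessed by split-Rhat and effective sample size;
#' if any monitored parameter exceeds `rhat_limit` (or the population
#' parameters fall below `min_ess`) the returned object is flagged
#' non-converged and a warning is raised.
#'
#' @param dataset A [longitudinal_dataset()].
#' @param priors A [prior_spec()].
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Posterior iterations kept per chain.
#' @param n_adapt,n_burn Adaptation and burn-in iterations.
#' @param thin Thinning interval.
#' @param seed Integer seed.
#' @param rhat_limit,min_ess Convergence-flag thresholds.
#' @param quiet Suppress JAGS progress output.
#'
#' @return An object of classes `cnm_fit` and `cnm_draws` with components
#'   `pop` (draws x 6 matrix of population parameters), `alpha` and `beta`
#'   (draws x patients matrices), `chain`, `diagnostics`, `converged`,
#'   `dataset`, `priors`, `seed`.
#' @export
fit_mcmc <- function(dataset, priors = prior_spec(), n_chains = 2,
                     n_iter = 2000, n_adapt = 500, n_burn = 500, thin = 1,
                     seed = 1L, rhat_limit = 1.05, min_ess = 400,
                     quiet = TRUE) {
  stopifnot(inherits(dataset, "cnm_data"), inherits(priors, "prior_spec"),
            n_chains >= 2, n_iter >= 2, thin >= 1)
  obs <- dataset$observations
  ids <- dataset$patients$patient_id
  pid <- match(obs$patient_id, ids)
  data <- list(N = nrow(obs), P = length(ids), y = obs$scaled_value,
               t = obs$time_months, pid = pid,
               T = dataset$centering_constant)
  model_str <- jags_model_string(priors)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) * 1000L + ch,
         mu_pop = c(0, 0), sd_a = 0.5, sd_b = 0.05, rho = 0,
         log_nu = log(20), u = cbind(rep(0, length(ids)), rep(0, length(ids))))
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = data,
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_adapt, quiet = quiet)
    stats::update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, c("mu_pop", "sd_a", "sd_b", "rho", "nu", "u"),
                        n.iter = n_iter, thin = thin,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressMessages(run()) else run()

  vn <- coda::varnames(samples)
  pop_map <- c(pop_intercept = "mu_pop[1]", pop_slope = "mu_pop[2]",
               re_sd_intercept = "sd_a", re_sd_slope = "sd_b",
               re_correlation = "rho", precision_nu = "nu")
  stacked <- do.call(rbind, lapply(samples, as.matrix))
  kept <- nrow(samples[[1]])
  chain <- rep(seq_len(n_chains), each = kept)
  pop <- stacked[, pop_map, drop = FALSE]
  colnames(pop) <- names(pop_map)
  a_cols <- sprintf("u[%d,1]", seq_along(ids))
  b_cols <- sprintf("u[%d,2]", seq_along(ids))
  alpha <- stacked[, a_cols, drop = FALSE]; colnames(alpha) <- ids
  beta <- stacked[, b_cols, drop = FALSE]; colnames(beta) <- ids

  diag_names <- c(pop_map, stats::setNames(a_cols, paste0("alpha[", ids, "]")),
                  stats::setNames(b_cols, paste0("beta[", ids, "]")))
  rhat <- vapply(diag_names, function(v)
    split_rhat(sapply(samples, function(ch) as.matrix(ch)[, v])),
    numeric(1))
  ess <- coda::effectiveSize(samples)[diag_names]
  diagnostics <- data.frame(parameter = names(diag_names),
                            rhat = unname(rhat), ess = unname(ess),
                            stringsAsFactors = FALSE)
  pop_ess <- diagnostics$ess[seq_len(6)]
  converged <- all(diagnostics$rhat <= rhat_limit, na.rm = TRUE) &&
    all(pop_ess >= min_ess)
  out <- structure(
    list(pop = pop, alpha = alpha, beta = beta, chain = chain,
         patient_ids = ids, endpoint = dataset$endpoint,
         centering_constant = dataset$centering_constant,
         diagnostics = diagnostics, converged = converged,
         dataset = dataset, priors = priors, seed = as.integer(seed),
         config = list(n_chains = n_chains, n_iter = n_iter,
                       n_adapt = n_adapt, n_burn = n_burn, thin = thin,
                       rhat_limit = rhat_limit, min_ess = min_ess)),
    class = c("cnm_fit", "cnm_draws"))
  if (!converged) {
    worst <- diagnostics[which.max(diagnostics$rhat), ]
    warning(sprintf(
      "MCMC convergence flag: max split-Rhat %.3f (%s), min population ESS %.0f; increase iterations",
      worst$rhat, worst$parameter, min(pop_ess)), call. = FALSE)
  }
  out
}

# JAGS model; priors injected from prior_spec (dnorm uses precision)
jags_model_string <- function(priors) {
  sprintf("
model {
  for (k in 1:N) {
    logit(mu[k]) <- u[pid[k],1] + u[pid[k],2] * (T + t[k])
    y[k] ~ dbeta(mu[k] * nu, (1 - mu[k]) * nu)
  }
  for (i in 1:P) {
    u[i,1:2] ~ dmnorm.vcov(mu_pop[1:2], Sigma[1:2,1:2])
  }
  mu_pop[1] ~ dnorm(%g, %g)
  mu_pop[2] ~ dnorm(%g, %g)
  sd_a ~ dt(0, %g, 1) T(0,)
  sd_b ~ dt(0, %g, 1) T(0,)
  rho ~ dunif(-1, 1)
  Sigma[1,1] <- sd_a * sd_a
  Sigma[2,2] <- sd_b * sd_b
  Sigma[1,2] <- rho * sd_a * sd_b
  Sigma[2,1] <- Sigma[1,2]
  log_nu ~ dnorm(%g, %g)
  nu <- exp(log_nu)
}",
    priors$intercept_loc, 1 / priors$intercept_scale^2,
    priors$slope_loc, 1 / priors$slope_scale^2,
    1 / priors$re_sd_scale^2, 1 / priors$re_sd_scale^2,
    priors$nu_log_loc, 1 / priors$nu_log_scale^2)
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain trends register as apparent non-convergence.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return The split-Rhat value (>= 1, with 1 indicating convergence), or
#'   `NA` for degenerate (zero-variance) chains.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])))
  m <- ncol(splits); nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt((nn - 1) / nn + B / (W * nn))
}

#' @export
print.cnm_fit <- function(x, ...) {
  cat(sprintf("<cnm_fit> %s: %d patients, %d draws (%d chains), seed %d\n",
              x$endpoint$name, length(x$patient_ids), nrow(x$pop),
              x$config$n_chains, x$seed))
  cat(if (x$converged) "  converged (split-Rhat/ESS within limits)\n"
      else "  NOT converged: inspect $diagnostics\n")
  print(summary_matrix(x$pop))
  invisible(x)
}

summary_matrix <- function(m) {
  t(apply(m, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      `2.5%` = unname(stats::quantile(v, 0.025)),
      `97.5%` = unname(stats::quantile(v, 0.975)))))
}

#' Posterior summary of a fit
#'
#' @param object A `cnm_fit`.
#' @param ... Unused.
#' @return Matrix of posterior means, sds and central 95% intervals for the
#'   population parameters.
#' @export
summary.cnm_fit <- function(object, ...) summary_matrix(object$pop)

#' Build draws from known population parameters
#'
#' Constructs a draws object representing a point-mass "posterior" at known
#' generating parameters, replicated `n_draws` times. Used to run the
#' predictive and trial machinery directly from a known generator (e.g. in
#' simulation studies), and to encode degenerate single-point draws for
#' analytic checks. If `params$patient_effects` is supplied those patients
#' get (constant) effect columns.
#'
#' @param params A [model_parameters()].
#' @param n_draws Number of replicated draws.
#' @param endpoint Optional [endpoint_spec()] carried along for unscaling.
#' @param centering_constant Time-centering constant `T` (months).
#' @return An object of class `cnm_draws`.
#' @export
population_draws <- function(params, n_draws = 4000,
                             endpoint = endpoint_fev1(),
                             centering_constant = 0) {
  stopifnot(inherits(params, "model_parameters"), n_draws >= 1)
  pop <- matrix(rep(c(params$pop_intercept, params$pop_slope,
                      params$re_sd_intercept, params$re_sd_slope,
                      params$re_correlation, params$precision_nu),
                    each = n_draws),
                nrow = n_draws,
                dimnames = list(NULL, c("pop_intercept", "pop_slope",
                                        "re_sd_intercept", "re_sd_slope",
                                        "re_correlation", "precision_nu")))
  alpha <- beta <- NULL; ids <- character(0)
  if (!is.null(params$patient_effects)) {
    eff <- params$patient_effects
    ids <- eff$patient_id
    alpha <- matrix(rep(eff$alpha, each = n_draws), nrow = n_draws,
                    dimnames = list(NULL, ids))
    beta <- matrix(rep(eff$beta, each = n_draws), nrow = n_draws,
                   dimnames = list(NULL, ids))
  }
  structure(
    list(pop = pop, alpha = alpha, beta = beta,
         chain = rep(1L, n_draws), patient_ids = ids, endpoint = endpoint,
         centering_constant = centering_constant,
         diagnostics = NULL, converged = TRUE, dataset = NULL,
         priors = NULL, seed = NA_integer_, config = list()),
    class = "cnm_draws")
}

#' Posterior-predictive fit check
#'
#' For every observation, computes the posterior mean of the model mean
#' `mu_ij` and a central posterior-predictive interval, and reports the
#' fraction of observations falling inside their nominal-level interval.
#' This is the package's analogue of overlaying model fits on per-patient
#' score trajectories.
#'
#' @param fit A `cnm_fit` from [fit_mcmc()].
#' @param dataset The dataset the model was fit to; defaults to the one
#'   stored in the fit. Supplying a dataset for a different endpoint is an
#'   error.
#' @param level Nominal predictive-interval level.
#' @param seed Seed for the predictive draws.
#' @return An object of class `cnm_fit_check`: a list with `fitted` (one
#'   row per observation: posterior mean trajectory, interval, indicator)
#'   and `coverage` (fraction inside).
#' @export
posterior_fit_check <- function(fit, dataset = fit$dataset, level = 0.95,
                                seed = 1L) {
  stopifnot(inherits(fit, "cnm_fit"), inherits(dataset, "cnm_data"),
            level > 0, level < 1)
  if (!identical(dataset$endpoint$name, fit$endpoint$name))
    stop("endpoint mismatch between fit and dataset")
  obs <- dataset$observations
  idx <- match(obs$patient_id, fit$patient_ids)
  if (anyNA(idx)) stop("dataset contains patients absent from the fit")
  set.seed(seed)
  nu <- fit$pop[, "precision_nu"]
  lo <- (1 - level) / 2; hi <- 1 - lo
  fitted <- obs[, c("patient_id", "time_months", "scaled_value")]
  fitted$fit_mean <- NA_real_; fitted$lower <- NA_real_; fitted$upper <- NA_real_
  for (r in seq_len(nrow(obs))) {
    mu <- plogis(fit$alpha[, idx[r]] + fit$beta[, idx[r]] *
                   (fit$centering_constant + obs$time_months[r]))
    yrep <- rbeta(length(mu), mu * nu, (1 - mu) * nu)
    q <- stats::quantile(yrep, c(lo, hi), names = FALSE)
    fitted$fit_mean[r] <- mean(mu)
    fitted$lower[r] <- q[1]; fitted$upper[r] <- q[2]
  }
  fitted$inside <- fitted$scaled_value >= fitted$lower &
    fitted$scaled_value <= fitted$upper
  structure(list(fitted = fitted, coverage = mean(fitted$inside),
                 level = level),
            class = "cnm_fit_check")
}

#' @export
print.cnm_fit_check <- function(x, ...) {
  cat(sprintf("<cnm_fit_check> %.0f%% predictive intervals cover %.1f%% of %d observations\n",
              100 * x$level, 100 * x$coverage, nrow(x$fitted)))
  invisible(x)
}

#' Persist posterior draws as CSV plus JSON metadata
#'
#' Writes a long-format CSV (`chain`, `iteration`, `parameter`, `value`)
#' and a JSON sidecar with the seed, run configuration, prior settings and
#' diagnostics, so a draws file is self-describing.
#'
#' @param fit A `cnm_fit`.
#' @param path Path of the CSV file to create; the sidecar gets the same
#'   path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "cnm_fit"))
  kept <- table(fit$chain)[1]
  wide <- cbind(fit$pop, fit$alpha, fit$beta)
  colnames(wide) <- c(colnames(fit$pop),
                      paste0("alpha[", fit$patient_ids, "]"),
                      paste0("beta[", fit$patient_ids, "]"))
  long <- data.frame(
    chain = rep(fit$chain, times = ncol(wide)),
    iteration = rep(rep(seq_len(kept), length(unique(fit$chain))),
                    times = ncol(wide)),
    parameter = rep(colnames(wide), each = nrow(wide)),
    value = as.vector(wide), stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(seed = fit$seed, config = fit$config,
               priors = unclass(fit$priors),
               endpoint = unclass(fit$endpoint),
               centering_constant = fit$centering_constant,
               converged = fit$converged,
               diagnostics = fit$diagnostics)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read draws persisted by [write_draws()]
#'
#' @param path Path of the draws CSV.
#' @return An object of class `cnm_draws` (without the original dataset).
#' @export
read_draws <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  params <- unique(long$parameter)
  wide <- sapply(params, function(p) long$value[long$parameter == p])
  chain <- long$chain[long$parameter == params[1]]
  pop_cols <- c("pop_intercept", "pop_slope", "re_sd_intercept",
                "re_sd_slope", "re_correlation", "precision_nu")
  a_cols <- grep("^alpha\\[", params, value = TRUE)
  b_cols <- grep("^beta\\[", params, value = TRUE)
  ids <- sub("^alpha\\[(.*)\\]$", "\\1", a_cols)
  ep <- meta$endpoint
  structure(
    list(pop = wide[, pop_cols, drop = FALSE],
         alpha = `colnames<-`(wide[, a_cols, drop = FALSE], ids),
         beta = `colnames<-`(wide[, b_cols, drop = FALSE], ids),
         chain = chain, patient_ids = ids,
         endpoint = endpoint_spec(ep$name, ep$lower_bound, ep$upper_bound,
                                  ep$improvement_direction,
                                  ep$relevance_margin),
         centering_constant = meta$centering_constant,
         diagnostics = meta$diagnostics, converged = meta$converged,
         dataset = NULL, priors = do.call(prior_spec, as.list(meta$priors)),
         seed = meta$seed, config = meta$config),
    class = c("cnm_fit", "cnm_draws"))
}
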