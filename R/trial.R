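#' Single-arm trial design based on responder counting
#'
#' Collects the design constants of the responder-based single-arm trial:
#' the number of patients, the number of post-treatment visits entering the
#' joint predictive probability, the responder cut-off, the overall Type I
#' error bound, and the prior on the response rate.
#'
#' @param n_patients Patients enrolled (default 12).
#' @param n_future_visits Post-treatment visits entering the joint
#'   statistic (default 3, e.g. months 2, 4 and 6 after treatment).
#' @param responder_cutoff Joint-predictive-probability cut-off at or below
#'   which a patient is declared a responder (default 0.01).
#' @param alpha Overall Type I error bound (default 0.05).
#' @param rate_prior Length-2 beta shape pair of the prior on the response
#'   rate (default uniform, `c(1, 1)`).
#' @param threshold_grid_step Grid resolution for the calibrated decision
#'   threshold (default 0.01, matching a percent-scale threshold).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_patients = 12, n_future_visits = 3,
                         responder_cutoff = 0.01, alpha = 0.05,
                         rate_prior = c(1, 1), threshold_grid_step = 0.01) {
  stopifnot(n_patients >= 1, n_future_visits >= 1,
            responder_cutoff > 0, responder_cutoff < 1,
            alpha > 0, alpha < 1,
            length(rate_prior) == 2L, all(rate_prior > 0),
            threshold_grid_step > 0, threshold_grid_step < 1)
  structure(
    list(n_patients = as.integer(n_patients),
         n_future_visits = as.integer(n_future_visits),
         responder_cutoff = responder_cutoff, alpha = alpha,
         rate_prior = rate_prior,
         threshold_grid_step = threshold_grid_step),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "<trial_design> n = %d, %d future visits, responder cutoff %g, alpha %g, rate prior Beta(%g, %g)\n",
    x$n_patients, x$n_future_visits, x$responder_cutoff, x$alpha,
    x$rate_prior[1], x$rate_prior[2]))
  invisible(x)
}

#' Classify one patient as responder / clinically relevant
#'
#' A patient is a responder when the joint predictive probability of the
#' observed improvement is at or below the design's cut-off (inclusive).
#' Separately, the observed change is flagged clinically relevant when it
#' moves in the endpoint's improvement direction by at least the
#' endpoint's relevance margin (8 percentage points for FEV1). The two
#' flags are reported independently.
#'
#' @param joint_probability Joint predictive probability from
#'   [joint_improvement_probability()].
#' @param observed_change Observed change in raw score units (signed;
#'   positive means the score increased).
#' @param design A [trial_design()].
#' @param endpoint An [endpoint_spec()].
#' @return An object of class `responder_call` with fields
#'   `joint_probability`, `is_responder`, `clinically_relevant`,
#'   `observed_change`.
#' @export
call_responder <- function(joint_probability, observed_change, design,
                           endpoint) {
  stopifnot(inherits(design, "trial_design"),
            inherits(endpoint, "endpoint_spec"),
            joint_probability >= 0, joint_probability <= 1)
  signed <- if (endpoint$improvement_direction == "increase")
    observed_change else -observed_change
  structure(
    list(joint_probability = as.numeric(joint_probability),
         is_responder = joint_probability <= design$responder_cutoff,
         clinically_relevant = signed >= endpoint$relevance_margin,
         observed_change = observed_change),
    class = "responder_call")
}

#' @export
print.responder_call <- function(x, ...) {
  cat(sprintf(
    "<responder_call> joint p = %.4g -> %sresponder; change %+g (%sclinically relevant)\n",
    x$joint_probability, if (x$is_responder) "" else "non-",
    x$observed_change, if (x$clinically_relevant) "" else "not "))
  invisible(x)
}

#' Null responder rate of the joint tail statistic under independence
#'
#' For `k` future visits whose predictive coordinates are (conditionally)
#' independent, the joint improvement probability evaluated at null futures
#' is a product of `k` independent uniforms, so the probability that it
#' falls at or below the cut-off `q` is `P(Gamma(k, 1) >= -log q)`. This is
#' the per-patient null responder rate in the noise-dominated limit and an
#' upper bound in general; dependence induced by shared parameter
#' uncertainty pulls the rate down towards `q` (the comonotone limit). It
#' does not depend on the endpoint, only on `k` and `q`.
#'
#' @param design A [trial_design()], or `NULL` if `k` and `cutoff` are
#'   given directly.
#' @param k Number of future visits.
#' @param cutoff Responder cut-off.
#' @return The per-patient null responder probability.
#' @examples
#' null_responder_rate(k = 3, cutoff = 0.01)  # 0.162
#' @export
null_responder_rate <- function(design = NULL, k = design$n_future_visits,
                                cutoff = design$responder_cutoff) {
  stopifnot(k >= 1, cutoff > 0, cutoff < 1)
  pgamma(-log(cutoff), shape = k, rate = 1, lower.tail = FALSE)
}

#' Estimate the per-patient null responder rate by full-pipeline simulation
#'
#' Simulates patients from a known generating model: each patient receives
#' a natural-history history on the age-dependent visit schedule, futures
#' at the next `n_future_visits` post-treatment visits are drawn from their
#' true trajectory (no treatment effect), the patient's predictive
#' distribution is built by importance-reweighting population draws by the
#' history likelihood (exactly as for a run-in patient), and the joint
#' improvement probability is compared to the responder cut-off. The
#' returned fraction is the Monte-Carlo estimate of the rule's true null
#' responder rate under the generating conditions.
#'
#' @param params A [model_parameters()] generating model.
#' @param design A [trial_design()].
#' @param n_patients Number of simulated patients.
#' @param n_draws Predictive trajectory draws per patient (>= 4000 for
#'   production use).
#' @param seed Integer seed.
#' @param age_range,follow_up_range Baseline ages (years) and follow-up
#'   (months) sampled uniformly per patient.
#' @param future_spacing Months between post-treatment visits (default 2,
#'   i.e. visits at 2, 4, 6 months after the last history visit).
#' @return Estimated rate with attributes `mc_se` and `n`.
#' @export
estimate_null_responder_rate <- function(params, design = trial_design(),
                                         n_patients = 2000, n_draws = 4000,
                                         seed = 1L, age_range = c(0, 30),
                                         follow_up_range = c(12, 48),
                                         future_spacing = 2) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(design, "trial_design"), n_patients >= 1)
  set.seed(seed)
  nu <- params$precision_nu
  k <- design$n_future_visits
  hits <- logical(n_patients)
  for (i in seq_len(n_patients)) {
    eff <- draw_effects(1, params)
    tt <- visit_schedule(runif(1, age_range[1], age_range[2]),
                         runif(1, follow_up_range[1], follow_up_range[2]))
    mu_h <- plogis(eff$alpha + eff$beta * tt)
    y <- rbeta(length(tt), mu_h * nu, (1 - mu_h) * nu)
    tf <- max(tt) + future_spacing * seq_len(k)
    mu_f <- plogis(eff$alpha + eff$beta * tf)
    yf <- rbeta(k, mu_f * nu, (1 - mu_f) * nu)
    jp <- importance_joint_probability(params, tt, y, tf, yf, n_draws)
    hits[i] <- jp <= design$responder_cutoff
  }
  p <- mean(hits)
  structure(p, mc_se = sqrt(p * (1 - p) / n_patients), n = n_patients)
}

# importance-reweighted effect draws given a patient's history, from known
# hyperparameters (the run-in machinery specialised to a point-mass
# "posterior"); shared by the null-rate estimator, the full trial
# simulator and the coverage check
importance_effects <- function(params, hist_t, hist_y, n_draws) {
  nu <- params$precision_nu
  cand <- draw_effects(n_draws, params)
  lw <- 0
  for (j in seq_along(hist_t)) {
    mu <- plogis(cand$alpha + cand$beta * hist_t[j])
    lw <- lw + dbeta(hist_y[j], mu * nu, (1 - mu) * nu, log = TRUE)
  }
  w <- exp(lw - max(lw))
  idx <- sample.int(n_draws, n_draws, replace = TRUE, prob = w)
  list(alpha = cand$alpha[idx], beta = cand$beta[idx])
}

# orthant probability of the futures under the importance predictive
# (direction-free: null futures are exchangeable with the predictive, so
# ">= observed" is used as for an increasing endpoint)
importance_joint_probability <- function(params, hist_t, hist_y, fut_t,
                                         fut_y, n_draws) {
  nu <- params$precision_nu
  eff <- importance_effects(params, hist_t, hist_y, n_draws)
  hit <- rep(TRUE, n_draws)
  for (j in seq_along(fut_t)) {
    mu <- plogis(eff$alpha + eff$beta * fut_t[j])
    hit <- hit & (rbeta(n_draws, mu * nu, (1 - mu) * nu) >= fut_y[j])
  }
  mean(hit)
}

#' Marginal coverage of central prediction intervals on held-out futures
#'
#' Simulates patients from a known generating model, holds out one future
#' visit per patient, builds each patient's predictive distribution from
#' their simulated history (importance-reweighted population draws), and
#' reports the fraction of held-out observations falling inside the
#' central `level` prediction interval. If the predictive machinery is
#' correct this fraction matches the nominal level up to Monte-Carlo
#' error.
#'
#' @param params A [model_parameters()] generating model.
#' @param n_patients Number of simulated patients.
#' @param level Nominal central interval level.
#' @param n_draws Predictive trajectory draws per patient.
#' @param seed Integer seed.
#' @param age_range,follow_up_range Baseline age (years) and follow-up
#'   (months) ranges sampled uniformly per patient.
#' @param horizon Months after the last history visit of the held-out
#'   future observation.
#' @return Coverage fraction with attributes `mc_se` and `n`.
#' @export
marginal_coverage_check <- function(params, n_patients = 5000,
                                    level = 0.95, n_draws = 4000,
                                    seed = 1L, age_range = c(0, 30),
                                    follow_up_range = c(12, 48),
                                    horizon = 2) {
  stopifnot(inherits(params, "model_parameters"), n_patients >= 1,
            level > 0, level < 1)
  set.seed(seed)
  nu <- params$precision_nu
  lo <- (1 - level) / 2
  inside <- logical(n_patients)
  for (i in seq_len(n_patients)) {
    eff <- draw_effects(1, params)
    tt <- visit_schedule(runif(1, age_range[1], age_range[2]),
                         runif(1, follow_up_range[1], follow_up_range[2]))
    mu_h <- plogis(eff$alpha + eff$beta * tt)
    y <- rbeta(length(tt), mu_h * nu, (1 - mu_h) * nu)
    tf <- max(tt) + horizon
    mu_f <- plogis(eff$alpha + eff$beta * tf)
    yf <- rbeta(1, mu_f * nu, (1 - mu_f) * nu)
    imp <- importance_effects(params, tt, y, n_draws)
    mu_p <- plogis(imp$alpha + imp$beta * tf)
    traj <- rbeta(n_draws, mu_p * nu, (1 - mu_p) * nu)
    q <- stats::quantile(traj, c(lo, 1 - lo), names = FALSE)
    inside[i] <- yf >= q[1] && yf <= q[2]
  }
  p <- mean(inside)
  structure(p, mc_se = sqrt(p * (1 - p) / n_patients), n = n_patients)
}

#' Simulate null trials (responder counts under no treatment effect)
#'
#' Simulates the number of responders among `n_patients` when every
#' patient merely follows their natural visit-to-visit variability.
#' Two modes:
#' \describe{
#'   \item{`"shortcut"`}{responder indicators are Bernoulli with the
#'     per-patient null responder rate `null_prob`; counts are Binomial.
#'     By default `null_prob` is estimated from the full pipeline via
#'     [estimate_null_responder_rate()] (when `params` is supplied) or set
#'     to the analytic independence rate [null_responder_rate()]. Note the
#'     rule's true null rate is far above the nominal cut-off: the joint
#'     tail statistic is not uniform under the null.}
#'   \item{`"full"`}{each patient is simulated through the entire pipeline
#'     (history, importance predictive, joint probability, responder
#'     call). Slower; used at reduced `n_sim` to validate the shortcut.}
#' }
#'
#' @param design A [trial_design()].
#' @param n_sim Number of simulated trials.
#' @param seed Integer seed.
#' @param mode `"shortcut"` or `"full"`.
#' @param null_prob Per-patient null responder probability for the
#'   shortcut; if `NULL`, estimated or computed as described above.
#' @param params A [model_parameters()] generating model (required for
#'   `mode = "full"`, used for rate estimation in `"shortcut"` when given).
#' @param n_draws Predictive draws per patient in full mode (and in rate
#'   estimation).
#' @param n_rate_patients Patients used to estimate `null_prob` in
#'   shortcut mode when `params` is supplied.
#' @return An object of class `null_trials`: integer responder counts with
#'   fields `n`, `mode`, `null_prob`, `seed`.
#' @export
simulate_null_trials <- function(design = trial_design(), n_sim = 10000,
                                 seed = 1L, mode = c("shortcut", "full"),
                                 null_prob = NULL, params = NULL,
                                 n_draws = 4000, n_rate_patients = 2000) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "trial_design"), n_sim >= 1)
  n <- design$n_patients
  if (mode == "shortcut") {
    if (is.null(null_prob)) {
      null_prob <- if (!is.null(params)) {
        as.numeric(estimate_null_responder_rate(
          params, design, n_patients = n_rate_patients, n_draws = n_draws,
          seed = seed + 1L))
      } else {
        null_responder_rate(design)
      }
    }
    set.seed(seed)
    counts <- stats::rbinom(n_sim, n, null_prob)
  } else {
    if (is.null(params))
      stop("`params` (a generating model) is required for mode = 'full'")
    set.seed(seed)
    nu <- params$precision_nu
    k <- design$n_future_visits
    counts <- integer(n_sim)
    for (s in seq_len(n_sim)) {
      resp <- 0L
      for (i in seq_len(n)) {
        eff <- draw_effects(1, params)
        tt <- visit_schedule(runif(1, 0, 30), runif(1, 12, 48))
        mu_h <- plogis(eff$alpha + eff$beta * tt)
        y <- rbeta(length(tt), mu_h * nu, (1 - mu_h) * nu)
        tf <- max(tt) + 2 * seq_len(k)
        mu_f <- plogis(eff$alpha + eff$beta * tf)
        yf <- rbeta(k, mu_f * nu, (1 - mu_f) * nu)
        jp <- importance_joint_probability(params, tt, y, tf, yf, n_draws)
        resp <- resp + (jp <= design$responder_cutoff)
      }
      counts[s] <- resp
    }
    null_prob <- mean(counts) / n
  }
  structure(counts, class = "null_trials", n = n, mode = mode,
            null_prob = null_prob, seed = as.integer(seed))
}

#' @export
print.null_trials <- function(x, ...) {
  cat(sprintf(
    "<null_trials> %d %s-mode trials of n = %d; per-patient null rate %.4f; mean count %.3f\n",
    length(x), attr(x, "mode"), attr(x, "n"), attr(x, "null_prob"),
    mean(unclass(x))))
  invisible(x)
}

#' Conjugate beta posterior of the response rate
#'
#' With a `Beta(a, b)` prior on the response rate and `count` responders
#' out of `n`, the posterior is `Beta(a + count, b + n - count)`.
#'
#' @param count Number of responders (0 <= count <= n).
#' @param n Number of patients.
#' @param prior Length-2 beta shape pair (default uniform).
#' @return An object of class `beta_dist` with fields `shape1`, `shape2`.
#' @export
posterior_responder_rate <- function(count, n, prior = c(1, 1)) {
  stopifnot(count >= 0, count <= n, length(prior) == 2L, all(prior > 0))
  beta_dist(prior[1] + count, prior[2] + n - count)
}

#' Beta and degenerate rate distributions
#'
#' Light containers used for the observed-rate posterior and the null-rate
#' reference distribution.
#'
#' @param shape1,shape2 Beta shapes (> 0).
#' @return An object of class `beta_dist`.
#' @export
beta_dist <- function(shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  structure(list(shape1 = shape1, shape2 = shape2),
            class = c("beta_dist", "rate_dist"))
}

#' @rdname beta_dist
#' @param value Point mass location in \[0, 1\].
#' @export
degenerate_dist <- function(value) {
  stopifnot(value >= 0, value <= 1)
  structure(list(value = value), class = c("degenerate_dist", "rate_dist"))
}

#' @export
print.beta_dist <- function(x, ...) {
  cat(sprintf("<beta_dist> Beta(%.4g, %.4g), mean %.4g\n",
              x$shape1, x$shape2, x$shape1 / (x$shape1 + x$shape2)))
  invisible(x)
}

#' @export
print.degenerate_dist <- function(x, ...) {
  cat(sprintf("<degenerate_dist> point mass at %.4g\n", x$value))
  invisible(x)
}

rate_sample <- function(dist, n) {
  if (inherits(dist, "beta_dist")) rbeta(n, dist$shape1, dist$shape2)
  else rep(dist$value, n)
}

#' Fit the null response-rate reference distribution
#'
#' The trial's decision compares the observed-rate posterior to a
#' reference distribution of the response rate under no treatment effect.
#' The default fits a beta distribution by moments to the simulated null
#' trial response rates; a degenerate point mass at the per-patient null
#' rate is available as an alternative.
#'
#' @param null_trials A [simulate_null_trials()] result.
#' @param method `"moments"` (beta fitted to the simulated null rates) or
#'   `"degenerate"` (point mass at the per-patient null rate).
#' @return A `rate_dist` object.
#' @export
fit_null_rate_distribution <- function(null_trials,
                                       method = c("moments", "degenerate")) {
  method <- match.arg(method)
  stopifnot(inherits(null_trials, "null_trials"))
  n <- attr(null_trials, "n")
  rates <- unclass(null_trials) / n
  if (method == "degenerate") return(degenerate_dist(mean(rates)))
  m <- mean(rates); v <- stats::var(rates)
  if (m <= 0 || m >= 1 || v <= 0 || v >= m * (1 - m))
    stop("moment fit impossible (rate mean ", format(m),
         ", variance ", format(v), "); use method = 'degenerate'")
  nu <- m * (1 - m) / v - 1
  beta_dist(m * nu, (1 - m) * nu)
}

#' Posterior probability that the observed rate exceeds the null rate
#'
#' Monte-Carlo estimate of `P(p_obs - p_null > 0)` with independent draws
#' from the observed-rate posterior and the null-rate reference
#' distribution. This probability is the trial's decision statistic.
#'
#' @param observed A `rate_dist` (typically [posterior_responder_rate()]).
#' @param null A `rate_dist` (typically [fit_null_rate_distribution()]).
#' @param n_mc Monte-Carlo sample size.
#' @param seed Integer seed.
#' @return Probability in \[0, 1\] with attribute `mc_se`.
#' @export
prob_rate_difference_positive <- function(observed, null, n_mc = 100000,
                                          seed = 1L) {
  stopifnot(inherits(observed, "rate_dist"), inherits(null, "rate_dist"))
  set.seed(seed)
  p_obs <- rate_sample(observed, n_mc)
  p_null <- rate_sample(null, n_mc)
  p <- mean(p_obs > p_null)
  structure(p, mc_se = sqrt(p * (1 - p) / n_mc))
}

#' Calibrate the trial's decision threshold to the Type I error bound
#'
#' The trial declares success when the posterior probability that the
#' observed response rate exceeds the null rate is above a threshold `c`.
#' This function finds the smallest `c` on a grid (step
#' `design$threshold_grid_step`) such that the estimated probability of
#' success over null-simulated trials is at most `alpha`. Because the
#' decision statistic is monotone in the responder count, the per-count
#' probabilities are computed once and reused.
#'
#' @param null_trials A [simulate_null_trials()] result (>= 1000 trials
#'   recommended).
#' @param design A [trial_design()].
#' @param alpha Overall Type I bound; defaults to `design$alpha`.
#' @param rate_dist Null-rate reference distribution; default fitted by
#'   [fit_null_rate_distribution()] from `null_trials`.
#' @param n_mc Monte-Carlo size for each per-count probability.
#' @param seed Integer seed for the probability estimates.
#' @param method `"mc"` (Monte-Carlo, the default) or `"exact"`
#'   (numerical integration of the beta densities, used for
#'   cross-checking).
#' @return An object of class `trial_calibration`: `threshold`,
#'   `type1_estimate` (on the calibration sample), `prob_by_count`,
#'   `rate_dist`, `design`, `alpha`, `seed`.
#' @export
calibrate_threshold <- function(null_trials, design = trial_design(),
                                alpha = design$alpha, rate_dist = NULL,
                                n_mc = 100000, seed = 1L,
                                method = c("mc", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(null_trials, "null_trials"),
            inherits(design, "trial_design"), alpha > 0, alpha <= 1)
  n <- attr(null_trials, "n")
  if (n != design$n_patients)
    stop("null trials were simulated for n = ", n,
         " but the design has n = ", design$n_patients)
  if (is.null(rate_dist)) rate_dist <- fit_null_rate_distribution(null_trials)
  prob_by_count <- decision_prob_by_count(n, design$rate_prior, rate_dist,
                                          n_mc, seed, method)
  grid <- seq(design$threshold_grid_step, 1 - design$threshold_grid_step,
              by = design$threshold_grid_step)
  counts <- unclass(null_trials)
  type1 <- vapply(grid, function(c)
    mean(prob_by_count[counts + 1L] > c), numeric(1))
  ok <- which(type1 <= alpha)
  if (length(ok) == 0L)
    stop(sprintf(
      "no grid threshold attains Type I <= %g; achievable minimum is %g at threshold %g",
      alpha, min(type1), grid[which.min(type1)]))
  i <- min(ok)
  structure(
    list(threshold = grid[i], type1_estimate = type1[i],
         prob_by_count = prob_by_count, rate_dist = rate_dist,
         design = design, alpha = alpha, n_sim = length(counts),
         null_prob = attr(null_trials, "null_prob"),
         seed = as.integer(seed), method = method),
    class = "trial_calibration")
}

# decision statistic per possible responder count 0..n
decision_prob_by_count <- function(n, rate_prior, rate_dist, n_mc, seed,
                                   method = "mc") {
  vapply(0:n, function(k) {
    post <- posterior_responder_rate(k, n, rate_prior)
    if (method == "mc") {
      as.numeric(prob_rate_difference_positive(post, rate_dist, n_mc,
                                               seed = seed + k))
    } else {
      if (inherits(rate_dist, "degenerate_dist")) {
        stats::pbeta(rate_dist$value, post$shape1, post$shape2,
                     lower.tail = FALSE)
      } else {
        stats::integrate(function(y)
          dbeta(y, post$shape1, post$shape2) *
            stats::pbeta(y, rate_dist$shape1, rate_dist$shape2),
          0, 1, rel.tol = 1e-10)$value
      }
    }
  }, numeric(1))
}

#' @export
print.trial_calibration <- function(x, ...) {
  cat(sprintf(
    "<trial_calibration> threshold %.2f (grid %.2g) -> estimated Type I %.4f <= alpha %.2f\n",
    x$threshold, x$design$threshold_grid_step, x$type1_estimate, x$alpha))
  cat(sprintf("  %d null trials, per-patient null rate %.4f, decision rule: success iff P(rate difference > 0) > %.2f\n",
              x$n_sim, x$null_prob, x$threshold))
  invisible(x)
}

#' Estimate the Type I error of a calibrated rule on fresh null trials
#'
#' @param calibration A [calibrate_threshold()] result.
#' @param null_trials Fresh [simulate_null_trials()] counts (independent
#'   seed).
#' @return Rejection rate with attribute `mc_se`.
#' @export
type1_error <- function(calibration, null_trials) {
  stopifnot(inherits(calibration, "trial_calibration"),
            inherits(null_trials, "null_trials"))
  counts <- unclass(null_trials)
  p <- mean(calibration$prob_by_count[counts + 1L] > calibration$threshold)
  structure(p, mc_se = sqrt(p * (1 - p) / length(counts)))
}

#' Assurance (expected power) curve of the calibrated design
#'
#' For each responder-rate increase `delta` on a grid, simulates trials in
#' which each patient responds with probability `null rate + delta`
#' (clipped at 1 with a warning), applies the calibrated decision rule,
#' and records the success fraction. A separate curve is computed for each
#' sample size in `n_set`, each with its own threshold calibrated to the
#' design's Type I bound, so the assurance at `delta = 0` is that design's
#' Type I error estimate.
#'
#' @param design A [trial_design()] (its `n_patients` is replaced by each
#'   element of `n_set` in turn).
#' @param effect_grid Responder-rate increases over the null rate.
#' @param n_set Sample sizes to compute curves for (default 12 and 24).
#' @param null_prob Per-patient null responder rate; if `NULL`, estimated
#'   from `params` when given, else the analytic independence rate.
#' @param params Optional [model_parameters()] for rate estimation.
#' @param n_sim Simulated trials per grid point (and for calibration).
#' @param seed Integer seed.
#' @return An object of class `trial_oc`: a list with `curve` (data frame
#'   `delta`, `n`, `power`), `calibrations` (per sample size),
#'   `type1_error`, `n_sim`, `seed`.
#' @export
assurance_curve <- function(design = trial_design(),
                            effect_grid = seq(0, 0.6, by = 0.05),
                            n_set = c(12, 24), null_prob = NULL,
                            params = NULL, n_sim = 10000, seed = 1L) {
  stopifnot(inherits(design, "trial_design"), all(effect_grid >= 0))
  if (is.null(null_prob)) {
    null_prob <- if (!is.null(params)) {
      as.numeric(estimate_null_responder_rate(params, design,
                                              seed = seed + 17L))
    } else {
      null_responder_rate(design)
    }
  }
  calibrations <- list(); rows <- list(); r <- 0L
  for (n in n_set) {
    des_n <- design; des_n$n_patients <- as.integer(n)
    nulls <- simulate_null_trials(des_n, n_sim = n_sim, seed = seed,
                                  null_prob = null_prob)
    cal <- calibrate_threshold(nulls, des_n, seed = seed)
    calibrations[[as.character(n)]] <- cal
    for (delta in effect_grid) {
      p_eff <- null_prob + delta
      if (p_eff > 1) {
        warning(sprintf(
          "responder probability %.3f clipped to 1 (delta = %g)", p_eff,
          delta), call. = FALSE)
        p_eff <- 1
      }
      if (delta == 0) {
        # the null grid point reuses the calibration trials, so the curve
        # at zero effect is exactly the design's Type I estimate
        counts <- unclass(nulls)
      } else {
        set.seed(seed + 1000L * n + round(10000 * delta))
        counts <- stats::rbinom(n_sim, n, p_eff)
      }
      success <- mean(cal$prob_by_count[counts + 1L] > cal$threshold)
      r <- r + 1L
      rows[[r]] <- data.frame(delta = delta, n = n, power = success)
    }
  }
  curve <- do.call(rbind, rows)
  structure(
    list(curve = curve, calibrations = calibrations,
         type1_error = vapply(calibrations, function(c) c$type1_estimate,
                              numeric(1)),
         null_prob = null_prob, n_sim = n_sim, seed = as.integer(seed)),
    class = "trial_oc")
}

#' @export
print.trial_oc <- function(x, ...) {
  cat("<trial_oc> assurance curves\n")
  for (n in names(x$calibrations)) {
    cal <- x$calibrations[[n]]
    cat(sprintf("  n = %s: threshold %.2f, Type I %.4f\n",
                n, cal$threshold, cal$type1_estimate))
  }
  sub <- x$curve[x$curve$delta %in% range(x$curve$delta), ]
  print(sub, row.names = FALSE)
  invisible(x)
}

#' Write operating characteristics to CSV and JSON
#'
#' @param oc A [assurance_curve()] result.
#' @param csv_path Path for the curve CSV (`delta`, `n`, `power`).
#' @param json_path Path for the summary JSON (thresholds, Type I
#'   estimates, seeds, simulation sizes).
#' @return `csv_path`, invisibly.
#' @export
write_operating_characteristics <- function(oc, csv_path, json_path) {
  stopifnot(inherits(oc, "trial_oc"))
  utils::write.csv(oc$curve, csv_path, row.names = FALSE)
  summary <- list(
    thresholds = lapply(oc$calibrations, function(c) c$threshold),
    type1 = as.list(oc$type1_error),
    null_prob = oc$null_prob, n_sim = oc$n_sim, seed = oc$seed)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
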