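#' Configuration of a synthetic natural-history cohort
#'
#' Describes a cohort with the structure of the NatHis-CNM natural-history
#' study: 44 *MTM1* and 15 *DNM2* patients distributed over baseline-age
#' strata 0-2, 2-6, 6-16 and >16 years, with heterogeneous follow-up.
#' Scores are generated from the hierarchical beta/logit model.
#'
#' @param n_mtm1,n_dnm2 Patient counts per genotype (defaults 44 and 15).
#' @param age_strata Named list with one integer vector per genotype giving
#'   counts in the four baseline-age strata `0-2`, `2-6`, `6-16`, `>16`.
#'   Counts must sum to the genotype totals. The default, `NULL`,
#'   allocates the totals proportionally to the study's composition
#'   (MTM1 12/10/13/9, DNM2 0/1/1/13) by largest remainder, which
#'   reproduces those counts exactly at the default cohort size.
#' @param sex_counts Named list per genotype, `c(M =, F =)`; `NULL`
#'   allocates proportionally to the study's 41/3 (MTM1) and 6/9 (DNM2).
#' @param follow_up_range Range in months from which each patient's
#'   follow-up is drawn uniformly; default 12-48 months (some patients were
#'   followed one year, some four).
#' @param adult_age_max Upper bound in years used when sampling baseline
#'   ages in the open-ended `>16` stratum.
#' @param generating_params A [model_parameters()] object used as the data
#'   generator.
#' @param endpoint An [endpoint_spec()]; default FEV1 percent predicted.
#' @param seed Integer seed for [simulate_cohort()].
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_mtm1 = 44, n_dnm2 = 15,
                          age_strata = NULL, sex_counts = NULL,
                          follow_up_range = c(12, 48),
                          adult_age_max = 45,
                          generating_params = model_parameters(),
                          endpoint = endpoint_fev1(),
                          seed = 1L) {
  stopifnot(n_mtm1 >= 0, n_dnm2 >= 0, n_mtm1 + n_dnm2 >= 1,
            inherits(generating_params, "model_parameters"),
            inherits(endpoint, "endpoint_spec"),
            length(follow_up_range) == 2L, follow_up_range[1] >= 0,
            follow_up_range[1] <= follow_up_range[2])
  totals <- c(MTM1 = n_mtm1, DNM2 = n_dnm2)
  ref_strata <- list(MTM1 = c(`0-2` = 12, `2-6` = 10, `6-16` = 13, `>16` = 9),
                     DNM2 = c(`0-2` = 0, `2-6` = 1, `6-16` = 1, `>16` = 13))
  ref_sex <- list(MTM1 = c(M = 41, F = 3), DNM2 = c(M = 6, F = 9))
  if (is.null(age_strata))
    age_strata <- lapply(stats::setNames(nm = names(totals)), function(g)
      largest_remainder(totals[[g]], ref_strata[[g]]))
  if (is.null(sex_counts))
    sex_counts <- lapply(stats::setNames(nm = names(totals)), function(g)
      largest_remainder(totals[[g]], ref_sex[[g]]))
  for (g in names(totals)) {
    st <- age_strata[[g]]
    if (length(st) != 4L || any(st < 0) || sum(st) != totals[[g]])
      stop(sprintf("age strata for %s must be 4 non-negative counts summing to %d",
                   g, totals[[g]]))
    sx <- sex_counts[[g]]
    if (sum(sx) != totals[[g]])
      stop(sprintf("sex counts for %s must sum to %d", g, totals[[g]]))
  }
  structure(
    list(n_mtm1 = n_mtm1, n_dnm2 = n_dnm2, age_strata = age_strata,
         sex_counts = sex_counts, follow_up_range = follow_up_range,
         adult_age_max = adult_age_max,
         generating_params = generating_params, endpoint = endpoint,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Age-dependent visit schedule
#'
#' Natural-history visits occur every 3 months while the patient is under 2
#' years of age, every 6 months between ages 2 and 6, and for patients over
#' 6 at months 6 and 12 after enrolment and then once a year. The spacing
#' follows the patient's age at each visit, so a child crossing an age
#' threshold during follow-up switches regime.
#'
#' @param baseline_age_years Age in years at the first visit (>= 0).
#' @param follow_up_months Total follow-up in months (>= 0).
#' @return Numeric vector of visit times in months, starting at 0.
#' @examples
#' visit_schedule(10, 26)  # 0, 6, 12, 24
#' visit_schedule(1, 9)    # 0, 3, 6, 9
#' @export
visit_schedule <- function(baseline_age_years, follow_up_months) {
  stopifnot(is.numeric(baseline_age_years), is.numeric(follow_up_months),
            length(baseline_age_years) == 1L, length(follow_up_months) == 1L,
            baseline_age_years >= 0)
  if (follow_up_months < 0) stop("`follow_up_months` must be non-negative")
  times <- 0
  t <- 0
  repeat {
    age <- baseline_age_years + t / 12
    step <- if (age < 2) 3 else if (age < 6) 6 else if (t < 12) 6 else 12
    t <- t + step
    if (t > follow_up_months) break
    times <- c(times, t)
  }
  times
}

#' Simulate a synthetic natural-history cohort
#'
#' Draws per-patient random effects `(alpha_i, beta_i)` from the bivariate
#' normal population distribution, builds each patient's visit schedule from
#' their baseline age and follow-up, and generates bounded scores
#' `y_ij ~ Beta(mu_ij * nu, (1 - mu_ij) * nu)` with `mu_ij` given by
#' [logit_mean()]. The time-centering constant is set from the realised
#' visit times.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A [longitudinal_dataset()] whose `patients` table carries the
#'   realised `alpha`/`beta` effects as extra columns (useful for parameter
#'   recovery and oracle checks).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  p <- config$generating_params
  strata_bounds <- list(`0-2` = c(0, 2), `2-6` = c(2, 6),
                        `6-16` = c(6, 16), `>16` = c(16, config$adult_age_max))
  pats <- list(); obs <- list(); k <- 0L
  for (g in c("MTM1", "DNM2")) {
    st <- config$age_strata[[g]]
    sexes <- sample(rep(names(config$sex_counts[[g]]),
                        times = config$sex_counts[[g]]))
    gi <- 0L
    for (s in names(st)) {
      if (st[[s]] == 0) next
      b <- strata_bounds[[s]]
      for (j in seq_len(st[[s]])) {
        k <- k + 1L; gi <- gi + 1L
        id <- sprintf("%s-%02d", g, gi)
        age0 <- runif(1, b[1], b[2])
        fu <- runif(1, config$follow_up_range[1], config$follow_up_range[2])
        eff <- draw_effects(1, p)
        tt <- visit_schedule(age0, fu)
        mu <- logit_mean(eff$alpha, eff$beta, 0, tt)  # centred later
        y <- rbeta(length(tt), mu * p$precision_nu, (1 - mu) * p$precision_nu)
        pats[[k]] <- data.frame(patient_id = id, genotype = g, sex = sexes[gi],
                                baseline_age = age0, alpha = eff$alpha,
                                beta = eff$beta, stringsAsFactors = FALSE)
        obs[[k]] <- data.frame(patient_id = id, time_months = tt,
                               age_years = age0 + tt / 12,
                               raw_value = unscale_score(y, config$endpoint),
                               scaled_value = y, stringsAsFactors = FALSE)
      }
    }
  }
  observations <- do.call(rbind, obs)
  patients <- do.call(rbind, pats)
  # the generator's chi uses T = 0; re-centre by shifting alpha so that the
  # stored dataset uses T = -mean(t) with identical trajectories
  Tc <- -mean(observations$time_months)
  patients$alpha <- patients$alpha - patients$beta * Tc
  longitudinal_dataset(observations, patients, config$endpoint,
                       centering_constant = Tc)
}

# draw n random-effect pairs from the population distribution
draw_effects <- function(n, params) {
  sa <- params$re_sd_intercept; sb <- params$re_sd_slope
  rho <- params$re_correlation
  z1 <- rnorm(n); z2 <- rnorm(n)
  alpha <- params$pop_intercept + sa * z1
  beta <- params$pop_slope + sb * (rho * z1 + sqrt(1 - rho^2) * z2)
  list(alpha = alpha, beta = beta)
}

#' Treatment-effect specification
#'
#' Parameterises a hypothetical treatment as a step change of the logit
#' intercept at the time of intervention plus a change in slope from that
#' time onwards. The null (no treatment) is the zero-shift specification.
#'
#' @param intercept_shift Step on the logit scale applied from `onset_time`.
#' @param slope_shift Additional slope on the logit scale per month,
#'   accruing with time since `onset_time`.
#' @param onset_time Months (on the patient's visit time scale) at which
#'   the intervention starts; must be >= 0.
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(intercept_shift = 0, slope_shift = 0,
                             onset_time = 0) {
  stopifnot(is.finite(intercept_shift), is.finite(slope_shift),
            is.finite(onset_time))
  if (onset_time < 0) stop("`onset_time` must be non-negative")
  structure(list(intercept_shift = intercept_shift,
                 slope_shift = slope_shift, onset_time = onset_time),
            class = "treatment_effect")
}

#' Simulate future observations for given patient effects
#'
#' Generates observations at the requested future times from the same
#' beta/logit law that generated the history, optionally perturbed by a
#' [treatment_effect()]: from `onset_time` the linear predictor gains
#' `intercept_shift + slope_shift * (t - onset_time)`. With a zero-effect
#' specification this is exactly the null generator.
#'
#' @param alpha,beta Patient effects on the logit scale.
#' @param times Numeric vector of future times in months (same scale as the
#'   patient's visit times); may be empty.
#' @param params A [model_parameters()] supplying `precision_nu`.
#' @param effect A [treatment_effect()]; default none.
#' @param T_center Centering constant of the fitted/generating model.
#' @param seed Optional integer seed.
#' @return Numeric vector of simulated scaled observations, one per time.
#' @export
simulate_future <- function(alpha, beta, times, params,
                            effect = treatment_effect(), T_center = 0,
                            seed = NULL) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(effect, "treatment_effect"))
  if (length(times) == 0L) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  chi <- alpha + beta * (T_center + times)
  post <- times >= effect$onset_time
  chi[post] <- chi[post] + effect$intercept_shift +
    effect$slope_shift * (times[post] - effect$onset_time)
  mu <- plogis(chi)
  rbeta(length(times), mu * params$precision_nu,
        (1 - mu) * params$precision_nu)
}

# integer allocation of n proportional to reference weights
largest_remainder <- function(n, ref) {
  if (sum(ref) == 0 || n == 0) {
    out <- ref * 0
  } else {
    quota <- n * ref / sum(ref)
    out <- floor(quota)
    left <- n - sum(out)
    if (left > 0) {
      bump <- order(quota - out, decreasing = TRUE)[seq_len(left)]
      out[bump] <- out[bump] + 1
    }
  }
  stats::setNames(as.integer(out), names(ref))
}
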