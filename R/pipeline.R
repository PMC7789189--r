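#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], optionally
#' overridden from a YAML file and/or by name. The configuration controls
#' the synthetic cohort (or an input CSV), the endpoint, the MCMC run, the
#' predictive settings, the trial design and the simulation sizes, plus
#' the seed from which all randomness flows.
#'
#' @param path Optional YAML file; entries override the defaults.
#' @param ... Named top-level overrides applied after the file.
#' @return A nested configuration list of class `run_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  config <- list(
    seed = 1L,
    output_dir = "cnmbayes-run",
    input_csv = NULL,
    endpoint = list(name = "FEV1", lower_bound = 0, upper_bound = 100,
                    improvement_direction = "increase",
                    relevance_margin = 8),
    cohort = list(n_mtm1 = 44, n_dnm2 = 15),
    model = list(n_chains = 2, n_iter = 1000, n_adapt = 400, n_burn = 400),
    predict = list(future_offsets = c(2, 4, 6), n_draws = 4000),
    design = list(n_patients = 12, n_future_visits = 3,
                  responder_cutoff = 0.01, alpha = 0.05),
    trial = list(n_sim = 10000, n_rate_patients = 1000,
                 effect_grid = seq(0, 0.6, by = 0.1), n_set = c(12, 24)),
    stages = c("simulate", "fit", "predict", "call", "calibrate", "assure"),
    verbose = TRUE)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    config <- utils::modifyList(config, user)
  }
  dots <- list(...)
  if (length(dots)) config <- utils::modifyList(config, dots)
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow: simulate (or read) a longitudinal
#' dataset, fit the progression model, derive per-patient predictive
#' distributions, call responders on (simulated null) post-treatment
#' observations, calibrate the trial decision threshold from the fitted
#' model, and compute assurance curves. Stages execute in the fixed order
#' above; requesting a stage whose prerequisite is absent is an error
#' naming the stage. Every artifact directory is stamped with the seed and
#' an MD5 hash of the configuration, and a rerun with the same
#' configuration reproduces the summary files.
#'
#' @param config A `run_config` from [pipeline_config()], or a path to a
#'   YAML file.
#' @return Invisibly, a list with the in-memory results of the executed
#'   stages (`dataset`, `fit`, `predictives`, `calls`, `calibration`,
#'   `oc`) and `artifacts` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(config$stages,
                      c("simulate", "fit", "predict", "call", "calibrate",
                        "assure"), several.ok = TRUE)
  # stage -> c(state field it needs, stage that provides it)
  deps <- list(fit = c("dataset", "simulate"),
               predict = c("fit", "fit"),
               call = c("predictives", "predict"),
               calibrate = c("fit", "fit"),
               assure = c("calibration", "calibrate"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$output_dir, name)

  ep <- do.call(endpoint_spec, config$endpoint)
  design <- do.call(trial_design, config$design)
  state <- list(artifacts = character(0))
  need <- function(stage) {
    d <- deps[[stage]]
    if (!is.null(d) && is.null(state[[d[1]]]))
      stop(sprintf("stage '%s' requires '%s' to have run first", stage,
                   if (d[2] == "simulate") "simulate (or input_csv)" else d[2]))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      if (!is.null(config$input_csv)) {
        say("simulate: reading %s", config$input_csv)
        state$dataset <- read_longitudinal_csv(config$input_csv, ep)
      } else {
        cfg <- cohort_config(n_mtm1 = config$cohort$n_mtm1,
                             n_dnm2 = config$cohort$n_dnm2,
                             endpoint = ep, seed = config$seed)
        state$dataset <- simulate_cohort(cfg)
        say("simulate: %d patients, %d observations (seed %d)",
            nrow(state$dataset$patients),
            nrow(state$dataset$observations), config$seed)
      }
      write_longitudinal_csv(state$dataset, art("cohort.csv"))
      state$artifacts <- c(state$artifacts, art("cohort.csv"))
    } else if (stage == "fit") {
      need("fit")
      m <- config$model
      say("fit: %d chains x %d iterations", m$n_chains, m$n_iter)
      state$fit <- suppressWarnings(fit_mcmc(
        state$dataset, n_chains = m$n_chains, n_iter = m$n_iter,
        n_adapt = m$n_adapt, n_burn = m$n_burn, seed = config$seed))
      if (!state$fit$converged)
        say("fit: convergence flag raised (see draws.json diagnostics)")
      write_draws(state$fit, art("draws.csv"))
      check <- posterior_fit_check(state$fit, seed = config$seed)
      utils::write.csv(check$fitted, art("fit_check.csv"),
                       row.names = FALSE)
      state$artifacts <- c(state$artifacts, art("draws.csv"),
                           art("fit_check.csv"))
    } else if (stage == "predict") {
      need("predict")
      p <- config$predict
      state$predictives <- list(); ivals <- list()
      for (id in state$fit$patient_ids) {
        last <- max(state$dataset$observations$time_months[
          state$dataset$observations$patient_id == id])
        ft <- last + p$future_offsets
        pred <- predict_individual(state$fit, id, ft,
                                   n_draws = p$n_draws,
                                   seed = config$seed)
        state$predictives[[id]] <- pred
        iv <- prediction_intervals(pred, 0.95)
        iv$patient_id <- id
        ivals[[id]] <- iv
      }
      utils::write.csv(do.call(rbind, ivals),
                       art("predictive_intervals.csv"), row.names = FALSE)
      state$artifacts <- c(state$artifacts, art("predictive_intervals.csv"))
      say("predict: %d patients at offsets %s months",
          length(state$predictives),
          paste(p$future_offsets, collapse = ", "))
    } else if (stage == "call") {
      need("call")
      # post-treatment observations: null futures from the simulated truth
      pat <- state$dataset$patients
      if (!all(c("alpha", "beta") %in% names(pat)))
        stop("stage 'call' needs simulated data with known effects, or supply observed futures")
      gen <- do.call(model_parameters, config$generating %||% list())
      calls <- list()
      set.seed(config$seed + 7L)
      for (id in names(state$predictives)) {
        pred <- state$predictives[[id]]
        i <- match(id, pat$patient_id)
        yf <- simulate_future(pat$alpha[i], pat$beta[i], pred$future_times,
                              gen, T_center = state$fit$centering_constant)
        jp <- joint_improvement_probability(pred, yf,
                                            ep$improvement_direction)
        obs <- state$dataset$observations
        y_last <- obs$raw_value[obs$patient_id == id][
          which.max(obs$time_months[obs$patient_id == id])]
        change <- unscale_score(yf[length(yf)], ep) - y_last
        rc <- call_responder(jp, change, design, ep)
        calls[[id]] <- data.frame(patient_id = id,
                                  joint_probability = rc$joint_probability,
                                  is_responder = rc$is_responder,
                                  clinically_relevant = rc$clinically_relevant,
                                  observed_change = rc$observed_change)
      }
      state$calls <- do.call(rbind, calls)
      utils::write.csv(state$calls, art("responder_calls.csv"),
                       row.names = FALSE)
      state$artifacts <- c(state$artifacts, art("responder_calls.csv"))
      say("call: %d/%d responders at cutoff %g",
          sum(state$calls$is_responder), nrow(state$calls),
          design$responder_cutoff)
    } else if (stage == "calibrate") {
      need("calibrate")
      # null responder rate under the fitted model (posterior means)
      pm <- colMeans(state$fit$pop)
      fitted_params <- model_parameters(
        pop_intercept = pm["pop_intercept"], pop_slope = pm["pop_slope"],
        re_sd_intercept = pm["re_sd_intercept"],
        re_sd_slope = pm["re_sd_slope"],
        re_correlation = pm["re_correlation"],
        precision_nu = pm["precision_nu"])
      tr <- config$trial
      rate <- estimate_null_responder_rate(
        fitted_params, design, n_patients = tr$n_rate_patients,
        seed = config$seed + 11L)
      nulls <- simulate_null_trials(design, n_sim = tr$n_sim,
                                    seed = config$seed + 13L,
                                    null_prob = as.numeric(rate))
      state$calibration <- calibrate_threshold(nulls, design,
                                               seed = config$seed + 13L)
      state$fitted_params <- fitted_params
      jsonlite::write_json(
        list(threshold = state$calibration$threshold,
             type1_estimate = state$calibration$type1_estimate,
             null_responder_rate = as.numeric(rate),
             responder_cutoff = design$responder_cutoff,
             alpha = design$alpha, n_patients = design$n_patients,
             n_sim = tr$n_sim, seed = config$seed),
        art("calibration.json"), auto_unbox = TRUE, digits = NA)
      state$artifacts <- c(state$artifacts, art("calibration.json"))
      say("calibrate: threshold %.2f, Type I %.4f (alpha %g, cutoff %g, n %d)",
          state$calibration$threshold, state$calibration$type1_estimate,
          design$alpha, design$responder_cutoff, design$n_patients)
    } else if (stage == "assure") {
      need("assure")
      tr <- config$trial
      state$oc <- assurance_curve(design, effect_grid = tr$effect_grid,
                                  n_set = tr$n_set,
                                  null_prob = state$calibration$null_prob,
                                  n_sim = tr$n_sim,
                                  seed = config$seed + 13L)
      write_operating_characteristics(state$oc, art("assurance.csv"),
                                      art("assurance.json"))
      state$artifacts <- c(state$artifacts, art("assurance.csv"),
                           art("assurance.json"))
      say("assure: curves for n = %s", paste(tr$n_set, collapse = ", "))
    }
  }
  summary <- list(seed = config$seed, config_md5 = config_hash(config),
                  stages = stages, artifacts = state$artifacts)
  jsonlite::write_json(summary, art("run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable MD5 of a configuration (via its YAML serialisation)
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}
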