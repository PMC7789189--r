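#' Longitudinal dataset of bounded clinical scores
#'
#' Container for per-visit observations of one bounded endpoint together
#' with per-patient metadata and the time-centering constant used by the
#' model. Observation times are in months since each patient's first visit.
#'
#' @param observations Data frame with columns `patient_id`, `time_months`,
#'   `age_years`, `raw_value`, `scaled_value`. Scaled values must lie
#'   strictly inside (0, 1); use [scale_score()] with a finite `n_obs`.
#' @param patients Data frame with columns `patient_id`, `genotype`
#'   (`"MTM1"` or `"DNM2"`), `sex` (`"M"`/`"F"`), `baseline_age` (years).
#' @param endpoint An [endpoint_spec()].
#' @param centering_constant Time-centering constant `T` in months. The
#'   default, `NULL`, sets `T = -mean(time_months)` so that `T + t` is
#'   centred at zero over the dataset.
#'
#' @return An object of class `cnm_data`.
#' @export
longitudinal_dataset <- function(observations, patients, endpoint,
                                 centering_constant = NULL) {
  stopifnot(is.data.frame(observations), is.data.frame(patients),
            inherits(endpoint, "endpoint_spec"))
  need_obs <- c("patient_id", "time_months", "age_years",
                "raw_value", "scaled_value")
  need_pat <- c("patient_id", "genotype", "sex", "baseline_age")
  if (!all(need_obs %in% names(observations)))
    stop("`observations` must have columns: ", paste(need_obs, collapse = ", "))
  if (!all(need_pat %in% names(patients)))
    stop("`patients` must have columns: ", paste(need_pat, collapse = ", "))
  observations$patient_id <- as.character(observations$patient_id)
  patients$patient_id <- as.character(patients$patient_id)
  if (nrow(observations) == 0L) stop("dataset has no observations")
  if (anyDuplicated(patients$patient_id))
    stop("duplicated patient ids in `patients`")
  if (!all(observations$patient_id %in% patients$patient_id))
    stop("observations refer to patients missing from `patients`")
  if (!all(patients$patient_id %in% observations$patient_id))
    stop("every patient must have at least one observation")
  if (any(observations$time_months < 0))
    stop("`time_months` must be non-negative")
  s <- observations$scaled_value
  if (any(!is.finite(s) | s <= 0 | s >= 1))
    stop("all scaled values must lie strictly inside (0, 1)")
  if (is.null(centering_constant))
    centering_constant <- -mean(observations$time_months)
  stopifnot(is.finite(centering_constant))
  structure(
    list(endpoint = endpoint,
         observations = observations[order(observations$patient_id,
                                           observations$time_months), ,
                                     drop = FALSE],
         patients = patients,
         centering_constant = centering_constant),
    class = "cnm_data")
}

#' @export
print.cnm_data <- function(x, ...) {
  tab <- table(x$patients$genotype)
  cat(sprintf("<cnm_data> %s: %d observations on %d patients (%s), T = %.2f months\n",
              x$endpoint$name, nrow(x$observations), nrow(x$patients),
              paste(sprintf("%d %s", as.integer(tab), names(tab)),
                    collapse = ", "),
              x$centering_constant))
  invisible(x)
}

#' @export
summary.cnm_data <- function(object, ...) {
  obs <- object$observations
  per_pat <- table(obs$patient_id)
  out <- list(
    endpoint = object$endpoint$name,
    n_patients = nrow(object$patients),
    n_observations = nrow(obs),
    visits_per_patient = summary(as.integer(per_pat)),
    follow_up_months = summary(tapply(obs$time_months, obs$patient_id, max)),
    raw_range = range(obs$raw_value),
    genotypes = table(object$patients$genotype))
  class(out) <- "summary.cnm_data"
  out
}

#' @export
print.summary.cnm_data <- function(x, ...) {
  cat(sprintf("%s dataset: %d patients, %d observations\n",
              x$endpoint, x$n_patients, x$n_observations))
  cat("visits per patient:\n"); print(x$visits_per_patient)
  cat("follow-up (months):\n"); print(x$follow_up_months)
  cat(sprintf("raw score range: [%g, %g]\n", x$raw_range[1], x$raw_range[2]))
  print(x$genotypes)
  invisible(x)
}

#' Restrict a dataset to a genotype and/or age class
#'
#' The model can be fit "by age class and by genotype" as independent fits
#' on filtered subsets; this helper performs the filtering. Age classes
#' refer to the age at baseline.
#'
#' @param dataset A [longitudinal_dataset()].
#' @param genotype Optional genotype to keep (`"MTM1"` or `"DNM2"`).
#' @param age_min,age_max Optional baseline-age window in years
#'   (`age_min <= age < age_max`).
#' @return A filtered `cnm_data` object.
#' @export
filter_dataset <- function(dataset, genotype = NULL,
                           age_min = NULL, age_max = NULL) {
  stopifnot(inherits(dataset, "cnm_data"))
  pat <- dataset$patients
  keep <- rep(TRUE, nrow(pat))
  if (!is.null(genotype)) keep <- keep & pat$genotype %in% genotype
  if (!is.null(age_min)) keep <- keep & pat$baseline_age >= age_min
  if (!is.null(age_max)) keep <- keep & pat$baseline_age < age_max
  if (!any(keep)) stop("no patients left after filtering")
  pat <- pat[keep, , drop = FALSE]
  obs <- dataset$observations
  obs <- obs[obs$patient_id %in% pat$patient_id, , drop = FALSE]
  longitudinal_dataset(obs, pat, dataset$endpoint)
}
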