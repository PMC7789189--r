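#' Read a longitudinal CSV into a dataset
#'
#' Reads the package's longitudinal dialect: a UTF-8, comma-separated file
#' with header `patient_id, genotype, sex, age_years, time_months,
#' endpoint, value`, one row per visit, '.' as decimal mark, times in
#' months and ages in years. Rows are validated with row-numbered
#' diagnostics: non-numeric fields, duplicate (patient, time, endpoint)
#' rows and values outside the endpoint bounds are rejected. Raw values
#' are scaled to (0, 1) with the boundary squeeze sized by the number of
#' observations read.
#'
#' @param path CSV file path.
#' @param endpoint An [endpoint_spec()]; only rows whose `endpoint` column
#'   matches `endpoint$name` are kept.
#' @return A [longitudinal_dataset()].
#' @export
read_longitudinal_csv <- function(path, endpoint = endpoint_fev1()) {
  stopifnot(inherits(endpoint, "endpoint_spec"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  need <- c("patient_id", "genotype", "sex", "age_years", "time_months",
            "endpoint", "value")
  if (!identical(sort(names(raw)), sort(need)))
    stop("malformed header: expected columns ", paste(need, collapse = ", "),
         "; got ", paste(names(raw), collapse = ", "))
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  raw <- raw[raw$endpoint == endpoint$name, , drop = FALSE]
  if (nrow(raw) == 0L)
    stop("no rows for endpoint '", endpoint$name, "' in ", path)
  line <- as.integer(rownames(raw)) + 1L  # header is line 1
  for (col in c("age_years", "time_months", "value")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric %s '%s' at line %d (patient %s)",
                   col, raw[[col]][i], line[i], raw$patient_id[i]))
    }
    raw[[col]] <- v
  }
  key <- paste(raw$patient_id, raw$time_months, raw$endpoint, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (patient, time, endpoint) row at line %d (patient %s, t = %g)",
                 line[i], raw$patient_id[i], raw$time_months[i]))
  }
  oob <- raw$value < endpoint$lower_bound | raw$value > endpoint$upper_bound
  if (any(oob)) {
    i <- which(oob)[1L]
    stop(sprintf("value %g outside [%g, %g] at line %d (patient %s)",
                 raw$value[i], endpoint$lower_bound, endpoint$upper_bound,
                 line[i], raw$patient_id[i]))
  }
  n_obs <- nrow(raw)
  observations <- data.frame(
    patient_id = raw$patient_id, time_months = raw$time_months,
    age_years = raw$age_years, raw_value = raw$value,
    scaled_value = scale_score(raw$value, endpoint, n_obs = n_obs,
                               context = paste("patient", raw$patient_id,
                                               "line", line)),
    stringsAsFactors = FALSE)
  first <- !duplicated(raw$patient_id)
  ord <- order(raw$patient_id, raw$time_months)
  first_by_time <- !duplicated(raw$patient_id[ord])
  patients <- data.frame(
    patient_id = raw$patient_id[ord][first_by_time],
    genotype = raw$genotype[ord][first_by_time],
    sex = raw$sex[ord][first_by_time],
    baseline_age = raw$age_years[ord][first_by_time],
    stringsAsFactors = FALSE)
  longitudinal_dataset(observations, patients, endpoint)
}

#' Write a dataset to the longitudinal CSV dialect
#'
#' Inverse of [read_longitudinal_csv()]: raw values are written, so a
#' round trip through the file reproduces the dataset (the scaled values
#' are recomputed on read with the same squeeze size).
#'
#' @param dataset A [longitudinal_dataset()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_longitudinal_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cnm_data"))
  obs <- dataset$observations
  pat <- dataset$patients
  idx <- match(obs$patient_id, pat$patient_id)
  out <- data.frame(
    patient_id = obs$patient_id, genotype = pat$genotype[idx],
    sex = pat$sex[idx], age_years = obs$age_years,
    time_months = obs$time_months, endpoint = dataset$endpoint$name,
    value = obs$raw_value, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
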