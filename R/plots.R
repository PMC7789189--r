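#' Plot a posterior-predictive fit check
#'
#' Observed trajectories (points and lines) with the posterior mean
#' trajectory and predictive band for a selection of patients, one panel
#' per patient.
#'
#' @param x A [posterior_fit_check()] result.
#' @param patients Patient ids to show (default: first 9).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cnm_fit_check <- function(x, patients = NULL, ...) {
  f <- x$fitted
  ids <- unique(f$patient_id)
  if (is.null(patients)) patients <- utils::head(ids, 9)
  nr <- ceiling(sqrt(length(patients)))
  op <- graphics::par(mfrow = c(nr, ceiling(length(patients) / nr)),
                      mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(op))
  for (id in patients) {
    p <- f[f$patient_id == id, ]
    graphics::plot(p$time_months, p$scaled_value, ylim = c(0, 1),
                   xlab = "months", ylab = "scaled score", main = id,
                   pch = 19, col = "steelblue", ...)
    graphics::polygon(c(p$time_months, rev(p$time_months)),
                      c(p$lower, rev(p$upper)),
                      col = grDevices::adjustcolor("firebrick", 0.15),
                      border = NA)
    graphics::lines(p$time_months, p$fit_mean, col = "firebrick", lwd = 2)
    graphics::lines(p$time_months, p$scaled_value, col = "steelblue")
  }
  invisible(x)
}

#' Plot a predictive distribution fan
#'
#' Central 50%, 80% and 95% prediction intervals of the trajectories at
#' each future time, with the predictive median.
#'
#' @param x A `cnm_predictive`.
#' @param observed Optional observed values to overlay (one per time).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cnm_predictive <- function(x, observed = NULL, ...) {
  if (length(x$future_times) == 0L) stop("empty predictive")
  t <- x$future_times
  graphics::plot(range(t), c(0, 1), type = "n", xlab = "months",
                 ylab = "scaled score",
                 main = sprintf("%s (%s)", x$patient_id, x$source), ...)
  for (lv in c(0.95, 0.8, 0.5)) {
    iv <- prediction_intervals(x, lv)
    graphics::polygon(c(t, rev(t)), c(iv$lower, rev(iv$upper)),
                      col = grDevices::adjustcolor("grey40", 0.2),
                      border = NA)
  }
  graphics::lines(t, prediction_intervals(x, 0.5)$median, lwd = 2)
  if (!is.null(observed))
    graphics::points(t, observed, pch = 19, col = "forestgreen", cex = 1.2)
  invisible(x)
}

#' Plot assurance curves
#'
#' Assurance (expected power) against the increase in responder rate, one
#' curve per sample size; the value at zero increase is each design's
#' Type I error.
#'
#' @param x A [assurance_curve()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trial_oc <- function(x, ...) {
  cv <- x$curve
  ns <- sort(unique(cv$n))
  cols <- c("steelblue", "firebrick", "forestgreen", "darkorange")
  graphics::plot(range(cv$delta), c(0, 1), type = "n",
                 xlab = "increase in responder rate",
                 ylab = "assurance (expected power)", ...)
  graphics::abline(h = x$calibrations[[1]]$alpha, lty = 3)
  for (i in seq_along(ns)) {
    s <- cv[cv$n == ns[i], ]
    graphics::lines(s$delta, s$power, col = cols[(i - 1) %% 4 + 1], lwd = 2)
    graphics::points(s$delta, s$power, col = cols[(i - 1) %% 4 + 1],
                     pch = 19, cex = 0.6)
  }
  graphics::legend("bottomright", legend = paste("n =", ns),
                   col = cols[seq_along(ns)], lwd = 2, bty = "n")
  invisible(x)
}
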