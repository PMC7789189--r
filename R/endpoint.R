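#' Define a bounded clinical endpoint
#'
#' An endpoint specification records the natural bounds of a clinical score,
#' the direction in which a change counts as improvement, and the margin
#' beyond which an improvement is considered clinically relevant.
#'
#' @param name Character label, e.g. `"FEV1"`.
#' @param lower_bound,upper_bound Numeric bounds of the raw score
#'   (`lower_bound < upper_bound`).
#' @param improvement_direction `"increase"` or `"decrease"`: whether higher
#'   or lower values are better. FEV1 improves by increasing; time on
#'   ventilator improves by decreasing.
#' @param relevance_margin Non-negative change, in raw score units,
#'   considered clinically relevant (8 percentage points for FEV1).
#'
#' @return An object of class `endpoint_spec`.
#' @examples
#' endpoint_spec("FEV1", 0, 100, "increase", 8)
#' @export
endpoint_spec <- function(name, lower_bound, upper_bound,
                          improvement_direction = c("increase", "decrease"),
                          relevance_margin = 0) {
  improvement_direction <- match.arg(improvement_direction)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower_bound), is.numeric(upper_bound),
            length(lower_bound) == 1L, length(upper_bound) == 1L,
            is.finite(lower_bound), is.finite(upper_bound))
  if (lower_bound >= upper_bound)
    stop("`lower_bound` must be strictly below `upper_bound`")
  if (!is.finite(relevance_margin) || relevance_margin < 0)
    stop("`relevance_margin` must be a non-negative number")
  structure(
    list(name = name, lower_bound = lower_bound, upper_bound = upper_bound,
         improvement_direction = improvement_direction,
         relevance_margin = relevance_margin),
    class = "endpoint_spec")
}

#' Preset endpoint: FEV1 percent predicted
#'
#' Forced expiratory volume in one second, expressed as percent of the
#' predicted value, bounded in \[0, 100\]. An increase of 8 percentage
#' points is treated as clinically relevant.
#'
#' @return An [endpoint_spec()].
#' @export
endpoint_fev1 <- function() {
  endpoint_spec("FEV1", 0, 100, "increase", 8)
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat(sprintf("<endpoint_spec> %s on [%g, %g], improvement = %s, margin = %g\n",
              x$name, x$lower_bound, x$upper_bound,
              x$improvement_direction, x$relevance_margin))
  invisible(x)
}

#' Scale a raw score to the open unit interval
#'
#' Linearly maps a raw score from `[lower_bound, upper_bound]` to `[0, 1]`.
#' Values landing exactly on a bound are then compressed into the open
#' interval with `(y * (N - 1) + 0.5) / N`, `N = n_obs`, since the beta
#' likelihood is undefined at 0 and 1; interior values are untouched, so
#' the mapping is exactly linear away from the bounds. The squeeze moves a
#' boundary value by half an observation's worth of probability mass
#' (`0.5 / N` on the unit scale), which shrinks as the dataset grows.
#'
#' @param raw Numeric vector of raw scores; must lie within the endpoint
#'   bounds.
#' @param endpoint An [endpoint_spec()].
#' @param n_obs Number of observations in the dataset the value belongs
#'   to, sizing the boundary squeeze. Scores exactly at a bound require a
#'   finite `n_obs >= 2`.
#' @param context Optional character vector (recycled) naming the
#'   patient/visit of each value, used in error messages.
#'
#' @return Numeric vector of values strictly inside (0, 1).
#' @seealso [unscale_score()] for the inverse.
#' @examples
#' ep <- endpoint_fev1()
#' scale_score(50, ep)                 # 0.5
#' scale_score(100, ep, n_obs = 295)   # squeezed just below 1
#' @export
scale_score <- function(raw, endpoint, n_obs = Inf, context = NULL) {
  stopifnot(inherits(endpoint, "endpoint_spec"), is.numeric(raw))
  bad <- !is.finite(raw) | raw < endpoint$lower_bound | raw > endpoint$upper_bound
  if (any(bad)) {
    where <- if (is.null(context)) paste("element", which(bad)[1L])
             else rep_len(context, length(raw))[which(bad)[1L]]
    stop(sprintf("raw %s value %s outside bounds [%g, %g] (%s)",
                 endpoint$name, format(raw[which(bad)[1L]]),
                 endpoint$lower_bound, endpoint$upper_bound, where))
  }
  y <- (raw - endpoint$lower_bound) / (endpoint$upper_bound - endpoint$lower_bound)
  at_bound <- y == 0 | y == 1
  if (any(at_bound)) {
    if (!is.finite(n_obs))
      stop("scores exactly at the bounds need a finite `n_obs` for the boundary squeeze")
    if (n_obs < 2) stop("`n_obs` must be at least 2 for the boundary squeeze")
    y[at_bound] <- (y[at_bound] * (n_obs - 1) + 0.5) / n_obs
  }
  y
}

#' Recover a raw score from a scaled value
#'
#' Inverts the linear part of [scale_score()]. Values that were compressed
#' away from a bound are recovered to within the squeeze tolerance
#' (`0.5 / n_obs` of the score range).
#'
#' @inheritParams scale_score
#' @param scaled Numeric vector of scaled values.
#' @return Numeric vector on the raw score scale.
#' @export
unscale_score <- function(scaled, endpoint) {
  stopifnot(inherits(endpoint, "endpoint_spec"), is.numeric(scaled))
  endpoint$lower_bound +
    scaled * (endpoint$upper_bound - endpoint$lower_bound)
}
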