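# Weibull survival evaluation, history-conditional event-time sampling,
# competing-event selection and Kaplan-Meier median estimation.

#' Weibull survival function
#'
#' S(t) = exp(-(t/scale)^shape).
#'
#' @param t Time(s) >= 0.
#' @param shape,scale Weibull parameters, > 0.
#' @return Survival probabilities in `(0, 1]`.
#' @export
weibull_survival <- function(t, shape, scale) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  stopifnot(shape > 0, scale > 0)
  exp(-(t / scale)^shape)
}

#' Conditional Weibull event time
#'
#' Inverse-CDF sampling of a Weibull event time conditional on survival to
#' `elapsed`: returns the `t > elapsed` solving S(t)/S(elapsed) = u,
#' i.e. t = scale * ((elapsed/scale)^shape - log(u))^(1/shape). With
#' `elapsed = 0` this is plain inverse-transform sampling. Vectorized over
#' `u` and `elapsed`.
#'
#' @param shape,scale Weibull parameters, > 0.
#' @param elapsed Time already survived (same unit as `scale`), >= 0.
#' @param u Uniform(0,1) variates.
#' @return Event time(s), each > `elapsed`.
#' @export
conditional_weibull_time <- function(shape, scale, elapsed, u) {
  if (any(u <= 0) || any(u >= 1)) stop("u must lie in (0, 1)", call. = FALSE)
  if (any(elapsed < 0)) stop("elapsed must be >= 0", call. = FALSE)
  stopifnot(shape > 0, scale > 0)
  scale * ((elapsed / scale)^shape - log(u))^(1 / shape)
}

#' Sample time to next event from a covariate-shifted specification
#'
#' Shifts the event-time median by the patient's covariates
#' ([shifted_median()]), calibrates the Weibull scale to it, and draws the
#' event time conditional on the time already survived on this clock.
#'
#' @param spec A [survival_spec()].
#' @param covariates Named covariate values (see [shifted_median()]).
#' @param elapsed Months already survived without the event, >= 0.
#' @param u Uniform(0,1) variate(s); defaults to a fresh draw.
#' @param line Therapy line for per-line baseline medians.
#' @return Event time(s) in months since the clock origin, each > `elapsed`.
#' @export
sample_conditional_time <- function(spec, covariates = NULL, elapsed = 0,
                                    u = runif(1), line = 1L) {
  med <- shifted_median(spec, covariates, line = line)
  scale <- calibrate_weibull_scale(spec$shape, med)
  conditional_weibull_time(spec$shape, scale, elapsed, u)
}

# Deterministic tie-break order: competing candidates at the same instant
# resolve in favour of the most absorbing event.
.EVENT_PRIORITY <- c("nonhiv_death", "hiv_death", "aids_event", "line_switch",
                     "virological_failure", "resistance", "regimen_switch",
                     "hospitalization", "viral_suppression")

#' Event tie-break priority
#'
#' @return Character vector, highest priority first (death preempts all).
#' @export
event_priority <- function() .EVENT_PRIORITY

#' Select the next event among competing candidates
#'
#' Returns the minimum-time candidate; exact ties are broken by the
#' documented priority order ([event_priority()]): non-HIV death, HIV death,
#' AIDS event, line switch, virological failure, resistance, regimen switch,
#' hospitalization, suppression. Unknown event names rank last.
#'
#' @param candidates Named numeric vector of candidate times (names are event
#'   labels), or a data frame with columns `event` and `time`.
#' @return List with `event` and `time`.
#' @export
next_event <- function(candidates) {
  if (is.data.frame(candidates)) {
    candidates <- setNames(candidates$time, candidates$event)
  }
  if (length(candidates) == 0L) {
    stop("no candidate events", call. = FALSE)
  }
  rank <- match(names(candidates), .EVENT_PRIORITY,
                nomatch = length(.EVENT_PRIORITY) + 1L)
  ord <- order(candidates, rank)
  list(event = names(candidates)[ord[1L]],
       time = unname(candidates[ord[1L]]))
}

#' Kaplan-Meier median survival time
#'
#' Product-limit estimate of the median: the first observed time at which the
#' Kaplan-Meier curve drops to 0.5 or below, or `NA` if it never does.
#' Estimation is delegated to [survival::survfit()].
#'
#' @param times Event/censoring times.
#' @param event_flags Logical (or 0/1): `TRUE` for an observed event,
#'   `FALSE` for censoring. Defaults to all events.
#' @return Median time, or `NA` if the curve never reaches 0.5.
#' @export
km_median <- function(times, event_flags = rep(TRUE, length(times))) {
  stopifnot(length(times) == length(event_flags))
  fit <- survival::survfit(survival::Surv(times, as.integer(event_flags)) ~ 1)
  unname(stats::quantile(fit, probs = 0.5)$quantile)
}
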