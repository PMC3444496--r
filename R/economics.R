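# Conversion of states, intervals and events into discounted costs,
# life-years and QALYs (2009 euro, National Health Service perspective,
# direct medical costs only).

.cost_lp <- function(effects, reference, state) {
  if (length(effects) == 0L) return(0)
  tot <- 0
  for (nm in names(effects)) {
    x <- if (!is.null(state[[nm]])) {
      state[[nm]]
    } else if (nm == "adherence_pct" && !is.null(state[["adherence"]])) {
      100 * state[["adherence"]]
    } else {
      reference[[nm]]
    }
    r <- if (nm %in% names(reference)) reference[[nm]] else 0
    tot <- tot + effects[[nm]] * (x - r)
  }
  tot
}

.monthly_cost <- function(glm, reference, state, line) {
  anchors <- glm$anchors
  l <- pmin(as.integer(line), length(anchors))
  base <- anchors[l]
  if (any(is.na(base))) {
    stop("no cost anchor for line ", paste(unique(line[is.na(base)]),
                                           collapse = ", "), call. = FALSE)
  }
  exp(log(base) + .cost_lp(glm$effects, reference, state))
}

#' Monthly ART cost
#'
#' Log-link generalized-linear cost model: exp(log anchor + sum of
#' covariate effects), with per-line anchors calibrated so the first-line
#' median at the reference patient matches the arm's printed anchor.
#' Covariates are centred at the reference values of `params`.
#'
#' @param state `patient_state` data frame (covariates in registry names:
#'   `female`, `age`, `log10vl`, `cd4`, `hcv`, `year_init`,
#'   `resistance_level`, `prevfail1`, `prevfail2`, ...).
#' @param params A [model_parameters()].
#' @param line Therapy line(s); defaults to `state$line`.
#' @return Cost(s) in euro per month, strictly positive.
#' @export
monthly_art_cost <- function(state, params, line = state$line) {
  .monthly_cost(params$costs$art_glm, params$reference, state, line)
}

#' Monthly non-ART outpatient cost
#'
#' As [monthly_art_cost()] with the non-ART (Gamma GLM, log link) anchors
#' and effects.
#'
#' @inheritParams monthly_art_cost
#' @return Cost(s) in euro per month.
#' @export
monthly_nonart_cost <- function(state, params, line = state$line) {
  .monthly_cost(params$costs$nonart_glm, params$reference, state, line)
}

#' Cost attached to a clinical event
#'
#' Line switch (regimen change with virological failure): 582; regimen
#' switch without failure: 495, plus the inflation-adjusted adverse-event
#' cost when the cause is toxicity; AIDS-defining event: 4765;
#' hospitalization: 4742; suppression, resistance and death carry no cost
#' (default unit costs, in 2009 euro).
#'
#' @param event One of `"line_switch"`, `"regimen_switch"`, `"aids_event"`,
#'   `"hospitalization"`, `"viral_suppression"`, `"resistance"`,
#'   `"hiv_death"`, `"nonhiv_death"`.
#' @param cause For regimen switches: `"toxicity"` or `"other"`.
#' @param costs A [cost_parameters()].
#' @return Cost in euro.
#' @export
event_cost <- function(event, cause = "other", costs) {
  ae <- costs$adverse_event_cost_2005 * costs$inflation_factor_2005_to_2009
  switch(event,
         line_switch = costs$line_switch_cost,
         regimen_switch = costs$regimen_switch_cost +
           if (identical(cause, "toxicity")) ae else 0,
         aids_event = costs$aids_event_cost,
         hospitalization = costs$hospitalization_cost,
         viral_suppression = 0,
         resistance = 0,
         hiv_death = 0,
         nonhiv_death = 0,
         stop("unknown event type: ", event, call. = FALSE))
}

#' Daily ART cost on non-suppressive therapy
#'
#' Lognormal draw, fixed per individual on entry to non-suppressive therapy.
#'
#' @param costs A [cost_parameters()] (uses `nonsupp_art_lognormal`).
#' @param n Number of draws.
#' @return Strictly positive daily cost(s) in euro.
#' @export
nonsuppressive_daily_art_cost <- function(costs, n = 1L) {
  rlnorm(n, costs$nonsupp_art_lognormal[1], costs$nonsupp_art_lognormal[2])
}

#' Present value of a future amount
#'
#' Discrete annual compounding: `amount * (1 + rate)^(-time_years)`. For
#' continuously accruing quantities the package convention is to discount at
#' the midpoint of each accrual interval (see [accumulate_qalys()]).
#'
#' @param amount Amount(s).
#' @param time_years Time(s) from present in years, >= 0.
#' @param rate Annual discount rate (> -1).
#' @return Present value(s).
#' @export
discount <- function(amount, time_years, rate) {
  if (any(time_years < 0)) stop("time must be >= 0", call. = FALSE)
  if (rate <= -1) stop("rate must be > -1", call. = FALSE)
  amount * (1 + rate)^(-time_years)
}

#' Utility weight for a health state
#'
#' Table lookup by CD4 stratum and viral-suppression status.
#'
#' @param cd4 CD4 count(s), >= 0.
#' @param suppressed Logical (recycled).
#' @param table A [utility_table()].
#' @return Utility weight(s) in `[0, 1]`.
#' @export
utility_weight <- function(cd4, suppressed, table) {
  stopifnot(inherits(table, "utility_table"))
  if (any(cd4 < 0)) stop("cd4 must be >= 0", call. = FALSE)
  stratum <- findInterval(cd4, table$breaks) + 1L
  ifelse(rep_len(suppressed, length(cd4)),
         table$suppressed[stratum], table$unsuppressed[stratum])
}

#' Accumulate discounted QALYs over intervals
#'
#' QALYs = sum over intervals of length x utility x discount factor, with
#' the discount factor evaluated at the interval midpoint (mid-interval
#' convention for continuously accruing quantities).
#'
#' @param intervals Data frame with columns `start`, `end` (years from ART
#'   initiation), `cd4` and `suppressed` (state over the interval).
#' @param table A [utility_table()].
#' @param rate Annual discount rate.
#' @return Total discounted QALYs.
#' @export
accumulate_qalys <- function(intervals, table, rate) {
  len <- intervals$end - intervals$start
  stopifnot(all(len >= 0))
  w <- utility_weight(intervals$cd4, intervals$suppressed, table)
  mid <- (intervals$start + intervals$end) / 2
  sum(len * w * discount(1, mid, rate))
}

.EVENT_CODES <- c("nonhiv_death", "hiv_death", "aids_event", "line_switch",
                  "virological_failure", "resistance", "regimen_switch",
                  "hospitalization", "viral_suppression", "enter_nonsuppressive")

#' Replay an event trace through the economics rules
#'
#' Recomputes a full cost/effect ledger from a per-event trace (as emitted by
#' [simulate_individual()]): interval accruals (ART, non-ART, life-years,
#' QALYs) are discounted at interval midpoints and event costs at the event
#' time. Used to audit the simulation engine: the replayed ledger must equal
#' the engine's own accumulators.
#'
#' @param trace Trace data frame with columns `t0`, `t1` (months), `cd4`,
#'   `suppressed`, `art_monthly`, `nonart_monthly`, `event`, `event_cost`.
#' @param params A [model_parameters()] (for the discount rate and utility
#'   table).
#' @return Named list of ledger totals (discounted and undiscounted).
#' @export
replay_ledger <- function(trace, params) {
  r <- params$costs$discount_rate
  dt <- trace$t1 - trace$t0
  mid_y <- (trace$t0 + trace$t1) / 2 / 12
  df_mid <- discount(1, mid_y, r)
  df_end <- discount(1, trace$t1 / 12, r)
  w <- utility_weight(trace$cd4, trace$suppressed == 1, params$utilities)
  list(
    art_undisc = sum(trace$art_monthly * dt),
    art_disc = sum(trace$art_monthly * dt * df_mid),
    nonart_undisc = sum(trace$nonart_monthly * dt),
    nonart_disc = sum(trace$nonart_monthly * dt * df_mid),
    event_undisc = sum(trace$event_cost),
    event_disc = sum(trace$event_cost * df_end),
    ly_undisc = sum(dt) / 12,
    ly_disc = sum(dt / 12 * df_mid),
    qaly_undisc = sum(dt / 12 * w),
    qaly_disc = sum(dt / 12 * w * df_mid))
}
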