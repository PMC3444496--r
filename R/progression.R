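# State-update rules applied when events fire: marker trajectories,
# adherence, the resistance ladder, AIDS classification and line/regimen
# transitions. All functions are vectorized over rows of a patient_state
# data frame where a state argument is taken.

#' CD4 change over an interval on a therapy line
#'
#' Logarithmic within-line trajectory: the accumulated change over `dt`
#' months on suppressive line L is `a[L] * log(1 + b[L] * dt)` (zero at
#' `dt = 0`, monotone when `a, b > 0`); on non-suppressive therapy CD4
#' declines linearly at the configured yearly rate.
#'
#' @param line Therapy line: 1-3, or 4/"nonsuppressive".
#' @param dt Months on the line, >= 0.
#' @param traj A [trajectory_spec()].
#' @return CD4 change in cells/uL.
#' @export
cd4_change <- function(line, dt, traj) {
  stopifnot(inherits(traj, "trajectory_spec"), all(dt >= 0))
  if (is.character(line)) {
    line <- ifelse(line %in% c("nonsuppressive", "non_suppressive"), 4L,
                   as.integer(line))
  }
  ifelse(line >= 4L,
         -traj$nonsupp_decline / 12 * dt,
         traj$cd4_a[pmin(line, 3L)] * log(1 + traj$cd4_b[pmin(line, 3L)] * dt))
}

#' Log10 viral-load drift over an interval
#'
#' Per-line logarithmic drift of log10VL while unsuppressed (zero under the
#' default parameters: viral load then moves only at suppression and
#' rebound).
#'
#' @inheritParams cd4_change
#' @return Change in log10 copies/mL.
#' @export
log10vl_change <- function(line, dt, traj) {
  stopifnot(inherits(traj, "trajectory_spec"), all(dt >= 0))
  l <- pmin(as.integer(line), 3L)
  traj$vl_a[l] * log(1 + traj$vl_b[l] * dt)
}

#' Apply viral suppression
#'
#' Sets the suppressed flag and drops log10 viral load instantaneously to
#' the detectability floor, where it remains until a rebound.
#'
#' @param state A `patient_state` data frame.
#' @param floor log10VL value assigned on suppression (default 1.69, i.e.
#'   log10 of 49 copies/mL).
#' @return Updated state.
#' @export
apply_suppression <- function(state, floor = 1.69) {
  state$suppressed <- TRUE
  state$log10vl <- floor
  state
}

#' Apply viral rebound
#'
#' On virological failure after suppression, clears the suppressed flag and
#' draws the rebound log10 viral load from a uniform distribution within the
#' configured bounds.
#'
#' @param state A `patient_state` data frame; every row must currently be
#'   suppressed.
#' @param bounds `c(lo, hi)` rebound bounds on the log10 scale.
#' @return Updated state.
#' @export
apply_rebound <- function(state, bounds) {
  if (!all(state$suppressed)) {
    stop("rebound without prior suppression", call. = FALSE)
  }
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  state$suppressed <- FALSE
  state$log10vl <- runif(nrow(state), bounds[1], bounds[2])
  state
}

#' Update adherence from current covariates
#'
#' Inverse-logit update: each patient keeps an individual baseline logit
#' (anchored at their sampled baseline adherence) and the logit-scale
#' coefficients of the [adherence_model()] move it as covariates change:
#' p = plogis(qlogis(p0) + sum(beta * (x - x0))). The output is strictly
#' inside (0, 1).
#'
#' @param model An [adherence_model()].
#' @param adherence_baseline Baseline adherence fraction(s), clamped to
#'   `[0.01, 0.99]` before the logit.
#' @param covariates Named list/data frame of current covariate values.
#' @param covariates_baseline Covariate values at baseline (defaults to the
#'   model reference).
#' @return Adherence fraction(s) in (0, 1).
#' @export
update_adherence <- function(model, adherence_baseline, covariates,
                             covariates_baseline = NULL) {
  stopifnot(inherits(model, "adherence_model"))
  lp <- function(cov) {
    if (length(model$beta) == 0L) return(0)
    tot <- 0
    for (nm in names(model$beta)) {
      x <- if (!is.null(cov[[nm]])) cov[[nm]] else model$reference[[nm]]
      tot <- tot + model$beta[[nm]] * (x - model$reference[[nm]])
    }
    tot
  }
  base <- qlogis(pmin(pmax(adherence_baseline, 0.01), 0.99))
  x0 <- if (is.null(covariates_baseline)) 0 else lp(covariates_baseline)
  plogis(base + lp(covariates) - x0)
}

#' Advance the resistance ladder
#'
#' On a resistance event the patient moves to the adjacent (next) class,
#' capped at class 4, and draws a new level uniformly within the new class
#' bounds. A patient already in class 4 instead updates the level to the
#' maximum of the current level and a triangular draw on the class-4 range
#' (resistance never decreases).
#'
#' @param state A `patient_state` data frame.
#' @param params A [model_parameters()] (for `resistance_bounds` and
#'   `triangular`).
#' @return Updated state.
#' @export
advance_resistance <- function(state, params) {
  b <- params$resistance_bounds        # c(1, 5, 10, 25)
  lo <- c(0, b[1], b[2], b[3])
  hi <- c(b[1], b[2], b[3], b[4])
  n <- nrow(state)
  at4 <- state$resistance_class >= 4L
  newc <- pmin(state$resistance_class + 1L, 4L)
  lev <- runif(n, lo[newc], hi[newc])
  tri <- rtriangular(n, params$triangular[1], params$triangular[2],
                     params$triangular[3])
  state$resistance_level <- ifelse(at4, pmax(state$resistance_level, tri),
                                   lev)
  state$resistance_class <- ifelse(at4, 4L, newc)
  state
}

#' Triangular random variates
#'
#' Inverse-CDF sampling from a triangular distribution.
#'
#' @param n Number of draws.
#' @param min,max,mode Support and mode, `min <= mode <= max`.
#' @return Numeric vector.
#' @export
rtriangular <- function(n, min, max, mode) {
  stopifnot(min <= mode, mode <= max, min < max)
  u <- runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Evaluate line-transition rules after an event
#'
#' Applies the treatment-line logic: on lines 1-2 a suppression-deadline
#' breach or a confirmed virological failure triggers a switch to the next
#' line; on line 3 a failure keeps the patient on the line (regimen
#' reshuffle) while resistance is below the highest class, and moves them to
#' non-suppressive therapy once class 4 is reached. At most two line
#' switches can ever occur from line 1.
#'
#' @param state One-row `patient_state` data frame (or list) with at least
#'   `line` and `resistance_class`.
#' @param event `"deadline"` (suppression not reached in time),
#'   `"virological_failure"`, or `"resistance"` (a class change).
#' @param months_in_line Months spent on the current line (informational).
#' @param params A [model_parameters()].
#' @return List with `action` (`"stay"`, `"regimen_switch"`, `"line_switch"`,
#'   `"enter_nonsuppressive"`) and `cause` (`"failure_no_suppression"`,
#'   `"failure_after_suppression"`, `"resistance"`, or `NA`).
#' @export
evaluate_line_rules <- function(state, event, months_in_line, params) {
  line <- as.integer(state$line[[1]])
  cls <- as.integer(state$resistance_class[[1]])
  if (!line %in% 1:4 || !cls %in% 1:4) {
    stop("inconsistent line/resistance class", call. = FALSE)
  }
  if (line == 4L) return(list(action = "stay", cause = NA_character_))
  cause <- switch(event,
                  deadline = "failure_no_suppression",
                  virological_failure = "failure_after_suppression",
                  resistance = "resistance",
                  NA_character_)
  if (event == "resistance") {
    if (line == 3L && cls >= 4L) {
      return(list(action = "enter_nonsuppressive", cause = cause))
    }
    return(list(action = "stay", cause = NA_character_))
  }
  if (!event %in% c("deadline", "virological_failure")) {
    return(list(action = "stay", cause = NA_character_))
  }
  if (line <= 2L) {
    return(list(action = "line_switch", cause = cause))
  }
  # line 3
  if (cls >= 4L) {
    list(action = "enter_nonsuppressive", cause = cause)
  } else {
    list(action = "regimen_switch", cause = cause)
  }
}

#' Classify AIDS status
#'
#' Permanently flags AIDS upon the first AIDS-defining event or a CD4 count
#' strictly below 200 cells/uL; the flag never reverts.
#'
#' @param state A `patient_state` data frame.
#' @param aids_event Logical (recycled): did an AIDS-defining event fire?
#' @return Updated state.
#' @export
classify_aids <- function(state, aids_event = FALSE) {
  state$aids <- as.integer(state$aids == 1L | state$cd4 < 200 |
                             rep_len(aids_event, nrow(state)))
  state
}

#' Draw new regimen characteristics
#'
#' Independent categorical draws of the number of PIs, daily dose frequency
#' and pills per day from the line-specific table distributions, applied on
#' every regimen or line change.
#'
#' @param line Therapy line (1-3; line 4 reuses the line-3 tables).
#' @param tables Per-line regimen tables as in [model_parameters()].
#' @param n Number of draws.
#' @return Data frame with columns `n_pis`, `doses_per_day`, `pills_per_day`.
#' @export
draw_regimen_characteristics <- function(line, tables, n = 1L) {
  l <- min(as.integer(line), length(tables))
  tab <- tables[[l]]
  if (is.null(tab)) stop("no regimen table for line ", line, call. = FALSE)
  data.frame(n_pis = .sample_table(tab$n_pis, n),
             doses_per_day = .sample_table(tab$doses, n),
             pills_per_day = .sample_table(tab$pills, n))
}

#' Assign the cause of a regimen switch without failure
#'
#' Toxicity with probability `p` (triggering the adverse-event cost),
#' otherwise "other", mirroring the observed cause mix.
#'
#' @param n Number of draws.
#' @param p Toxicity probability in `[0, 1]`.
#' @return Character vector of `"toxicity"`/`"other"`.
#' @export
assign_switch_cause <- function(n, p = 0.54) {
  stopifnot(p >= 0, p <= 1)
  ifelse(runif(n) < p, "toxicity", "other")
}
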