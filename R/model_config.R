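#' @useDynLib artpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis qlogis runif rlnorm rnorm rbeta median quantile
#'   setNames integrate uniroot pweibull qweibull rweibull
#' @importFrom utils write.csv modifyList
NULL

# Registry of patient-state covariates that survival / cost / adherence models
# may reference. Order is fixed: the C++ engine indexes covariates by position.
.COVARIATES <- c(
  "female", "age", "log10vl", "cd4", "hcv", "adherence_pct", "year_init",
  "n_pis", "resistance_level", "regimen_number", "line2", "line3",
  "prevfail1", "prevfail2", "resclass2", "resclass3", "resclass4",
  "idu", "homosexual", "othertrans", "aids", "doses1", "doses3", "pills",
  "art_years", "art_cost"
)

#' Covariate registry
#'
#' Names of the patient-state covariates recognised by event-time, cost and
#' adherence models. `line2`/`line3`, `prevfail1`/`prevfail2` (exactly one /
#' more than one prior virological failure), `resclass2..4`, transmission-group
#' and dose-frequency entries are 0/1 indicators; `adherence_pct` is adherence
#' in percent, `art_years` time since ART initiation in years and `art_cost`
#' the current monthly ART cost in euro.
#'
#' @return Character vector of covariate names.
#' @export
art_covariates <- function() .COVARIATES

.named_effects <- function(effects) {
  if (is.null(effects)) return(setNames(numeric(0), character(0)))
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  unknown <- setdiff(names(effects), .COVARIATES)
  if (length(unknown) > 0L) {
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  effects
}

#' Weibull time-to-event specification
#'
#' A Weibull event-time model parameterised by its shape and its median at a
#' reference patient, plus additive covariate effects on the median (months per
#' covariate unit, applied to covariates centred at `reference`).
#'
#' @param event Event name (character scalar).
#' @param shape Weibull shape parameter, > 0.
#' @param median Baseline (reference-patient) median time to event in months,
#'   > 0. May be a vector of length 4 giving per-line medians.
#' @param effects Named numeric vector of additive median shifts (months per
#'   covariate unit); names must come from [art_covariates()].
#' @param reference Named numeric vector of covariate reference values at which
#'   the baseline median holds; defaults to 0 for every covariate in `effects`.
#' @param floor Positive lower bound for the shifted median (months).
#' @param strata Optional stratification label (e.g. `"aids"` for HIV death).
#' @return An object of class `survival_spec`.
#' @export
survival_spec <- function(event, shape, median, effects = NULL,
                          reference = NULL, floor = 0.1, strata = NULL) {
  stopifnot(is.character(event), length(event) == 1L)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0) {
    stop("shape must be a positive number", call. = FALSE)
  }
  if (!is.numeric(median) || any(!is.finite(median)) || any(median <= 0)) {
    stop("median must be positive", call. = FALSE)
  }
  if (!is.numeric(floor) || floor <= 0) {
    stop("floor must be positive", call. = FALSE)
  }
  effects <- .named_effects(effects)
  ref <- setNames(rep(0, length(effects)), names(effects))
  if (!is.null(reference)) {
    reference <- .named_effects(reference)
    ref[names(reference)[names(reference) %in% names(ref)]] <-
      reference[names(reference) %in% names(ref)]
  }
  structure(list(event = event, shape = shape, median = median,
                 effects = effects, reference = ref, floor = floor,
                 strata = strata),
            class = "survival_spec")
}

#' Calibrate a Weibull scale to a target median
#'
#' Inverts the Weibull survival function S(t) = exp(-(t/scale)^shape) at
#' S = 1/2, returning the scale for which the distribution median equals
#' `target_median`: scale = median / log(2)^(1/shape).
#'
#' @param shape Weibull shape, > 0.
#' @param target_median Target median (same time unit as the returned scale),
#'   > 0.
#' @return Weibull scale parameter.
#' @export
#' @examples
#' calibrate_weibull_scale(1, log(2))  # exponential: scale 1
calibrate_weibull_scale <- function(shape, target_median) {
  if (any(!is.finite(shape)) || any(shape <= 0)) {
    stop("shape must be positive", call. = FALSE)
  }
  if (any(!is.finite(target_median)) || any(target_median <= 0)) {
    stop("target_median must be positive", call. = FALSE)
  }
  target_median / log(2)^(1 / shape)
}

#' Median of a Weibull distribution
#'
#' @param shape,scale Weibull parameters, > 0.
#' @return scale * log(2)^(1/shape).
#' @export
weibull_median <- function(shape, scale) scale * log(2)^(1 / shape)

#' Covariate-shifted median time to event
#'
#' Applies the additive marginal covariate effects of a [survival_spec()] to a
#' set of covariate values: adjusted = max(median + sum(effect * (x - ref)),
#' floor). Covariates are centred at the spec's reference values so the
#' baseline median holds at the reference patient.
#'
#' @param spec A [survival_spec()].
#' @param covariates Named numeric vector or list with one value per covariate
#'   named in `spec$effects` (extra entries are ignored).
#' @param line Optional therapy line (1-4) selecting among per-line baseline
#'   medians when `spec$median` has length > 1.
#' @return Adjusted median in months.
#' @export
shifted_median <- function(spec, covariates = NULL, line = 1L) {
  stopifnot(inherits(spec, "survival_spec"))
  base <- if (length(spec$median) > 1L) {
    spec$median[[min(line, length(spec$median))]]
  } else {
    spec$median
  }
  if (length(spec$effects) == 0L) return(max(base, spec$floor))
  covariates <- unlist(covariates)
  missing <- setdiff(names(spec$effects), names(covariates))
  if (length(missing) > 0L) {
    stop("missing covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(covariates[names(spec$effects)])
  shift <- sum(spec$effects * (x - spec$reference[names(spec$effects)]))
  max(base + shift, spec$floor)
}

#' Marker-trajectory specification
#'
#' Per-line logarithmic trajectories for CD4 count and log10 viral load:
#' change over `dt` months in line L is `a[L] * log(1 + b[L] * dt)` (zero at
#' dt = 0), plus a constant CD4 decline rate on non-suppressive therapy.
#'
#' @param cd4_a,cd4_b Numeric length 3 (lines 1-3): amplitude (cells/uL) and
#'   curvature (1/month) of the CD4 trajectory.
#' @param nonsupp_decline CD4 decline rate on non-suppressive therapy,
#'   cells/uL per year (positive number = decline).
#' @param vl_a,vl_b As `cd4_a`/`cd4_b` for log10 viral load drift while
#'   unsuppressed (defaults 0: viral load moves only at suppression/rebound).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(cd4_a, cd4_b, nonsupp_decline = 17,
                            vl_a = c(0, 0, 0), vl_b = c(0.2, 0.2, 0.2)) {
  stopifnot(length(cd4_a) == 3L, length(cd4_b) == 3L,
            all(is.finite(c(cd4_a, cd4_b, vl_a, vl_b, nonsupp_decline))),
            all(cd4_b > 0), all(vl_b > 0))
  structure(list(cd4_a = as.numeric(cd4_a), cd4_b = as.numeric(cd4_b),
                 nonsupp_decline = nonsupp_decline,
                 vl_a = as.numeric(vl_a), vl_b = as.numeric(vl_b)),
            class = "trajectory_spec")
}

#' Cost parameters
#'
#' Unit costs (2009 euro), the annual discount rate, and the generalized
#' linear cost models for monthly ART and non-ART outpatient spending.
#'
#' @param discount_rate Annual discount rate (fraction, >= 0).
#' @param line_switch_cost Cost of a regimen change with virological failure.
#' @param regimen_switch_cost Cost of a regimen change without failure.
#' @param adverse_event_cost_2005 Cost of a toxicity episode at 2005 prices.
#' @param inflation_factor_2005_to_2009 Multiplier updating 2005 to 2009 prices.
#' @param aids_event_cost Inpatient cost of an AIDS-defining event.
#' @param hospitalization_cost Inpatient cost of a non-AIDS hospitalization.
#' @param art_glm,nonart_glm Lists with elements `anchors` (euro/month at the
#'   reference patient, length 4: lines 1-3 and non-suppressive; ART line 4
#'   is costed by the lognormal daily draw instead) and `effects` (named
#'   log-scale coefficients per covariate unit).
#' @param nonsupp_art_lognormal `c(meanlog, sdlog)` of the daily ART cost on
#'   non-suppressive therapy.
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(discount_rate = 0.05,
                            line_switch_cost = 582,
                            regimen_switch_cost = 495,
                            adverse_event_cost_2005 = 1126,
                            inflation_factor_2005_to_2009 = 1.10,
                            aids_event_cost = 4765,
                            hospitalization_cost = 4742,
                            art_glm = list(anchors = c(613, 850, 1000, NA),
                                           effects = NULL),
                            nonart_glm = list(anchors = c(63, 90, 150, 200),
                                              effects = NULL),
                            nonsupp_art_lognormal = c(log(20), 0.25)) {
  errs <- character(0)
  if (!is.numeric(discount_rate) || discount_rate < 0) {
    errs <- c(errs, "discount_rate must be >= 0")
  }
  unit <- c(line_switch_cost = line_switch_cost,
            regimen_switch_cost = regimen_switch_cost,
            adverse_event_cost_2005 = adverse_event_cost_2005,
            aids_event_cost = aids_event_cost,
            hospitalization_cost = hospitalization_cost)
  bad <- names(unit)[!is.finite(unit) | unit < 0]
  if (length(bad) > 0L) {
    errs <- c(errs, paste0(bad, " must be a non-negative number"))
  }
  if (length(errs) > 0L) stop(paste(errs, collapse = "; "), call. = FALSE)
  art_glm$effects <- .named_effects(art_glm$effects)
  nonart_glm$effects <- .named_effects(nonart_glm$effects)
  structure(list(discount_rate = discount_rate,
                 line_switch_cost = line_switch_cost,
                 regimen_switch_cost = regimen_switch_cost,
                 adverse_event_cost_2005 = adverse_event_cost_2005,
                 inflation_factor_2005_to_2009 = inflation_factor_2005_to_2009,
                 aids_event_cost = aids_event_cost,
                 hospitalization_cost = hospitalization_cost,
                 art_glm = art_glm, nonart_glm = nonart_glm,
                 nonsupp_art_lognormal = as.numeric(nonsupp_art_lognormal)),
            class = "cost_parameters")
}

#' Utility table
#'
#' Health-state utility weights stratified by CD4 count and viral suppression
#' status. `breaks` give the internal CD4 stratum boundaries; with
#' `breaks = c(100, 200)` the strata are `[0,100)`, `[100,200)`, `[200,Inf)`.
#'
#' @param breaks Increasing positive CD4 boundaries (cells/uL).
#' @param unsuppressed,suppressed Utility weights in `[0, 1]`, one per stratum
#'   (length `length(breaks) + 1`), ordered from the lowest CD4 stratum up.
#' @return An object of class `utility_table`.
#' @export
utility_table <- function(breaks = c(100, 200),
                          unsuppressed = c(0.78, 0.84, 0.92),
                          suppressed = c(0.81, 0.87, 0.95)) {
  k <- length(breaks) + 1L
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
    stop("breaks must be strictly increasing and positive", call. = FALSE)
  }
  if (length(unsuppressed) != k || length(suppressed) != k) {
    stop("need one weight per CD4 stratum (", k, ")", call. = FALSE)
  }
  w <- c(unsuppressed, suppressed)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("utility weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(breaks = as.numeric(breaks),
                 unsuppressed = as.numeric(unsuppressed),
                 suppressed = as.numeric(suppressed)),
            class = "utility_table")
}

#' Adherence model
#'
#' Logit-link model for pharmacy-refill adherence. Table-style marginal
#' effects are supplied in percentage points per covariate unit and converted
#' to logit-scale coefficients locally at the reference adherence `p_ref`
#' via beta = delta_p / (p_ref * (1 - p_ref)).
#'
#' @param effects_pp Named numeric vector: percentage-point change in
#'   adherence per covariate unit.
#' @param reference Named numeric vector of covariate reference values
#'   (default 0).
#' @param p_ref Reference adherence (fraction) at which marginal effects are
#'   anchored.
#' @return An object of class `adherence_model` with logit-scale `beta`.
#' @export
adherence_model <- function(effects_pp, reference = NULL, p_ref = 0.88) {
  effects_pp <- .named_effects(effects_pp)
  stopifnot(p_ref > 0, p_ref < 1)
  beta <- (effects_pp / 100) / (p_ref * (1 - p_ref))
  ref <- setNames(rep(0, length(beta)), names(beta))
  if (!is.null(reference)) {
    reference <- .named_effects(reference)
    keep <- names(reference) %in% names(ref)
    ref[names(reference)[keep]] <- reference[keep]
  }
  structure(list(beta = beta, effects_pp = effects_pp, reference = ref,
                 p_ref = p_ref),
            class = "adherence_model")
}

#' Bundle of model parameters for one strategy arm
#'
#' Validates and assembles the complete parameter set driving the simulation
#' of one strategy arm. Most users will start from [default_parameters()] and
#' modify fields, or load a configuration file with [load_parameters()].
#'
#' @param arm `"nnrti"` or `"pir"`.
#' @param baseline A `baseline_profile` (see [baseline_profile()]).
#' @param events Named list of [survival_spec()] objects; required names:
#'   `viral_suppression`, `viral_suppression_l3`, `virological_failure_l12`,
#'   `virological_failure_l3`, `regimen_switch`, `first_resistance`,
#'   `resistance_class_switch`, `hospitalization`.
#' @param hiv_death List with `shape` and `median` (months), each length 2
#'   (`non_aids`, `aids`): Weibull HIV-death model stratified by AIDS status.
#' @param aids_event List with `shape`, `median_by_cd4` (months, one per CD4
#'   stratum of `cd4_breaks`), `cd4_breaks`, and `transmission_multiplier`
#'   (named: hetero, idu, homosexual, other) multiplying the median.
#' @param trajectory A [trajectory_spec()].
#' @param costs A [cost_parameters()].
#' @param utilities A [utility_table()].
#' @param adherence An [adherence_model()].
#' @param rebound_bounds `c(lo, hi)`: support of the uniform log10 viral-load
#'   rebound draw.
#' @param resistance_bounds Strictly increasing resistance-class boundaries
#'   (default `c(1, 5, 10, 25)`).
#' @param triangular `c(min, max, mode)` of the class-4 resistance-level draw.
#' @param toxicity_p Probability that a regimen switch without failure is due
#'   to toxicity.
#' @param suppression_deadline Months allowed to reach suppression on lines
#'   1-2 before the line is declared failed.
#' @param line3_suppression_window Months allowed for the initial line-3
#'   suppression attempt.
#' @param detect_floor log10 viral load assigned on suppression.
#' @param regimen_tables Per-line list (lines 1-3) of table distributions for
#'   `n_pis`, `doses` and `pills`, each `list(values=, probs=)`.
#' @param life_table Data frame with columns `age`, `sex` (`"male"`/
#'   `"female"`) and `qx` (annual death probability) for non-HIV mortality.
#' @param reference Named covariate reference vector shared by the event/cost
#'   models (merged into each spec at validation).
#' @param max_lines Number of suppressive therapy lines (fixed at 3).
#' @param cd4_cap,age_cap Caps on CD4 (cells/uL) and age (years).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(arm, baseline, events, hiv_death, aids_event,
                             trajectory, costs, utilities, adherence,
                             rebound_bounds, resistance_bounds = c(1, 5, 10, 25),
                             triangular = c(10, 25, 15), toxicity_p = 0.54,
                             suppression_deadline = 12,
                             line3_suppression_window = 36,
                             detect_floor = 1.69,
                             regimen_tables, life_table, reference,
                             max_lines = 3, cd4_cap = 1500, age_cap = 105) {
  p <- structure(list(arm = arm, baseline = baseline, events = events,
                      hiv_death = hiv_death, aids_event = aids_event,
                      trajectory = trajectory, costs = costs,
                      utilities = utilities, adherence = adherence,
                      rebound_bounds = as.numeric(rebound_bounds),
                      resistance_bounds = as.numeric(resistance_bounds),
                      triangular = as.numeric(triangular),
                      toxicity_p = toxicity_p,
                      suppression_deadline = suppression_deadline,
                      line3_suppression_window = line3_suppression_window,
                      detect_floor = detect_floor,
                      regimen_tables = regimen_tables,
                      life_table = life_table,
                      reference = reference,
                      max_lines = max_lines, cd4_cap = cd4_cap,
                      age_cap = age_cap),
                 class = "model_parameters")
  validate_parameters(p)
  p
}

.REQUIRED_EVENTS <- c("viral_suppression", "viral_suppression_l3",
                      "virological_failure_l12", "virological_failure_l3",
                      "regimen_switch", "first_resistance",
                      "resistance_class_switch", "hospitalization")

#' Validate a model-parameter bundle
#'
#' Checks every structural invariant of a [model_parameters()] object and
#' stops with a message listing all offending fields.
#'
#' @param p A `model_parameters` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_parameters <- function(p) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(p$arm %in% c("nnrti", "pir"), "arm must be 'nnrti' or 'pir'")
  chk(inherits(p$baseline, "baseline_profile"),
      "baseline must be a baseline_profile")
  miss <- setdiff(.REQUIRED_EVENTS, names(p$events))
  chk(length(miss) == 0L,
      paste0("missing event spec(s): ", paste(miss, collapse = ", ")))
  for (nm in intersect(.REQUIRED_EVENTS, names(p$events))) {
    s <- p$events[[nm]]
    chk(inherits(s, "survival_spec"), paste0(nm, " is not a survival_spec"))
    if (inherits(s, "survival_spec")) {
      chk(s$shape > 0, paste0(nm, ": shape must be > 0"))
      chk(all(s$median > 0), paste0(nm, ": median must be > 0"))
    }
  }
  chk(length(p$hiv_death$shape) == 2L && all(p$hiv_death$shape > 0),
      "hiv_death$shape must be two positive shapes (non-AIDS, AIDS)")
  chk(length(p$hiv_death$median) == 2L && all(p$hiv_death$median > 0),
      "hiv_death$median must be two positive medians (non-AIDS, AIDS)")
  chk(p$aids_event$shape > 0, "aids_event$shape must be > 0")
  chk(length(p$aids_event$median_by_cd4) ==
        length(p$aids_event$cd4_breaks) + 1L &&
        all(p$aids_event$median_by_cd4 > 0),
      "aids_event$median_by_cd4 must hold one positive median per CD4 stratum")
  chk(inherits(p$trajectory, "trajectory_spec"),
      "trajectory must be a trajectory_spec")
  chk(inherits(p$costs, "cost_parameters"),
      "costs must be a cost_parameters object")
  chk(inherits(p$utilities, "utility_table"),
      "utilities must be a utility_table")
  chk(inherits(p$adherence, "adherence_model"),
      "adherence must be an adherence_model")
  chk(length(p$rebound_bounds) == 2L &&
        p$rebound_bounds[1] < p$rebound_bounds[2],
      "rebound_bounds must be an increasing pair")
  chk(!is.unsorted(p$resistance_bounds, strictly = TRUE),
      "resistance_bounds must be strictly increasing")
  chk(is.numeric(p$toxicity_p) && p$toxicity_p >= 0 && p$toxicity_p <= 1,
      "toxicity_p must lie in [0, 1]")
  chk(p$suppression_deadline > 0, "suppression_deadline must be > 0")
  chk(p$line3_suppression_window > 0, "line3_suppression_window must be > 0")
  chk(p$max_lines == 3, "max_lines is fixed at 3")
  chk(is.data.frame(p$life_table) &&
        all(c("age", "sex", "qx") %in% names(p$life_table)),
      "life_table needs columns age, sex, qx")
  if (is.data.frame(p$life_table) && "qx" %in% names(p$life_table)) {
    chk(all(p$life_table$qx >= 0 & p$life_table$qx <= 1),
        "life_table qx must lie in [0, 1]")
  }
  chk(length(p$regimen_tables) >= 3L, "regimen_tables must cover lines 1-3")
  for (l in seq_len(min(3L, length(p$regimen_tables)))) {
    tab <- p$regimen_tables[[l]]
    for (fld in c("n_pis", "doses", "pills")) {
      t <- tab[[fld]]
      ok <- !is.null(t) && length(t$values) == length(t$probs) &&
        abs(sum(t$probs) - 1) < 1e-8 && all(t$probs >= 0)
      chk(ok, paste0("regimen_tables line ", l, " ", fld,
                     " must be a table distribution summing to 1"))
    }
  }
  if (length(errs) > 0L) {
    stop("invalid model parameters:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  invisible(p)
}

# ---- defaults -------------------------------------------------------------

# Marginal covariate effects (months per unit) on the event-time medians.
# One named vector per event; line indicators are handled through per-line
# baseline medians where the spec is line-resolved.
.default_event_effects <- function() {
  list(
    viral_suppression = c(
      female = -0.554, age = -0.111, log10vl = 0.951, cd4 = 0.000,
      hcv = -1.680, adherence_pct = -0.062, year_init = 0.022,
      n_pis = 0.297, resistance_level = -0.847),
    virological_failure_l12 = c(
      female = 7.653, age = 0.559, log10vl = -19.563, cd4 = 0.026,
      hcv = 10.094, adherence_pct = 0.184, year_init = 2.448,
      n_pis = -6.120, resistance_level = -1.894, regimen_number = -8.963),
    virological_failure_l3 = c(
      female = 0.643, age = -0.080, log10vl = -1.550, year_init = -5.188,
      n_pis = -0.618, regimen_number = 0.239,
      resclass2 = -6.225, resclass3 = -7.348, resclass4 = -7.021),
    regimen_switch = c(
      female = -2.702, age = -0.079, log10vl = 1.321, cd4 = 0.003,
      hcv = -5.223, adherence_pct = -0.940, year_init = -1.189,
      n_pis = -5.678, resistance_level = 0.269, regimen_number = 1.071),
    first_resistance = c(
      female = 8.590, age = -5.180, log10vl = -84.450, hcv = -26.000,
      adherence_pct = 2.910, year_init = -22.290, n_pis = -33.890,
      regimen_number = 3.990),
    resistance_class_switch = c(
      female = -0.486, age = -0.555, log10vl = -3.249, year_init = 0.020,
      n_pis = 6.850, regimen_number = -6.310),
    hospitalization = c(
      female = 11.149, age = -2.502, log10vl = -18.216, cd4 = 0.146,
      hcv = -32.008, adherence_pct = 0.424, year_init = 1.295,
      n_pis = -3.453, resistance_level = -7.927))
}

.default_reference <- function(arm) {
  c(female = 0, age = 39,
    log10vl = if (arm == "nnrti") 4.9 else 5.1,
    cd4 = if (arm == "nnrti") 234 else 219,
    hcv = 0,
    adherence_pct = if (arm == "nnrti") 89 else 88,
    year_init = if (arm == "nnrti") 2003 else 2005,
    n_pis = if (arm == "nnrti") 0 else 1,
    resistance_level = 0, regimen_number = 1,
    line2 = 0, line3 = 0, prevfail1 = 0, prevfail2 = 0,
    resclass2 = 0, resclass3 = 0, resclass4 = 0,
    idu = 0, homosexual = 0, othertrans = 0, aids = 0,
    doses1 = 0, doses3 = 0,
    pills = if (arm == "nnrti") 3 else 5,
    art_years = 0,
    art_cost = if (arm == "nnrti") 613 else 1057)
}

.default_regimen_tables <- function(arm) {
  line1 <- if (arm == "nnrti") {
    list(n_pis = list(values = 0, probs = 1),
         doses = list(values = c(1, 2), probs = c(0.35, 0.65)),
         pills = list(values = c(2, 3, 4), probs = c(0.3, 0.5, 0.2)))
  } else {
    list(n_pis = list(values = c(1, 2), probs = c(0.9, 0.1)),
         doses = list(values = c(1, 2), probs = c(0.15, 0.85)),
         pills = list(values = c(4, 5, 6), probs = c(0.3, 0.5, 0.2)))
  }
  later <- list(n_pis = list(values = c(0, 1, 2), probs = c(0.2, 0.7, 0.1)),
                doses = list(values = c(1, 2, 3), probs = c(0.25, 0.6, 0.15)),
                pills = list(values = 2:6,
                             probs = c(0.15, 0.25, 0.3, 0.2, 0.1)))
  list(line1, later, later)
}

# Expected value of 1 / X when X follows the piecewise-linear quantile
# distribution fitted to (q1, median, q3); used to centre the rebound bounds.
.mean_inverse_qdist <- function(d) {
  ps <- d$p
  qs <- d$q
  tot <- 0
  for (i in seq_len(length(ps) - 1L)) {
    a <- qs[i]; b <- qs[i + 1L]; w <- ps[i + 1L] - ps[i]
    tot <- tot + if (abs(b - a) < 1e-12) w / a else w * log(b / a) / (b - a)
  }
  tot
}

#' Calibrate rebound bounds to a target rebound ratio
#'
#' Chooses uniform log10 viral-load rebound bounds of a given width whose
#' centre makes the expected ratio of rebound log10VL to baseline log10VL
#' equal to `target_ratio` under the arm's baseline viral-load distribution
#' (rebound and baseline are independent, so E\[U/V0\] = E\[U\] E\[1/V0\]).
#'
#' @param profile A [baseline_profile()].
#' @param target_ratio Target mean rebound-to-baseline ratio of log10 values.
#' @param width Width of the uniform support (log10 copies/mL).
#' @return `c(lo, hi)`.
#' @export
calibrate_rebound_bounds <- function(profile, target_ratio = 0.83,
                                     width = 1.0) {
  d <- quantile_distribution(profile$log10vl["median"],
                             profile$log10vl["q1"], profile$log10vl["q3"],
                             lower = profile$log10vl_support[1],
                             upper = profile$log10vl_support[2])
  centre <- target_ratio / .mean_inverse_qdist(d)
  c(centre - width / 2, centre + width / 2)
}

#' Default model parameters for one strategy arm
#'
#' The packaged base-case parameter bundle. Printed anchors (Weibull shapes,
#' event-time medians, unit costs, cost anchors, discount rate, toxicity
#' fraction, baseline characteristics) are encoded directly; quantities the
#' source cohort analyses left unreported (line-3 response curve, HIV-death
#' medians, AIDS-event model, later-line cost anchors, utilities, life table)
#' carry documented synthetic defaults - see the methods vignette.
#'
#' @param arm `"nnrti"` or `"pir"`.
#' @return A [model_parameters()] object.
#' @export
default_parameters <- function(arm = c("nnrti", "pir")) {
  arm <- match.arg(arm)
  profile <- default_baseline_profile(arm)
  ref <- .default_reference(arm)
  eff <- .default_event_effects()
  mk <- function(event, shape, median, effects = eff[[event]], floor = 0.1) {
    survival_spec(event, shape, median, effects = effects, reference = ref,
                  floor = floor)
  }
  events <- list(
    # lines 1-2 suppression: per-line baseline medians calibrated to the
    # line-wise attainment pattern (the printed line-2 shift is absorbed)
    viral_suppression = mk("viral_suppression", 1.030, c(7.0, 10.0)),
    # line-3 suppression is trial-based and unshifted by covariates
    viral_suppression_l3 = survival_spec("viral_suppression_l3", 1.03, 30),
    virological_failure_l12 = mk("virological_failure_l12", 1.447,
                                 c(66, 66 - 10.658)),
    virological_failure_l3 = mk("virological_failure_l3", 1.873, 30),
    regimen_switch = mk("regimen_switch", 1.499,
                        if (arm == "nnrti") c(80.4, 56.4, 57.8, 57.8)
                        else c(32.4, 56.4, 57.8, 57.8)),
    first_resistance = mk("first_resistance", 1.501, 336),
    resistance_class_switch = mk("resistance_class_switch", 1.524, 84),
    # recurrent inpatient events: a 12-month floor on the shifted median
    # caps the hospitalization rate in the most severe states
    hospitalization = mk("hospitalization", 0.733,
                         c(84, 84 - 34.5, 84 - 64.061, 84 - 64.061),
                         floor = 12))
  art_eff <- c(female = -0.029, age = 0.0001, log10vl = -0.030, cd4 = -0.0001,
               hcv = -0.015, year_init = 0.035, resistance_level = 0.039,
               prevfail1 = 0.028, prevfail2 = 0.307)
  nonart_eff <- c(female = 0.046, age = 0.0001, log10vl = 0.028,
                  cd4 = -0.0001, hcv = 0.020, adherence_pct = 0.010,
                  year_init = 0.042, resistance_level = 0.021,
                  prevfail1 = 0.0001, prevfail2 = 0.166)
  art_anchor1 <- if (arm == "nnrti") 613 else 1057
  shared_art <- sqrt(613 * 1057)              # later lines shared across arms
  costs <- cost_parameters(
    art_glm = list(anchors = c(art_anchor1, shared_art * exp(0.028),
                               shared_art * exp(0.056), NA),
                   effects = art_eff),
    nonart_glm = list(anchors = c(if (arm == "nnrti") 63 else 98,
                                  90, 150, 200),
                      effects = nonart_eff))
  adh <- adherence_model(
    effects_pp = c(female = 1.4, age = 0.1, hcv = -1.0, n_pis = -1.2,
                   regimen_number = -1.6, line2 = -1.7, line3 = -3.1,
                   doses1 = 1.8, doses3 = -2.5, pills = 0.001,
                   art_years = -0.01, art_cost = 0.001),
    reference = ref, p_ref = 0.88)
  traj <- trajectory_spec(
    cd4_a = c(28, 24, 21) / log(1 + 0.2 * 12),
    cd4_b = c(0.2, 0.2, 0.2),
    nonsupp_decline = 17)
  model_parameters(
    arm = arm, baseline = profile, events = events,
    hiv_death = list(shape = c(non_aids = 1.4, aids = 1.1),
                     median = c(non_aids = 396, aids = 288)),
    aids_event = list(shape = 1.2, cd4_breaks = c(100, 200),
                      median_by_cd4 = c(48, 96, 192),
                      transmission_multiplier = c(hetero = 1, idu = 0.85,
                                                  homosexual = 1.1,
                                                  other = 0.95)),
    trajectory = traj, costs = costs, utilities = utility_table(),
    adherence = adh,
    rebound_bounds = calibrate_rebound_bounds(profile),
    regimen_tables = .default_regimen_tables(arm),
    life_table = default_life_table(),
    reference = ref)
}

# ---- serialization --------------------------------------------------------

.spec_to_list <- function(s) {
  list(event = s$event, shape = s$shape, median = as.numeric(s$median),
       effects = as.list(s$effects), reference = as.list(s$reference),
       floor = s$floor, strata = s$strata)
}

.spec_from_list <- function(x) {
  survival_spec(x$event, x$shape, unlist(x$median),
                effects = unlist(x$effects),
                reference = unlist(x$reference),
                floor = x$floor, strata = x$strata)
}

#' Write model parameters to a configuration file
#'
#' Serializes one or several [model_parameters()] bundles to YAML or JSON
#' (chosen by file extension). [load_parameters()] restores them.
#'
#' @param params A `model_parameters` object or a named list of them (one per
#'   arm).
#' @param path Output file (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  if (inherits(params, "model_parameters")) {
    params <- setNames(list(params), params$arm)
  }
  ser <- lapply(params, function(p) {
    list(arm = p$arm,
         baseline = .profile_to_list(p$baseline),
         events = lapply(p$events, .spec_to_list),
         hiv_death = lapply(p$hiv_death, as.list),
         aids_event = list(shape = p$aids_event$shape,
                           cd4_breaks = p$aids_event$cd4_breaks,
                           median_by_cd4 = p$aids_event$median_by_cd4,
                           transmission_multiplier =
                             as.list(p$aids_event$transmission_multiplier)),
         trajectory = unclass(p$trajectory),
         costs = list(
           discount_rate = p$costs$discount_rate,
           line_switch_cost = p$costs$line_switch_cost,
           regimen_switch_cost = p$costs$regimen_switch_cost,
           adverse_event_cost_2005 = p$costs$adverse_event_cost_2005,
           inflation_factor_2005_to_2009 =
             p$costs$inflation_factor_2005_to_2009,
           aids_event_cost = p$costs$aids_event_cost,
           hospitalization_cost = p$costs$hospitalization_cost,
           art_glm = list(anchors = p$costs$art_glm$anchors,
                          effects = as.list(p$costs$art_glm$effects)),
           nonart_glm = list(anchors = p$costs$nonart_glm$anchors,
                             effects = as.list(p$costs$nonart_glm$effects)),
           nonsupp_art_lognormal = p$costs$nonsupp_art_lognormal),
         utilities = unclass(p$utilities),
         adherence = list(effects_pp = as.list(p$adherence$effects_pp),
                          reference = as.list(p$adherence$reference),
                          p_ref = p$adherence$p_ref),
         rebound_bounds = p$rebound_bounds,
         resistance_bounds = p$resistance_bounds,
         triangular = p$triangular,
         toxicity_p = p$toxicity_p,
         suppression_deadline = p$suppression_deadline,
         line3_suppression_window = p$line3_suppression_window,
         detect_floor = p$detect_floor,
         regimen_tables = p$regimen_tables,
         life_table = as.list(p$life_table),
         reference = as.list(p$reference),
         max_lines = p$max_lines, cd4_cap = p$cd4_cap, age_cap = p$age_cap)
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(ser, path, precision = 15L)
  }
  invisible(path)
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML or JSON configuration written by [write_parameters()] (or by
#' hand in the same layout), applies documented defaults for absent optional
#' fields and validates every invariant.
#'
#' @param path Configuration file path.
#' @return A named list of [model_parameters()] objects, one per arm.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(raw, function(x) {
    fix_tab <- function(tabs) lapply(tabs, function(tab) {
      lapply(tab, function(t) list(values = as.numeric(unlist(t$values)),
                                   probs = as.numeric(unlist(t$probs))))
    })
    model_parameters(
      arm = x$arm,
      baseline = .profile_from_list(x$baseline),
      events = lapply(x$events, .spec_from_list),
      hiv_death = list(shape = unlist(x$hiv_death$shape),
                       median = unlist(x$hiv_death$median)),
      aids_event = list(shape = x$aids_event$shape,
                        cd4_breaks = as.numeric(unlist(x$aids_event$cd4_breaks)),
                        median_by_cd4 =
                          as.numeric(unlist(x$aids_event$median_by_cd4)),
                        transmission_multiplier =
                          unlist(x$aids_event$transmission_multiplier)),
      trajectory = trajectory_spec(
        cd4_a = as.numeric(unlist(x$trajectory$cd4_a)),
        cd4_b = as.numeric(unlist(x$trajectory$cd4_b)),
        nonsupp_decline = x$trajectory$nonsupp_decline,
        vl_a = as.numeric(unlist(x$trajectory$vl_a)),
        vl_b = as.numeric(unlist(x$trajectory$vl_b))),
      costs = cost_parameters(
        discount_rate = x$costs$discount_rate,
        line_switch_cost = x$costs$line_switch_cost,
        regimen_switch_cost = x$costs$regimen_switch_cost,
        adverse_event_cost_2005 = x$costs$adverse_event_cost_2005,
        inflation_factor_2005_to_2009 =
          x$costs$inflation_factor_2005_to_2009,
        aids_event_cost = x$costs$aids_event_cost,
        hospitalization_cost = x$costs$hospitalization_cost,
        art_glm = list(anchors = as.numeric(unlist(x$costs$art_glm$anchors)),
                       effects = unlist(x$costs$art_glm$effects)),
        nonart_glm = list(
          anchors = as.numeric(unlist(x$costs$nonart_glm$anchors)),
          effects = unlist(x$costs$nonart_glm$effects)),
        nonsupp_art_lognormal =
          as.numeric(unlist(x$costs$nonsupp_art_lognormal))),
      utilities = utility_table(
        breaks = as.numeric(unlist(x$utilities$breaks)),
        unsuppressed = as.numeric(unlist(x$utilities$unsuppressed)),
        suppressed = as.numeric(unlist(x$utilities$suppressed))),
      adherence = adherence_model(
        effects_pp = unlist(x$adherence$effects_pp),
        reference = unlist(x$adherence$reference),
        p_ref = x$adherence$p_ref),
      rebound_bounds = as.numeric(unlist(x$rebound_bounds)),
      resistance_bounds = as.numeric(unlist(x$resistance_bounds)),
      triangular = as.numeric(unlist(x$triangular)),
      toxicity_p = x$toxicity_p,
      suppression_deadline = x$suppression_deadline,
      line3_suppression_window = x$line3_suppression_window,
      detect_floor = x$detect_floor,
      regimen_tables = fix_tab(x$regimen_tables),
      life_table = data.frame(age = as.numeric(unlist(x$life_table$age)),
                              sex = as.character(unlist(x$life_table$sex)),
                              qx = as.numeric(unlist(x$life_table$qx)),
                              stringsAsFactors = FALSE),
      reference = unlist(x$reference),
      max_lines = x$max_lines, cd4_cap = x$cd4_cap, age_cap = x$age_cap)
  })
  names(out) <- vapply(out, function(p) p$arm, character(1))
  out
}

#' Resolved parameter table for audit
#'
#' Flattens the event-time models of one arm into a data frame (event, line,
#' shape, baseline median, calibrated scale) suitable for CSV export.
#'
#' @param params A [model_parameters()] object.
#' @param path Optional CSV output path.
#' @return The data frame, invisibly if `path` is given.
#' @export
resolved_parameter_table <- function(params, path = NULL) {
  rows <- do.call(rbind, lapply(params$events, function(s) {
    med <- s$median
    data.frame(event = s$event, line = seq_along(med), shape = s$shape,
               median_months = as.numeric(med),
               scale_months = calibrate_weibull_scale(s$shape,
                                                      as.numeric(med)),
               stringsAsFactors = FALSE)
  }))
  rows <- rbind(rows, data.frame(
    event = c("hiv_death_non_aids", "hiv_death_aids"),
    line = NA_integer_,
    shape = as.numeric(params$hiv_death$shape),
    median_months = as.numeric(params$hiv_death$median),
    scale_months = calibrate_weibull_scale(
      as.numeric(params$hiv_death$shape),
      as.numeric(params$hiv_death$median)),
    stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  if (!is.null(path)) {
    write.csv(rows, path, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
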