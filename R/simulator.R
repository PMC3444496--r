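# Drives individuals from ART initiation to death (C++ engine) and
# aggregates cohorts per strategy arm.

.spec_beta <- function(spec) {
  beta <- setNames(rep(0, length(.COVARIATES)), .COVARIATES)
  if (length(spec$effects) > 0L) beta[names(spec$effects)] <- spec$effects
  # per-line baseline medians absorb line effects
  beta[c("line2", "line3")] <- 0
  unname(beta)
}

.spec_flat <- function(spec) {
  med <- as.numeric(spec$median)
  med <- c(med, rep(med[length(med)], 4L - length(med)))[1:4]
  list(shape = spec$shape, med = med, beta = .spec_beta(spec),
       floor = spec$floor)
}

.glm_beta <- function(glm) {
  beta <- setNames(rep(0, length(.COVARIATES)), .COVARIATES)
  if (length(glm$effects) > 0L) beta[names(glm$effects)] <- glm$effects
  beta[c("line2", "line3")] <- 0
  unname(beta)
}

# Flatten a model_parameters bundle into the plain list the C++ engine reads.
.flatten_parameters <- function(p) {
  ref <- setNames(rep(0, length(.COVARIATES)), .COVARIATES)
  ref[names(p$reference)] <- p$reference
  adh_beta <- setNames(rep(0, length(.COVARIATES)), .COVARIATES)
  adh_beta[names(p$adherence$beta)] <- p$adherence$beta
  tm <- p$aids_event$transmission_multiplier
  list(
    ref = unname(ref),
    supp12 = .spec_flat(p$events$viral_suppression),
    supp3 = .spec_flat(p$events$viral_suppression_l3),
    vf12 = .spec_flat(p$events$virological_failure_l12),
    vf3 = .spec_flat(p$events$virological_failure_l3),
    rswitch = .spec_flat(p$events$regimen_switch),
    firstres = .spec_flat(p$events$first_resistance),
    classsw = .spec_flat(p$events$resistance_class_switch),
    hosp = .spec_flat(p$events$hospitalization),
    death_shape = unname(as.numeric(p$hiv_death$shape)),
    death_med = unname(as.numeric(p$hiv_death$median)),
    aids_shape = p$aids_event$shape,
    aids_med = as.numeric(p$aids_event$median_by_cd4),
    aids_breaks = as.numeric(p$aids_event$cd4_breaks),
    aids_mult = as.numeric(tm[c("hetero", "idu", "homosexual", "other")]),
    adh_beta = unname(adh_beta),
    art_loganchor = log(p$costs$art_glm$anchors[1:3]),
    art_beta = .glm_beta(p$costs$art_glm),
    nonart_loganchor = log(p$costs$nonart_glm$anchors[1:4]),
    nonart_beta = .glm_beta(p$costs$nonart_glm),
    ns_meanlog = p$costs$nonsupp_art_lognormal[1],
    ns_sdlog = p$costs$nonsupp_art_lognormal[2],
    util_breaks = p$utilities$breaks,
    util_unsupp = p$utilities$unsuppressed,
    util_supp = p$utilities$suppressed,
    cd4_a = p$trajectory$cd4_a,
    cd4_b = p$trajectory$cd4_b,
    ns_decline = p$trajectory$nonsupp_decline,
    rate = p$costs$discount_rate,
    c_line = p$costs$line_switch_cost,
    c_reg = p$costs$regimen_switch_cost,
    c_ae = p$costs$adverse_event_cost_2005 *
      p$costs$inflation_factor_2005_to_2009,
    c_aids = p$costs$aids_event_cost,
    c_hosp = p$costs$hospitalization_cost,
    tox_p = p$toxicity_p,
    deadline = p$suppression_deadline,
    l3window = p$line3_suppression_window,
    reb_lo = p$rebound_bounds[1],
    reb_hi = p$rebound_bounds[2],
    vfloor = p$detect_floor,
    medfloor = p$events$viral_suppression$floor,
    cd4cap = p$cd4_cap,
    age_cap = p$age_cap,
    res_bounds = p$resistance_bounds,
    tri = p$triangular,
    regimen_tables = p$regimen_tables[1:3])
}

.TRANS_CODE <- c(hetero = 0, idu = 1, homosexual = 2, other = 3)

.baseline_matrix <- function(state) {
  cbind(female = state$female,
        age = state$age,
        hcv = state$hcv,
        trans = unname(.TRANS_CODE[state$transmission]),
        aids = state$aids,
        cd4 = state$cd4,
        log10vl = state$log10vl,
        adherence = state$adherence,
        res_level = state$resistance_level,
        res_class = state$resistance_class,
        year_init = state$year_init,
        n_pis = state$n_pis,
        doses = state$doses_per_day,
        pills = state$pills_per_day,
        nonhiv_months = pmax((state$nonhiv_death_age - state$age) * 12, 0))
}

.OUTCOME_NAMES <- c(
  "life_months", "ly_disc", "ly_undisc", "qaly_disc", "qaly_undisc",
  "art_disc", "art_undisc", "nonart_disc", "nonart_undisc",
  "event_disc", "event_undisc", "n_regimen_switch", "n_line_switch",
  "n_hospitalization", "n_aids_event", "n_fail_after_supp", "n_fail_no_supp",
  "months_l1", "months_l2", "months_l3", "months_l4",
  "supp_l1", "supp_l2", "supp_l3", "reach_l2", "reach_l3", "reach_nonsupp",
  "death_hiv", "final_res_class", "final_cd4", "final_regimen_number",
  "n_toxicity_switch")

.EVENT_LABELS <- c("nonhiv_death", "hiv_death", "aids_event", "deadline",
                   "virological_failure", "resistance", "regimen_switch",
                   "hospitalization", "viral_suppression")

.run_engine <- function(params, baseline, seed, trace = FALSE) {
  res <- .sim_cohort_cpp(.flatten_parameters(params),
                         .baseline_matrix(baseline), as.integer(seed),
                         isTRUE(trace))
  out <- as.data.frame(res$outcomes)
  names(out) <- .OUTCOME_NAMES
  out$total_disc <- out$art_disc + out$nonart_disc + out$event_disc
  out$total_undisc <- out$art_undisc + out$nonart_undisc + out$event_undisc
  if (isTRUE(trace)) {
    tr <- res$trace
    tr$event <- .EVENT_LABELS[tr$event + 1L]
    attr(out, "trace") <- tr
  }
  out
}

#' Simulate one individual lifetime
#'
#' Runs a single patient through the discrete-event engine: at every
#' decision point candidate times for all admissible events are drawn from
#' their conditional Weibull distributions, the earliest fires, state and
#' ledger are updated, and the loop repeats until death (non-HIV death and
#' an age cap act as competing risks). Deterministic given `(params,
#' baseline, seed)`.
#'
#' @param params A [model_parameters()].
#' @param baseline One-row `patient_state` data frame
#'   (see [sample_baseline()]).
#' @param seed Integer RNG substream seed.
#' @return List of class `individual_outcome` with elements `outcome`
#'   (one-row data frame of ledger totals and event counts) and `trace`
#'   (per-event log: intervals, state, accrual rates, event, cost).
#' @export
simulate_individual <- function(params, baseline, seed = 1L) {
  stopifnot(nrow(baseline) == 1L)
  out <- .run_engine(params, baseline, seed, trace = TRUE)
  structure(list(outcome = out, trace = attr(out, "trace")),
            class = "individual_outcome")
}

#' Simulate a cohort for one strategy arm
#'
#' Samples `n` baseline patients from the arm's profile (R RNG, seeded with
#' `seed`) and simulates each on an independent substream derived from
#' `(seed, index)`. The same seed always reproduces the same summary
#' bit-for-bit.
#'
#' @param params A [model_parameters()].
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param keep_individuals Keep the per-individual outcome data frame?
#' @return A `cohort_summary`: arm, n, means and standard errors of every
#'   outcome component, percent attaining suppression per line and percent
#'   reaching each line.
#' @export
simulate_cohort <- function(params, n, seed = 1L, keep_individuals = FALSE) {
  stopifnot(n >= 1L)
  set.seed(seed)
  baseline <- sample_baseline(params$baseline, n, params = params)
  out <- .run_engine(params, baseline, seed)
  summarize_cohort(out, arm = params$arm,
                   keep_individuals = keep_individuals)
}

#' Summarize per-individual outcomes into a cohort summary
#'
#' @param outcomes Per-individual outcome data frame from the engine.
#' @param arm Arm label.
#' @param keep_individuals Attach the individual rows?
#' @return A `cohort_summary`.
#' @export
summarize_cohort <- function(outcomes, arm = "nnrti",
                             keep_individuals = FALSE) {
  n <- nrow(outcomes)
  num <- outcomes[vapply(outcomes, is.numeric, logical(1))]
  means <- vapply(num, mean, numeric(1))
  ses <- vapply(num, function(x) stats::sd(x) / sqrt(n), numeric(1))
  pct_supp <- c(
    l1 = 100 * mean(outcomes$supp_l1),
    l2 = if (any(outcomes$reach_l2 == 1))
      100 * mean(outcomes$supp_l2[outcomes$reach_l2 == 1]) else NA_real_,
    l3 = if (any(outcomes$reach_l3 == 1))
      100 * mean(outcomes$supp_l3[outcomes$reach_l3 == 1]) else NA_real_)
  pct_reach <- c(l2 = 100 * mean(outcomes$reach_l2),
                 l3 = 100 * mean(outcomes$reach_l3),
                 nonsupp = 100 * mean(outcomes$reach_nonsupp))
  s <- structure(list(arm = arm, n = n, mean = means, se = ses,
                      pct_suppression = pct_supp,
                      pct_reach = pct_reach,
                      total_cost = unname(means["total_disc"]),
                      total_cost_undisc = unname(means["total_undisc"]),
                      life_years = unname(means["ly_disc"]),
                      life_years_undisc = unname(means["ly_undisc"]),
                      qalys = unname(means["qaly_disc"]),
                      qalys_undisc = unname(means["qaly_undisc"])),
                 class = "cohort_summary")
  if (keep_individuals) s$individuals <- outcomes
  s
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: arm %s, n = %d\n", x$arm, x$n))
  cat(sprintf("  Discounted: cost %.0f EUR, LY %.2f, QALY %.2f\n",
              x$total_cost, x$life_years, x$qalys))
  cat(sprintf("  Undiscounted: cost %.0f EUR, LY %.2f, QALY %.2f\n",
              x$total_cost_undisc, x$life_years_undisc, x$qalys_undisc))
  cat(sprintf("  %% attaining suppression by line: %.1f / %.1f / %.1f\n",
              x$pct_suppression[1], x$pct_suppression[2],
              x$pct_suppression[3]))
  cat(sprintf("  %% reaching line 2 / 3 / non-suppressive: %.1f / %.1f / %.1f\n",
              x$pct_reach[1], x$pct_reach[2], x$pct_reach[3]))
  invisible(x)
}

#' Percent difference against a comparator
#'
#' `100 * (a - b) / b`, the convention used for arm contrasts (comparator
#' in the denominator).
#'
#' @param a,b Numeric values (intervention, comparator).
#' @return Percent difference(s).
#' @export
percent_difference <- function(a, b) 100 * (a - b) / b

#' Compare two strategies
#'
#' Incremental cost-effectiveness statistics for strategy `a` against
#' comparator `b`: differences in cost, life-years and QALYs; dominance
#' classification (dominant if `a` costs less and yields more effect,
#' dominated if the reverse); ICERs where defined (`NA` with a zero effect
#' difference); and percent differences with `b` as denominator.
#'
#' @param a,b `cohort_summary` objects, or lists with elements `total_cost`,
#'   `life_years` and `qalys` (e.g. published per-arm table values).
#' @return An `incremental_result` list with `delta_cost`, `delta_ly`,
#'   `delta_qaly`, `icer_ly`, `icer_qaly`, `classification` and
#'   `pct_cost`.
#' @export
compare_strategies <- function(a, b) {
  gv <- function(x, f) {
    v <- x[[f]]
    if (is.null(v)) stop("missing field ", f, call. = FALSE)
    as.numeric(v)
  }
  dc <- gv(a, "total_cost") - gv(b, "total_cost")
  dly <- gv(a, "life_years") - gv(b, "life_years")
  dq <- gv(a, "qalys") - gv(b, "qalys")
  classification <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else {
    "icer"
  }
  icer <- function(de) {
    if (classification != "icer") return(NA_real_)
    if (de == 0) return(NA_real_)  # undefined, not a division error
    dc / de
  }
  structure(list(delta_cost = dc, delta_ly = dly, delta_qaly = dq,
                 icer_ly = icer(dly), icer_qaly = icer(dq),
                 classification = classification,
                 pct_cost = percent_difference(gv(a, "total_cost"),
                                               gv(b, "total_cost"))),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental result: dCost %.0f EUR, dLY %.3f, dQALY %.3f\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  if (x$classification == "icer") {
    cat(sprintf("  ICER: %.0f EUR/LY, %.0f EUR/QALY\n", x$icer_ly,
                x$icer_qaly))
  } else {
    cat("  Classification:", x$classification, "\n")
  }
  invisible(x)
}
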