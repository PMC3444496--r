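# Second-order (parameter) uncertainty: prior sampling, probabilistic
# sensitivity analysis with common random numbers across arms, dominance
# fractions, cost-effectiveness acceptability curves and table rendering.

.PRIOR_TARGETS <- c(
  "median_viral_suppression", "median_viral_suppression_l3",
  "median_virological_failure_l12", "median_virological_failure_l3",
  "median_regimen_switch", "median_first_resistance",
  "median_resistance_class_switch", "median_hospitalization",
  "median_hiv_death", "median_aids_event",
  "anchor_art", "anchor_nonart",
  "cost_line_switch", "cost_regimen_switch", "cost_adverse_event",
  "cost_aids_event", "cost_hospitalization",
  "toxicity_p", "rebound_centre", "cd4_rate", "nonsupp_decline",
  "utility_scale")

#' Prior set for probabilistic sensitivity analysis
#'
#' Each row names an uncertain quantity and its sampling distribution.
#' Multiplicative targets (event-time medians, cost anchors, CD4 rates,
#' utilities) take `lognormal` priors on the multiplier (hyper-parameters:
#' meanlog, sdlog); probabilities take `beta` priors (shape1, shape2);
#' `rebound_centre` takes a `normal` additive shift (mean, sd). Family
#' `fixed` pins the base-case value (degenerate prior). Draws are truncated
#' to `[lo, hi]`.
#'
#' @param name Target names; see `artpath:::.PRIOR_TARGETS`.
#' @param family `"lognormal"`, `"normal"`, `"beta"` or `"fixed"`.
#' @param p1,p2 Hyper-parameters.
#' @param lo,hi Truncation bounds on the drawn multiplier/shift/value.
#' @return A `prior_set` data frame.
#' @export
prior_set <- function(name, family, p1 = 0, p2 = 0, lo = -Inf, hi = Inf) {
  unknown <- setdiff(name, .PRIOR_TARGETS)
  if (length(unknown) > 0L) {
    stop("unknown prior target(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- !family %in% c("lognormal", "normal", "beta", "fixed")
  if (any(bad)) stop("unknown prior family", call. = FALSE)
  structure(data.frame(name = name, family = family, p1 = p1, p2 = p2,
                       lo = lo, hi = hi, stringsAsFactors = FALSE),
            class = c("prior_set", "data.frame"))
}

#' Default PSA priors
#'
#' Lognormal multipliers (sd 0.1 on the log scale) on every event-time
#' median and cost anchor, a beta prior on the toxicity fraction centred at
#' 0.54, a normal shift on the rebound centre, and lognormal multipliers on
#' the CD4 trajectory rates and the utility scale (truncated so utilities
#' stay in \[0, 1\]).
#'
#' @return A [prior_set()].
#' @export
default_priors <- function() {
  med <- c("median_viral_suppression", "median_viral_suppression_l3",
           "median_virological_failure_l12", "median_virological_failure_l3",
           "median_regimen_switch", "median_first_resistance",
           "median_resistance_class_switch", "median_hospitalization",
           "median_hiv_death", "median_aids_event")
  rbind(
    prior_set(med, "lognormal", p1 = 0, p2 = 0.1, lo = 0.5, hi = 2),
    prior_set(c("anchor_art", "anchor_nonart"), "lognormal", 0, 0.1,
              lo = 0.5, hi = 2),
    prior_set(c("cost_line_switch", "cost_regimen_switch",
                "cost_adverse_event", "cost_aids_event",
                "cost_hospitalization"), "lognormal", 0, 0.1,
              lo = 0.5, hi = 2),
    prior_set("toxicity_p", "beta", 54, 46, lo = 0, hi = 1),
    prior_set("rebound_centre", "normal", 0, 0.1, lo = -0.5, hi = 0.5),
    prior_set(c("cd4_rate", "nonsupp_decline"), "lognormal", 0, 0.1,
              lo = 0.5, hi = 2),
    prior_set("utility_scale", "lognormal", 0, 0.03, lo = 0.8, hi = 1.05))
}

.draw_prior <- function(row) {
  v <- switch(row$family,
              fixed = if (row$family == "fixed") {
                if (is.finite(row$p1) && row$p1 != 0) row$p1 else 1
              },
              lognormal = rlnorm(1, row$p1, row$p2),
              normal = rnorm(1, row$p1, row$p2),
              beta = rbeta(1, row$p1, row$p2))
  min(max(v, row$lo), row$hi)
}

.apply_draw <- function(p, name, v) {
  scale_util <- function(u) pmin(pmax(u * v, 0), 1)
  ev <- sub("^median_", "", name)
  if (grepl("^median_", name) && ev %in% names(p$events)) {
    p$events[[ev]]$median <- p$events[[ev]]$median * v
  } else if (name == "median_hiv_death") {
    p$hiv_death$median <- p$hiv_death$median * v
  } else if (name == "median_aids_event") {
    p$aids_event$median_by_cd4 <- p$aids_event$median_by_cd4 * v
  } else if (name == "anchor_art") {
    p$costs$art_glm$anchors <- p$costs$art_glm$anchors * v
    p$costs$nonsupp_art_lognormal[1] <-
      p$costs$nonsupp_art_lognormal[1] + log(v)
  } else if (name == "anchor_nonart") {
    p$costs$nonart_glm$anchors <- p$costs$nonart_glm$anchors * v
  } else if (name == "cost_line_switch") {
    p$costs$line_switch_cost <- p$costs$line_switch_cost * v
  } else if (name == "cost_regimen_switch") {
    p$costs$regimen_switch_cost <- p$costs$regimen_switch_cost * v
  } else if (name == "cost_adverse_event") {
    p$costs$adverse_event_cost_2005 <- p$costs$adverse_event_cost_2005 * v
  } else if (name == "cost_aids_event") {
    p$costs$aids_event_cost <- p$costs$aids_event_cost * v
  } else if (name == "cost_hospitalization") {
    p$costs$hospitalization_cost <- p$costs$hospitalization_cost * v
  } else if (name == "toxicity_p") {
    p$toxicity_p <- v
  } else if (name == "rebound_centre") {
    p$rebound_bounds <- p$rebound_bounds + v
  } else if (name == "cd4_rate") {
    p$trajectory$cd4_a <- p$trajectory$cd4_a * v
  } else if (name == "nonsupp_decline") {
    p$trajectory$nonsupp_decline <- p$trajectory$nonsupp_decline * v
  } else if (name == "utility_scale") {
    p$utilities$suppressed <- scale_util(p$utilities$suppressed)
    p$utilities$unsuppressed <- scale_util(p$utilities$unsuppressed)
  } else {
    stop("unhandled prior target: ", name, call. = FALSE)
  }
  p
}

#' Sample one parameter set from the priors
#'
#' Draws every uncertain parameter independently from its prior and applies
#' it to each arm's base-case bundle (the same draw is applied to both arms,
#' keeping shared parameters coherent). The result is re-validated; invalid
#' draws are resampled up to `max_tries` before erroring. With all priors
#' degenerate (`fixed`) the base case is returned exactly.
#'
#' @param priors A [prior_set()].
#' @param base Named list of base-case [model_parameters()] (one per arm).
#' @param max_tries Resampling cap for invalid draws.
#' @return Named list of perturbed `model_parameters`.
#' @export
sample_parameter_set <- function(priors, base, max_tries = 20L) {
  stopifnot(inherits(priors, "prior_set"))
  for (try in seq_len(max_tries)) {
    draws <- vapply(seq_len(nrow(priors)),
                    function(i) .draw_prior(priors[i, ]), numeric(1))
    out <- base
    ok <- TRUE
    for (arm in names(base)) {
      p <- base[[arm]]
      for (i in seq_len(nrow(priors))) {
        if (priors$family[i] == "fixed") next
        p <- .apply_draw(p, priors$name[i], draws[i])
      }
      v <- tryCatch({ validate_parameters(p); TRUE },
                    error = function(e) FALSE)
      if (!v) { ok <- FALSE; break }
      out[[arm]] <- p
    }
    if (ok) return(out)
  }
  stop("could not draw a valid parameter set in ", max_tries, " tries",
       call. = FALSE)
}

#' Run a probabilistic sensitivity analysis
#'
#' For each of `n_sets` parameter draws, both arms are simulated with common
#' random numbers (the same baseline seed and per-individual substreams) and
#' the incremental cost and QALY pair is recorded. Reproducible from
#' `base_seed`; parameter-set i uses seed `base_seed + i` for its cohorts.
#'
#' @param base Named list of base-case [model_parameters()] with elements
#'   `nnrti` and `pir` (deltas are `nnrti - pir`).
#' @param priors A [prior_set()].
#' @param n_sets Number of outer parameter draws.
#' @param n_individuals Individuals per arm per draw.
#' @param base_seed Integer seed.
#' @return A `psa_result`: data frame with `set`, `seed`, `delta_cost`,
#'   `delta_qaly`, `delta_ly`.
#' @export
run_psa <- function(base, priors = default_priors(), n_sets = 133L,
                    n_individuals = 50000L, base_seed = 1L) {
  stopifnot(n_sets >= 1L, n_individuals >= 1L,
            all(c("nnrti", "pir") %in% names(base)))
  set.seed(base_seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample_parameter_set(priors, base)
  })
  rows <- lapply(seq_len(n_sets), function(i) {
    seed_i <- base_seed + i
    a <- simulate_cohort(sets[[i]]$nnrti, n_individuals, seed = seed_i)
    b <- simulate_cohort(sets[[i]]$pir, n_individuals, seed = seed_i)
    data.frame(set = i, seed = seed_i,
               delta_cost = a$total_cost - b$total_cost,
               delta_qaly = a$qalys - b$qalys,
               delta_ly = a$life_years - b$life_years)
  })
  structure(do.call(rbind, rows), class = c("psa_result", "data.frame"))
}

#' Fraction of PSA draws where the strategy is dominant
#'
#' Fraction of `(delta_cost, delta_qaly)` pairs with negative incremental
#' cost and positive incremental QALYs.
#'
#' @param psa A `psa_result` (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @return Fraction in `[0, 1]`.
#' @export
proportion_dominant <- function(psa) {
  if (nrow(psa) == 0L) stop("empty PSA result", call. = FALSE)
  mean(psa$delta_cost < 0 & psa$delta_qaly > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit `lambda * delta_qaly - delta_cost`.
#'
#' @param psa A `psa_result`.
#' @param lambda Willingness-to-pay grid (euro/QALY, >= 0).
#' @return Data frame with `lambda` and `probability`.
#' @export
ceac <- function(psa, lambda = seq(0, 100000, by = 1000)) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  prob <- vapply(lambda, function(l) {
    mean(l * psa$delta_qaly - psa$delta_cost > 0)
  }, numeric(1))
  data.frame(lambda = lambda, probability = prob)
}

#' Render result tables to files
#'
#' Writes the clinical-outcome table (per-line suppression, lifetime event
#' counts, percent differences with the comparator as denominator), the
#' cost/effect table (discounted and undiscounted costs, life-years, QALYs,
#' increments and dominance/ICER) and, when a PSA result is supplied, the
#' acceptability curve, as CSV files.
#'
#' @param summary_a,summary_b `cohort_summary` objects (intervention,
#'   comparator).
#' @param incremental An `incremental_result` from [compare_strategies()].
#' @param out_dir Output directory (created if needed).
#' @param psa Optional `psa_result` for the CEAC file.
#' @param lambda CEAC grid.
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(summary_a, summary_b, incremental, out_dir,
                          psa = NULL, lambda = seq(0, 100000, by = 1000)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  }
  clin_fields <- c(supp_l1 = "pct_suppression_l1",
                   supp_l2 = "pct_suppression_l2",
                   supp_l3 = "pct_suppression_l3")
  clin <- data.frame(
    measure = c("pct_suppression_l1", "pct_suppression_l2",
                "pct_suppression_l3", "pct_reach_l2", "pct_reach_l3",
                "pct_reach_nonsupp", "regimen_switches", "hospitalizations",
                "virological_failures", "failures_after_suppression",
                "suppression_not_achieved"),
    a = c(summary_a$pct_suppression, summary_a$pct_reach,
          summary_a$mean[c("n_regimen_switch", "n_hospitalization")],
          summary_a$mean["n_fail_after_supp"] +
            summary_a$mean["n_fail_no_supp"],
          summary_a$mean[c("n_fail_after_supp", "n_fail_no_supp")]),
    b = c(summary_b$pct_suppression, summary_b$pct_reach,
          summary_b$mean[c("n_regimen_switch", "n_hospitalization")],
          summary_b$mean["n_fail_after_supp"] +
            summary_b$mean["n_fail_no_supp"],
          summary_b$mean[c("n_fail_after_supp", "n_fail_no_supp")]),
    stringsAsFactors = FALSE)
  clin$percent_difference <- percent_difference(clin$a, clin$b)
  names(clin)[2:3] <- c(summary_a$arm, summary_b$arm)
  f1 <- file.path(out_dir, "clinical_outcomes.csv")
  write.csv(clin, f1, row.names = FALSE)

  ce <- data.frame(
    measure = c("art_cost", "nonart_cost", "event_cost", "total_cost",
                "life_years", "qalys"),
    a_disc = c(summary_a$mean[c("art_disc", "nonart_disc", "event_disc")],
               summary_a$total_cost, summary_a$life_years, summary_a$qalys),
    b_disc = c(summary_b$mean[c("art_disc", "nonart_disc", "event_disc")],
               summary_b$total_cost, summary_b$life_years, summary_b$qalys),
    a_undisc = c(summary_a$mean[c("art_undisc", "nonart_undisc",
                                  "event_undisc")],
                 summary_a$total_cost_undisc, summary_a$life_years_undisc,
                 summary_a$qalys_undisc),
    b_undisc = c(summary_b$mean[c("art_undisc", "nonart_undisc",
                                  "event_undisc")],
                 summary_b$total_cost_undisc, summary_b$life_years_undisc,
                 summary_b$qalys_undisc),
    stringsAsFactors = FALSE)
  ce$delta_disc <- ce$a_disc - ce$b_disc
  ce$delta_undisc <- ce$a_undisc - ce$b_undisc
  f2 <- file.path(out_dir, "cost_effectiveness.csv")
  write.csv(ce, f2, row.names = FALSE)

  inc <- data.frame(
    measure = c("delta_cost", "delta_ly", "delta_qaly", "icer_ly",
                "icer_qaly", "classification", "pct_cost"),
    value = c(incremental$delta_cost, incremental$delta_ly,
              incremental$delta_qaly, incremental$icer_ly,
              incremental$icer_qaly, incremental$classification,
              incremental$pct_cost),
    stringsAsFactors = FALSE)
  f3 <- file.path(out_dir, "incremental.csv")
  write.csv(inc, f3, row.names = FALSE)

  files <- c(f1, f2, f3)
  if (!is.null(psa)) {
    cv <- ceac(psa, lambda)
    f4 <- file.path(out_dir, "ceac.csv")
    write.csv(cv, f4, row.names = FALSE)
    files <- c(files, f4)
  }
  invisible(files)
}
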