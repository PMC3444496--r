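# Build a one-row baseline at the arm's reference patient values.
reference_patient <- function(params, nonhiv_death_age = 105) {
  r <- params$reference
  data.frame(female = r[["female"]], age = r[["age"]], employed = 1,
             hcv = r[["hcv"]], transmission = "hetero", aids = 0,
             cd4 = r[["cd4"]], log10vl = r[["log10vl"]],
             adherence = r[["adherence_pct"]] / 100,
             resistance_level = 0, resistance_class = 1L,
             year_init = r[["year_init"]], nrti_pair = "AZT+3TC",
             third_agent = "EFV", line = 1L, regimen_number = 1L,
             suppressed = FALSE, n_failures = 0L,
             n_pis = r[["n_pis"]], doses_per_day = 2,
             pills_per_day = r[["pills"]],
             nonhiv_death_age = nonhiv_death_age,
             stringsAsFactors = FALSE)
}

test_that("identical seeds reproduce cohorts bit for bit", {
  a1 <- simulate_cohort(PN, 500, seed = 123)
  a2 <- simulate_cohort(PN, 500, seed = 123)
  expect_identical(a1$mean, a2$mean)
  expect_identical(a1$pct_suppression, a2$pct_suppression)
  b <- simulate_cohort(PN, 500, seed = 124)
  expect_false(identical(a1$mean, b$mean))
})

test_that("a non-HIV death scheduled at entry yields an empty lifetime", {
  bl <- reference_patient(PN, nonhiv_death_age = PN$reference[["age"]])
  r <- simulate_individual(PN, bl, seed = 1)
  o <- r$outcome
  expect_equal(o$life_months, 0)
  expect_equal(o$ly_undisc, 0)
  expect_equal(o$qaly_disc, 0)
  expect_equal(o$n_regimen_switch + o$n_line_switch + o$n_hospitalization +
                 o$n_aids_event, 0)
  expect_equal(o$death_hiv, 0)
})

test_that("a degenerate scenario reproduces a hand-computed ledger", {
  p <- PN
  # push all clinical events beyond the horizon; no discounting; utility 1
  for (nm in names(p$events)) p$events[[nm]]$median <-
      rep(1e6, length(p$events[[nm]]$median))
  p$hiv_death$median <- c(1e6, 1e6)
  p$aids_event$median_by_cd4 <- rep(1e6, 3)
  p$suppression_deadline <- 1e6
  p$line3_suppression_window <- 1e6
  p$costs$discount_rate <- 0
  p$utilities <- utility_table(unsuppressed = c(1, 1, 1),
                               suppressed = c(1, 1, 1))
  # non-HIV death exactly two years after ART initiation
  bl <- reference_patient(p, nonhiv_death_age = p$reference[["age"]] + 2)
  r <- simulate_individual(p, bl, seed = 5)
  o <- r$outcome
  expect_equal(o$life_months, 24)
  expect_equal(o$ly_undisc, 2)
  expect_equal(o$ly_disc, 2)           # rate 0: discounted == undiscounted
  expect_equal(o$qaly_undisc, 2)
  # single interval at the reference patient: anchors apply exactly
  expect_equal(o$art_undisc, 24 * 613)
  expect_equal(o$nonart_undisc, 24 * 63)
  expect_equal(o$event_undisc, 0)
  expect_equal(o$months_l1, 24)
  expect_equal(nrow(r$trace), 1L)
})

test_that("lifetime outcomes satisfy the structural invariants", {
  s <- simulate_cohort(PN, 4000, seed = 7, keep_individuals = TRUE)
  o <- s$individuals
  expect_true(all(o$n_line_switch <= 2))
  expect_equal(o$months_l1 + o$months_l2 + o$months_l3 + o$months_l4,
               o$life_months, tolerance = 1e-8)
  expect_true(all(o[, c("n_regimen_switch", "n_line_switch",
                        "n_hospitalization", "n_aids_event",
                        "n_fail_after_supp", "n_fail_no_supp")] >= 0))
  # effects: discounting and utilities can only shrink life-years
  expect_true(all(o$ly_disc <= o$ly_undisc + 1e-9))
  expect_true(all(o$qaly_disc <= o$ly_disc + 1e-9))
  expect_true(all(o$qaly_undisc <= o$ly_undisc + 1e-9))
  expect_true(all(o$art_disc <= o$art_undisc + 1e-9))
  expect_true(all(o$total_disc <= o$total_undisc + 1e-9))
  # no suppression can be attained beyond line 3; line-3 flags require
  # having reached the line
  expect_true(all(o$supp_l3 <= o$reach_l3))
  expect_true(all(o$supp_l2 <= o$reach_l2))
  expect_true(all(o$reach_l3 <= o$reach_l2))
  expect_true(all(o$reach_nonsupp <= o$reach_l3))
  expect_true(all(o$final_res_class %in% 1:4))
  # rate-0 conservation on a small cohort
  p0 <- PN; p0$costs$discount_rate <- 0
  s0 <- simulate_cohort(p0, 300, seed = 8, keep_individuals = TRUE)
  expect_equal(s0$individuals$total_disc, s0$individuals$total_undisc,
               tolerance = 1e-10)
  expect_equal(s0$individuals$ly_disc, s0$individuals$ly_undisc,
               tolerance = 1e-10)
})

test_that("the event trace replays to the engine ledger exactly", {
  set.seed(91)
  bl <- sample_baseline(PN$baseline, 20, params = PN)
  for (i in seq_len(10)) {
    r <- simulate_individual(PN, bl[i, ], seed = 200 + i)
    led <- replay_ledger(r$trace, PN)
    o <- r$outcome
    expect_equal(o$art_disc, led$art_disc, tolerance = 1e-9)
    expect_equal(o$nonart_disc, led$nonart_disc, tolerance = 1e-9)
    expect_equal(o$event_disc, led$event_disc, tolerance = 1e-9)
    expect_equal(o$qaly_disc, led$qaly_disc, tolerance = 1e-9)
    expect_equal(o$ly_undisc, led$ly_undisc, tolerance = 1e-9)
  }
})

test_that("disjoint seeds agree within Monte-Carlo error and SEs shrink with n", {
  s1 <- simulate_cohort(PN, 4000, seed = 11)
  s2 <- simulate_cohort(PN, 4000, seed = 9911)
  for (f in c("total_disc", "ly_undisc", "qaly_disc")) {
    se <- sqrt(s1$se[f]^2 + s2$se[f]^2)
    expect_lt(abs(s1$mean[f] - s2$mean[f]), 4 * se)
  }
  # quadrupling n roughly halves the standard error
  small <- simulate_cohort(PN, 1500, seed = 12)
  big <- simulate_cohort(PN, 6000, seed = 13)
  ratio <- small$se["total_disc"] / big$se["total_disc"]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("strategy comparison reproduces the published worked example", {
  a <- list(total_cost = 172742, life_years = 15.69, qalys = 11.84)
  b <- list(total_cost = 192315, life_years = 15.57, qalys = 11.70)
  inc <- compare_strategies(a, b)
  expect_equal(inc$delta_cost, -19573)
  expect_equal(inc$delta_qaly, 0.14, tolerance = 1e-9)
  expect_equal(inc$delta_ly, 0.12, tolerance = 1e-9)
  expect_equal(inc$classification, "dominant")
  expect_true(is.na(inc$icer_qaly))

  # identical strategies: zero deltas, undefined ICER
  same <- compare_strategies(a, a)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_true(is.na(same$icer_qaly))

  # equal effect, higher cost: undefined marker rather than a division error
  worse <- compare_strategies(list(total_cost = 100, life_years = 1,
                                   qalys = 1),
                              list(total_cost = 90, life_years = 1,
                                   qalys = 1))
  expect_true(is.na(worse$icer_qaly))
  expect_equal(worse$classification, "icer")

  # percent difference uses the comparator as denominator
  expect_equal(percent_difference(4.16, 5.02), 100 * (4.16 - 5.02) / 5.02)
  expect_lt(abs(percent_difference(4.16, 5.02) - (-17.2)), 0.1)
})
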