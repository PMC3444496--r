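base_pair <- list(nnrti = PN, pir = PP)

test_that("degenerate priors return the base case exactly", {
  priors <- default_priors()
  priors$family <- "fixed"
  set.seed(101)
  drawn <- sample_parameter_set(prior_set(priors$name, priors$family),
                                base_pair)
  expect_equal(drawn$nnrti, PN)
  expect_equal(drawn$pir, PP)
})

test_that("prior draws respect bounds and moments", {
  priors <- default_priors()
  set.seed(102)
  meds <- numeric(2000)
  for (i in seq_len(2000)) {
    row <- priors[priors$name == "median_regimen_switch", ]
    meds[i] <- artpath:::.draw_prior(row)
  }
  expect_true(all(meds >= 0.5 & meds <= 2))
  # lognormal multiplier: mean exp(sd^2/2) within 3 standard errors
  expect_lt(abs(mean(meds) - exp(0.1^2 / 2)),
            3 * sd(meds) / sqrt(length(meds)))

  set.seed(103)
  ps <- sample_parameter_set(priors, base_pair)
  validate_parameters(ps$nnrti)
  validate_parameters(ps$pir)
  # the same multiplier applies to both arms (coherent shared parameters)
  expect_equal(ps$nnrti$events$first_resistance$median /
                 PN$events$first_resistance$median,
               ps$pir$events$first_resistance$median /
                 PP$events$first_resistance$median)
  expect_true(all(ps$nnrti$utilities$suppressed <= 1))
})

test_that("PSA runs are reproducible and degenerate to base-case deltas", {
  priors <- default_priors()
  priors$family <- "fixed"
  fixed <- prior_set(priors$name, priors$family)
  r1 <- run_psa(base_pair, fixed, n_sets = 3, n_individuals = 300,
                base_seed = 5)
  r2 <- run_psa(base_pair, fixed, n_sets = 3, n_individuals = 300,
                base_seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3L)
  # with fixed parameters each set equals a direct paired evaluation
  for (i in 1:3) {
    a <- simulate_cohort(PN, 300, seed = 5 + i)
    b <- simulate_cohort(PP, 300, seed = 5 + i)
    expect_equal(r1$delta_cost[i], a$total_cost - b$total_cost)
    expect_equal(r1$delta_qaly[i], a$qalys - b$qalys)
  }
})

test_that("common random numbers stabilize the incremental estimates", {
  # same parameters in both arms with shared substreams: deltas are exactly 0
  r <- run_psa(list(nnrti = PN, pir = PN),
               prior_set("toxicity_p", "fixed"), n_sets = 2,
               n_individuals = 200, base_seed = 9)
  expect_true(all(r$delta_cost == 0))
  expect_true(all(r$delta_qaly == 0))

  # with a comparator that differs only in a cost parameter, paired seeds
  # pin the event histories and the delta is far less variable than with
  # disjoint seeds
  alt <- PN
  alt$costs$art_glm$anchors <- alt$costs$art_glm$anchors * 1.2
  paired <- vapply(1:6, function(i) {
    a <- simulate_cohort(PN, 400, seed = 300 + i)
    b <- simulate_cohort(alt, 400, seed = 300 + i)
    a$total_cost - b$total_cost
  }, numeric(1))
  disjoint <- vapply(1:6, function(i) {
    a <- simulate_cohort(PN, 400, seed = 400 + i)
    b <- simulate_cohort(alt, 400, seed = 500 + i)
    a$total_cost - b$total_cost
  }, numeric(1))
  expect_lt(var(paired), var(disjoint))
})

test_that("dominance fractions and CEAC match hand enumeration", {
  mk <- function(dc, dq) {
    structure(data.frame(set = seq_along(dc), seed = seq_along(dc),
                         delta_cost = dc, delta_qaly = dq,
                         delta_ly = dq),
              class = c("psa_result", "data.frame"))
  }
  all_dom <- mk(rep(-1, 5), rep(0.1, 5))
  expect_equal(proportion_dominant(all_dom), 1)
  expect_true(all(ceac(all_dom, c(0, 1e4, 1e5))$probability == 1))

  quad <- mk(c(-1, 1, -1, 1), c(1, 1, -1, -1))
  expect_equal(proportion_dominant(quad), 0.25)
  expect_equal(proportion_dominant(mk(c(1, 1), c(1, -1))), 0)
  expect_error(proportion_dominant(mk(numeric(0), numeric(0))), "empty")

  # lambda = 0 reduces to the sign of the cost difference
  expect_equal(ceac(quad, 0)$probability, mean(quad$delta_cost < 0))
  # hand enumeration of NMB = lambda dq - dc > 0 on a constructed set
  pts <- mk(c(-5000, 20000, 1000, -100), c(0.5, 1, -0.1, 0))
  for (l in c(0, 1e4, 1e5)) {
    expect_equal(ceac(pts, l)$probability,
                 mean(l * pts$delta_qaly - pts$delta_cost > 0))
  }
  expect_error(ceac(pts, -5), "lambda")

  # monotone in lambda whenever every delta-QALY is non-negative
  pos <- mk(c(-2, 3, 8, 1), c(0.1, 0.4, 0, 0.2))
  cv <- ceac(pos, seq(0, 1e5, by = 5000))
  expect_true(all(diff(cv$probability) >= 0))
  # dominant draws always have positive net benefit at positive lambda
  expect_lte(proportion_dominant(pos), min(ceac(pos, c(1, 1e4))$probability))
})

test_that("rendered tables are internally consistent", {
  a <- simulate_cohort(PN, 400, seed = 21)
  b <- simulate_cohort(PP, 400, seed = 21)
  inc <- compare_strategies(a, b)
  psa <- run_psa(base_pair,
                 prior_set("toxicity_p", "beta", 54, 46, 0, 1),
                 n_sets = 2, n_individuals = 100, base_seed = 31)
  out <- file.path(tempdir(), "artpath-tables")
  files <- render_tables(a, b, inc, out, psa = psa)
  expect_true(all(file.exists(file.path(
    out, c("clinical_outcomes.csv", "cost_effectiveness.csv",
           "incremental.csv", "ceac.csv")))))

  clin <- read.csv(file.path(out, "clinical_outcomes.csv"))
  expect_equal(clin$percent_difference,
               100 * (clin[[2]] - clin[[3]]) / clin[[3]])
  ce <- read.csv(file.path(out, "cost_effectiveness.csv"))
  expect_equal(ce$delta_disc, ce$a_disc - ce$b_disc)
  expect_equal(ce$delta_disc[ce$measure == "total_cost"], inc$delta_cost)
  unlink(out, recursive = TRUE)
})
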