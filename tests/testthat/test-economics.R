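test_that("monthly cost models hit the printed first-line anchors", {
  # reference patient pays exactly the anchor (all effects cancel)
  ref <- as.data.frame(reference_covariates(PN))
  expect_equal(monthly_art_cost(ref, PN, line = 1), 613)
  expect_equal(monthly_nonart_cost(ref, PN, line = 1), 63)
  refp <- as.data.frame(reference_covariates(PP))
  expect_equal(monthly_art_cost(refp, PP, line = 1), 1057)
  expect_equal(monthly_nonart_cost(refp, PP, line = 1), 98)

  # cohort medians stay near the anchors under baseline covariate spread
  set.seed(81)
  bn <- sample_baseline(PN$baseline, 2e4, params = PN)
  bp <- sample_baseline(PP$baseline, 2e4, params = PP)
  expect_equal(median(monthly_art_cost(bn, PN, line = 1)), 613,
               tolerance = 0.03)
  expect_equal(median(monthly_art_cost(bp, PP, line = 1)), 1057,
               tolerance = 0.03)
  expect_equal(median(monthly_nonart_cost(bn, PN, line = 1)), 63,
               tolerance = 0.04)
  expect_equal(median(monthly_nonart_cost(bp, PP, line = 1)), 98,
               tolerance = 0.04)
  expect_true(all(monthly_art_cost(bn, PN, line = 1) > 0))
})

test_that("event costs follow the unit-cost schedule", {
  cc <- PN$costs
  expect_equal(event_cost("line_switch", costs = cc), 582)
  expect_equal(event_cost("regimen_switch", "other", cc), 495)
  expect_equal(event_cost("regimen_switch", "toxicity", cc),
               495 + 1126 * cc$inflation_factor_2005_to_2009)
  expect_equal(event_cost("aids_event", costs = cc), 4765)
  expect_equal(event_cost("hospitalization", costs = cc), 4742)
  expect_equal(event_cost("viral_suppression", costs = cc), 0)
  expect_equal(event_cost("resistance", costs = cc), 0)
  expect_equal(event_cost("hiv_death", costs = cc), 0)
  expect_error(event_cost("teleportation", costs = cc), "unknown event")
})

test_that("non-suppressive daily ART cost is lognormal", {
  cz <- PN$costs
  cz$nonsupp_art_lognormal <- c(log(20), 0)
  expect_equal(nonsuppressive_daily_art_cost(cz, 5), rep(20, 5))
  set.seed(82)
  d <- nonsuppressive_daily_art_cost(PN$costs, 1e5)
  expect_true(all(d > 0))
  expect_equal(median(d), exp(PN$costs$nonsupp_art_lognormal[1]),
               tolerance = 0.01)
})

test_that("discounting follows discrete annual compounding", {
  expect_equal(discount(100, 5, 0), 100)                 # rate 0 identity
  expect_equal(discount(100, 1, 0.05), 100 / 1.05)       # 95.238...
  expect_equal(discount(100, 1, 0.05), 95.238, tolerance = 1e-4)
  expect_error(discount(1, -1, 0.05), "time")
  expect_error(discount(1, 1, -1.5), "rate")

  # piecewise mid-interval stream versus numeric integration
  rate <- 0.05
  ends <- seq(0, 20, by = 1 / 12)
  mids <- (ends[-1] + ends[-length(ends)]) / 2
  stream <- sum(diff(ends) * discount(1, mids, rate))
  oracle <- integrate(function(t) (1 + rate)^(-t), 0, 20,
                      rel.tol = 1e-10)$value
  expect_equal(stream, oracle, tolerance = 1e-3)
})

test_that("utility weighting and QALY accumulation are exact", {
  ut <- PN$utilities
  expect_equal(utility_weight(250, TRUE, ut), ut$suppressed[3])
  expect_equal(utility_weight(50, FALSE, ut), ut$unsuppressed[1])
  expect_equal(utility_weight(150, TRUE, ut), ut$suppressed[2])
  expect_error(utility_weight(-5, TRUE, ut), "cd4")
  expect_error(utility_table(breaks = c(200, 100)), "increasing")
  expect_error(utility_table(suppressed = c(0.5, 0.6, 1.2)), "\\[0, 1\\]")

  # all weights one: QALYs equal discounted life-years
  ones <- utility_table(unsuppressed = c(1, 1, 1), suppressed = c(1, 1, 1))
  iv <- data.frame(start = c(0, 2, 5), end = c(2, 5, 9),
                   cd4 = c(300, 150, 80), suppressed = c(TRUE, FALSE, FALSE))
  ly_disc <- sum((iv$end - iv$start) *
                   discount(1, (iv$start + iv$end) / 2, 0.05))
  expect_equal(accumulate_qalys(iv, ones, 0.05), ly_disc, tolerance = 1e-12)

  # single interval, weight 0.8, no discounting
  one <- data.frame(start = 0, end = 2, cd4 = 300, suppressed = TRUE)
  tab8 <- utility_table(unsuppressed = c(0.8, 0.8, 0.8),
                        suppressed = c(0.8, 0.8, 0.8))
  expect_equal(accumulate_qalys(one, tab8, 0), 1.6)

  # three-interval hand computation at 5%
  hand <- 2 * ut$suppressed[3] * 1.05^-1 +
    3 * ut$unsuppressed[2] * 1.05^-3.5 +
    4 * ut$unsuppressed[1] * 1.05^-7
  expect_equal(accumulate_qalys(iv, ut, 0.05), hand, tolerance = 1e-9)
})
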