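test_that("CD4 trajectories are anchored at zero and hit the yearly rates", {
  tr <- PN$trajectory
  expect_equal(cd4_change(1, 0, tr), 0)
  expect_equal(cd4_change(1, 12, tr), 28, tolerance = 1e-9)
  expect_equal(cd4_change(2, 12, tr), 24, tolerance = 1e-9)
  expect_equal(cd4_change(3, 12, tr), 21, tolerance = 1e-9)
  expect_equal(cd4_change("nonsuppressive", 12, tr), -17, tolerance = 1e-9)
  # monotone in dt on suppressive lines
  dts <- seq(0, 60, by = 6)
  expect_true(all(diff(cd4_change(1, dts, tr)) > 0))
  expect_equal(log10vl_change(1, 0, tr), 0)
})

test_that("suppression floors the viral load and rebound redraws it uniformly", {
  set.seed(71)
  st <- sample_baseline(PN$baseline, 2e4)
  v0 <- st$log10vl
  st <- apply_suppression(st)
  expect_true(all(st$log10vl == 1.69))
  expect_true(all(st$suppressed))

  st <- apply_rebound(st, PN$rebound_bounds)
  expect_true(all(st$log10vl >= PN$rebound_bounds[1] &
                    st$log10vl <= PN$rebound_bounds[2]))
  expect_false(any(st$suppressed))

  # rebound requires prior suppression
  expect_error(apply_rebound(st, PN$rebound_bounds), "without prior")
})

test_that("adherence updates through the logit link", {
  m <- PN$adherence
  # zero linear predictor sits at one half
  expect_equal(update_adherence(m, 0.5, reference_covariates(PN)), 0.5)

  # once-daily versus twice-daily dosing: about +1.8 points at reference
  ref <- reference_covariates(PN)
  cov1 <- ref; cov1$doses1 <- 1
  gain <- update_adherence(m, m$p_ref, cov1) -
    update_adherence(m, m$p_ref, ref)
  expect_lt(abs(100 * gain - 1.8), 0.2)

  # extreme covariates stay strictly inside (0, 1)
  covx <- ref
  covx$regimen_number <- 60; covx$line3 <- 1; covx$pills <- 40
  p <- update_adherence(m, 0.99, covx)
  expect_true(p > 0 && p < 1)
  p2 <- update_adherence(m, 0.01, covx)
  expect_true(p2 > 0 && p2 < 1)
})

test_that("resistance advances one class at a time and never decreases", {
  set.seed(72)
  st <- sample_baseline(PN$baseline, 1e5)
  st$resistance_class <- 1L
  st$resistance_level <- runif(1e5)
  up <- advance_resistance(st, PN)
  expect_true(all(up$resistance_class == 2L))
  expect_true(all(up$resistance_level >= 1 & up$resistance_level < 5))
  # draws uniform within the new class
  ks <- suppressWarnings(ks.test(up$resistance_level, "punif", 1, 5))
  expect_lt(ks$statistic, 0.01)

  up2 <- advance_resistance(up, PN)
  expect_true(all(up2$resistance_class == 3L))
  expect_lt(suppressWarnings(
    ks.test(up2$resistance_level, "punif", 5, 10)$statistic), 0.01)

  # class-4 updates are a max with a triangular draw: never decreasing
  st4 <- up2
  st4$resistance_class <- 4L
  st4$resistance_level <- runif(1e5, 10, 25)
  up4 <- advance_resistance(st4, PN)
  expect_true(all(up4$resistance_class == 4L))
  expect_true(all(up4$resistance_level >= st4$resistance_level))
  expect_true(all(up4$resistance_level <= 25))
})

test_that("line rules implement the switch / stay / non-suppressive logic", {
  mk <- function(line, cls) data.frame(line = line, resistance_class = cls)
  # line 1, 12 months, never suppressed -> line switch
  r <- evaluate_line_rules(mk(1, 1), "deadline", 12, PN)
  expect_equal(r, list(action = "line_switch",
                       cause = "failure_no_suppression"))
  r2 <- evaluate_line_rules(mk(2, 2), "virological_failure", 20, PN)
  expect_equal(r2$action, "line_switch")
  expect_equal(r2$cause, "failure_after_suppression")
  # line 3 failure below the top class: stay (regimen reshuffle)
  expect_equal(
    evaluate_line_rules(mk(3, 2), "virological_failure", 30, PN)$action,
    "regimen_switch")
  # top resistance class on line 3: non-suppressive therapy
  expect_equal(
    evaluate_line_rules(mk(3, 4), "virological_failure", 30, PN)$action,
    "enter_nonsuppressive")
  expect_equal(evaluate_line_rules(mk(3, 4), "resistance", 30, PN)$action,
               "enter_nonsuppressive")
  expect_equal(evaluate_line_rules(mk(1, 4), "resistance", 5, PN)$action,
               "stay")
  expect_error(evaluate_line_rules(mk(7, 1), "deadline", 1, PN),
               "inconsistent")
})

test_that("AIDS classification is permanent and uses a strict 200 threshold", {
  st <- data.frame(aids = 0L, cd4 = 199)
  expect_equal(classify_aids(st)$aids, 1L)
  st2 <- data.frame(aids = 1L, cd4 = 450)
  expect_equal(classify_aids(st2)$aids, 1L)          # absorbing
  st3 <- data.frame(aids = 0L, cd4 = 200)
  expect_equal(classify_aids(st3)$aids, 0L)          # strict inequality
  expect_equal(classify_aids(st3, aids_event = TRUE)$aids, 1L)
})

test_that("regimen characteristics and switch causes follow their tables", {
  degen <- list(list(n_pis = list(values = 1, probs = 1),
                     doses = list(values = 2, probs = 1),
                     pills = list(values = 4, probs = 1)))
  d <- draw_regimen_characteristics(1, degen, 10)
  expect_true(all(d$n_pis == 1 & d$doses_per_day == 2 & d$pills_per_day == 4))
  expect_error(draw_regimen_characteristics(1, list(NULL), 1), "no regimen")

  set.seed(73)
  n <- 1e5
  d2 <- draw_regimen_characteristics(2, PN$regimen_tables, n)
  tab <- PN$regimen_tables[[2]]
  for (i in seq_along(tab$n_pis$values)) {
    p <- tab$n_pis$probs[i]
    expect_lt(abs(mean(d2$n_pis == tab$n_pis$values[i]) - p),
              3 * sqrt(p * (1 - p) / n))
  }

  expect_true(all(assign_switch_cause(50, 1) == "toxicity"))
  expect_true(all(assign_switch_cause(50, 0) == "other"))
  set.seed(74)
  expect_lt(abs(mean(assign_switch_cause(1e5, 0.54) == "toxicity") - 0.54),
            0.005)
})
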