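test_that("quantile-matching distributions reproduce their anchors", {
  # printed log10VL anchors: 4.9 [4.3; 5.4]
  d <- quantile_distribution(4.9, 4.3, 5.4, lower = 2, upper = 6.5)
  expect_equal(qdist_quantile(d, c(0.25, 0.5, 0.75)), c(4.3, 4.9, 5.4),
               tolerance = 1e-9)
  set.seed(5)
  x <- qdist_sample(d, 1e5)
  q <- quantile(x, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(q - c(4.3, 4.9, 5.4))), 0.02)

  # degenerate anchors collapse to a point mass
  dd <- quantile_distribution(3, 3, 3)
  expect_true(all(qdist_sample(dd, 100) == 3))

  # uniform quartile anchors reproduce the uniform distribution
  du <- quantile_distribution(0.5, 0.25, 0.75, lower = 0, upper = 1)
  set.seed(6)
  u <- qdist_sample(du, 1e5)
  expect_lt(suppressWarnings(ks.test(u, "punif")$statistic), 0.01)

  expect_error(quantile_distribution(1, 2, 3), "q1 <= median")
  expect_error(quantile_distribution(4.9, 4.3, 5.4, lower = 4.5), "support")
})

test_that("baseline cohorts match the arm profiles marginally", {
  set.seed(31)
  n <- 1e5
  st <- sample_baseline(PN$baseline, n, params = PN)
  expect_equal(nrow(st), n)
  validate_patient_state(st)

  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(st$female) - 0.323), max(se3(0.323), 0.005))
  expect_lt(abs(mean(st$aids) - 0.322), max(se3(0.322), 0.005))
  expect_lt(abs(mean(st$hcv) - 0.298), se3(0.298))
  expect_lt(abs(mean(st$transmission == "idu") - 0.278), se3(0.278))
  expect_lt(abs(mean(st$third_agent == "EFV") - 0.64), se3(0.64))
  expect_lt(abs(mean(st$resistance_class == 2) - 0.0127), se3(0.0127))
  # resistance level consistent with the class bounds
  expect_true(all(st$resistance_level[st$resistance_class == 2] >= 1 &
                    st$resistance_level[st$resistance_class == 2] < 5))
  expect_true(all(st$resistance_level[st$resistance_class == 1] < 1))
  expect_equal(unname(quantile(st$log10vl, 0.5)), 4.9, tolerance = 0.02)
  expect_equal(unname(quantile(st$cd4, 0.5)), 234, tolerance = 2)
  expect_gt(min(st$nonhiv_death_age), min(st$age))

  # degenerate profile: identical deterministic patients
  pf <- baseline_profile(
    p_female = 0, age = c(40, 40, 40), p_employed = 0,
    log10vl = c(5, 5, 5), cd4 = c(300, 300, 300), p_hcv = 0,
    adherence_pct = c(90, 90, 90), year_init = 2004,
    nrti_table = list(values = "AZT+3TC", probs = 1),
    third_agent_table = list(values = "EFV", probs = 1),
    p_resistance_gt1 = 0,
    transmission_table = list(values = "hetero", probs = 1), p_aids = 0)
  lt0 <- data.frame(age = rep(0:105, 2),
                    sex = rep(c("male", "female"), each = 106), qx = 0)
  st2 <- sample_baseline(pf, 50, life_table = lt0)
  expect_equal(nrow(unique(st2[, c("female", "age", "cd4", "log10vl",
                                   "adherence", "aids")])), 1L)
})

test_that("non-HIV death ages follow the life table", {
  ages <- 0:105
  lt0 <- data.frame(age = rep(ages, 2),
                    sex = rep(c("male", "female"), each = length(ages)),
                    qx = 0)
  # zero hazard: survives to the cap
  expect_equal(sample_nonhiv_death_age(39, "male", lt0), 105)

  # constant annual q = 0.01 from 39: median extra years = log(.5)/log(.99)
  # (the table is extended far enough that the absorbing cap does not bind)
  lt1 <- data.frame(age = rep(0:400, 2),
                    sex = rep(c("male", "female"), each = 401), qx = 0.01)
  set.seed(41)
  d <- sample_nonhiv_death_age(rep(39, 1e5), "male", lt1)
  extra <- median(d) - 39
  expect_lt(abs(extra - log(0.5) / log(0.99)), 1)

  # certain death in the next year
  lt2 <- lt0; lt2$qx[lt2$age == 40] <- 1
  dd <- sample_nonhiv_death_age(rep(39.5, 200), "female", lt2)
  expect_true(all(dd > 39.5 & dd <= 41))

  expect_error(sample_nonhiv_death_age(200, "male", lt0), "beyond")
  # default synthetic table: increasing mortality, q in [0, 1]
  lt <- default_life_table()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_true(all(diff(lt$qx[lt$sex == "male"]) >= 0))
})
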