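test_that("Weibull scale calibration inverts the survival median", {
  # exponential identity: median ln 2 <=> scale 1
  expect_equal(calibrate_weibull_scale(1, log(2)), 1)

  # closed-form inversion agrees with a root-finding oracle
  for (case in list(c(1.499, 80.4), c(1.501, 336))) {
    shape <- case[1]; target <- case[2]
    scale <- calibrate_weibull_scale(shape, target)
    oracle <- uniroot(function(m) weibull_survival(m, shape, scale) - 0.5,
                      c(1e-6, 1e5), tol = 1e-10)$root
    expect_equal(oracle, target, tolerance = 1e-7)
    expect_equal(weibull_survival(target, shape, scale), 0.5,
                 tolerance = 1e-9)
  }

  # round trip property over random shapes and targets
  set.seed(11)
  for (i in 1:25) {
    shape <- runif(1, 0.3, 4)
    target <- runif(1, 0.5, 500)
    expect_equal(weibull_median(shape, calibrate_weibull_scale(shape, target)),
                 target, tolerance = 1e-9)
  }

  expect_error(calibrate_weibull_scale(0, 10), "positive")
  expect_error(calibrate_weibull_scale(1, -1), "positive")
})

test_that("covariate effects shift event-time medians additively", {
  spec <- PN$events$virological_failure_l12
  ref <- reference_covariates(PN)

  # reference patient recovers the baseline median
  expect_equal(shifted_median(spec, ref, line = 1), spec$median[1])

  # being female adds the printed +7.653 months
  cov_f <- ref; cov_f$female <- 1
  expect_equal(shifted_median(spec, cov_f, line = 1),
               spec$median[1] + 7.653)

  # sum of several shifts equals the term-by-term brute-force total
  cov3 <- ref
  cov3$female <- 1; cov3$log10vl <- ref$log10vl + 0.5; cov3$cd4 <- ref$cd4 + 100
  brute <- spec$median[1]
  for (nm in c("female", "log10vl", "cd4")) {
    brute <- brute + spec$effects[[nm]] * (cov3[[nm]] - spec$reference[[nm]])
  }
  expect_equal(shifted_median(spec, cov3, line = 1), brute)

  # missing covariates are reported by name
  expect_error(shifted_median(spec, list(female = 1)), "log10vl")

  # the positive floor prevents degenerate medians
  cov_x <- ref; cov_x$log10vl <- ref$log10vl + 10   # -19.563 x 10 months
  expect_equal(shifted_median(spec, cov_x, line = 1), spec$floor)
})

test_that("parameter bundles validate, serialize and round-trip", {
  # packaged defaults: both arms discounted at 5%
  expect_equal(PN$costs$discount_rate, 0.05)
  expect_equal(PP$costs$discount_rate, 0.05)

  # invariant violations are rejected with informative messages
  expect_error(cost_parameters(discount_rate = -0.1), "discount_rate")
  bad <- PN
  bad$resistance_bounds <- c(5, 1, 10, 25)
  expect_error(validate_parameters(bad), "strictly increasing")
  bad2 <- PN
  bad2$toxicity_p <- 1.2
  expect_error(validate_parameters(bad2), "toxicity_p")
  bad3 <- PN
  bad3$events$viral_suppression <- NULL
  expect_error(validate_parameters(bad3), "viral_suppression")
  expect_error(survival_spec("x", 1, 10, effects = c(not_a_cov = 1)),
               "unknown covariate")

  # write -> read identity for both formats
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("pars.", ext))
    write_parameters(list(nnrti = PN, pir = PP), path)
    back <- load_parameters(path)
    expect_equal(back$nnrti, PN, tolerance = 1e-8)
    expect_equal(back$pir, PP, tolerance = 1e-8)
    unlink(path)
  }
  expect_error(load_parameters("no/such/file.yaml"), "no such file")

  # audit table carries a calibrated scale per (event, line)
  tab <- resolved_parameter_table(PN)
  expect_true(all(c("event", "shape", "median_months", "scale_months")
                  %in% names(tab)))
  expect_equal(tab$scale_months,
               calibrate_weibull_scale(tab$shape, tab$median_months))
})

test_that("random valid parameter bundles survive a write/read cycle", {
  set.seed(21)
  for (i in 1:3) {
    p <- PN
    p$events$regimen_switch$median <- runif(4, 20, 120)
    p$toxicity_p <- runif(1)
    p$costs$discount_rate <- runif(1, 0, 0.1)
    p$rebound_bounds <- sort(runif(2, 3, 5))
    validate_parameters(p)
    path <- tempfile(fileext = ".yaml")
    write_parameters(list(nnrti = p), path)
    expect_equal(load_parameters(path)$nnrti, p, tolerance = 1e-8)
    unlink(path)
  }
})
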