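# Shared fixtures: default parameter bundles are deterministic to build, so
# construct them once per test run.
PN <- default_parameters("nnrti")
PP <- default_parameters("pir")

# Reference-valued covariate vector for an arm (every registry covariate at
# the arm's reference), used to probe shifted medians and cost models.
reference_covariates <- function(params) {
  x <- setNames(rep(0, length(art_covariates())), art_covariates())
  x[names(params$reference)] <- params$reference
  as.list(x)
}

# Independent rejection-sampling oracle for the conditional Weibull sampler:
# draw unconditional Weibull times, keep those exceeding `elapsed`.
rejection_weibull <- function(n, shape, scale, elapsed) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rweibull(2 * n, shape, scale)
    out <- c(out, draw[draw > elapsed])
  }
  out[seq_len(n)]
}

# Hand-computed product-limit estimator (oracle for km_median).
product_limit_median <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events[ord])
  n <- length(times)
  surv <- 1
  for (i in seq_len(n)) {
    at_risk <- n - i + 1
    if (events[i]) surv <- surv * (1 - 1 / at_risk)
    if (surv <= 0.5 + 1e-12) return(times[i])
  }
  NA_real_
}
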