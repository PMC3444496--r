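# Baseline cohort generation: quantile-matching continuous distributions for
# the printed median/IQR anchors, table distributions for categorical fields,
# and a life-table competing risk for non-HIV death.

#' Continuous distribution matching quartile anchors
#'
#' Builds a sampleable continuous distribution whose quartiles equal the
#' supplied anchors, using a piecewise-linear quantile function through
#' (0.25, q1), (0.5, median), (0.75, q3). Tails extend the adjacent segment
#' slope scaled by `tail` and the quantile function is truncated at the
#' support bounds. Degenerate anchors give a point mass.
#'
#' @param median,q1,q3 Quartile anchors with `q1 <= median <= q3`.
#' @param lower,upper Support bounds.
#' @param tail Tail-stretch factor (>= 0): 0 pins the extremes to q1/q3, 1
#'   continues the inner quartile slope.
#' @return An object of class `quantile_distribution`.
#' @export
quantile_distribution <- function(median, q1, q3, lower = -Inf, upper = Inf,
                                  tail = 1) {
  if (!(q1 <= median && median <= q3)) {
    stop("anchors must satisfy q1 <= median <= q3", call. = FALSE)
  }
  if (q1 < lower || q3 > upper) {
    stop("anchors must lie within the support bounds", call. = FALSE)
  }
  q0 <- q1 - tail * (median - q1)
  q4 <- q3 + tail * (q3 - median)
  q <- pmin(pmax(c(q0, q1, median, q3, q4), lower), upper)
  structure(list(p = c(0, 0.25, 0.5, 0.75, 1), q = as.numeric(q),
                 lower = lower, upper = upper),
            class = "quantile_distribution")
}

#' Quantile function of a quantile-matching distribution
#'
#' @param d A [quantile_distribution()].
#' @param p Probabilities in `[0, 1]`.
#' @return Quantiles (linear interpolation between the anchor knots).
#' @export
qdist_quantile <- function(d, p) {
  stopifnot(inherits(d, "quantile_distribution"),
            all(p >= 0 & p <= 1))
  stats::approx(d$p, d$q, xout = p, rule = 2, ties = "ordered")$y
}

#' Sample from a quantile-matching distribution
#'
#' @param d A [quantile_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
qdist_sample <- function(d, n) qdist_quantile(d, runif(n))

.table_dist <- function(values, probs) {
  stopifnot(length(values) == length(probs), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-8)
  list(values = values, probs = probs)
}

.profile_fields <- c("p_female", "age", "age_support", "p_employed",
                     "log10vl", "log10vl_support", "cd4", "cd4_support",
                     "p_hcv", "adherence_pct", "year_init", "nrti_table",
                     "third_agent_table", "p_resistance_gt1",
                     "transmission_table", "p_aids")

#' Baseline cohort profile
#'
#' Marginal distributions of patient characteristics at ART initiation for
#' one strategy arm. Continuous markers are given as `c(median=, q1=, q3=)`
#' quartile anchors (see [quantile_distribution()]); categorical fields as
#' table distributions `list(values=, probs=)`.
#'
#' @param p_female,p_employed,p_hcv,p_aids Bernoulli probabilities.
#' @param age,log10vl,cd4,adherence_pct Quartile anchor vectors
#'   `c(median, q1, q3)` (adherence in percent).
#' @param age_support,log10vl_support,cd4_support Support bounds for the
#'   quantile fits (adherence is bounded to `[0, 100]`).
#' @param year_init Calendar year of ART initiation.
#' @param nrti_table,third_agent_table Table distributions over NRTI backbone
#'   and third-agent labels.
#' @param p_resistance_gt1 Probability that baseline resistance level exceeds
#'   1 (such patients draw a level uniformly in `[1, 5)`, others in `[0, 1)`).
#' @param transmission_table Table distribution over
#'   `c("hetero","idu","homosexual","other")`.
#' @return An object of class `baseline_profile`.
#' @export
baseline_profile <- function(p_female, age, p_employed, log10vl, cd4, p_hcv,
                             adherence_pct, year_init, nrti_table,
                             third_agent_table, p_resistance_gt1,
                             transmission_table, p_aids,
                             age_support = c(18, 80),
                             log10vl_support = c(2, 6.5),
                             cd4_support = c(1, 1200)) {
  pr <- c(p_female = p_female, p_employed = p_employed, p_hcv = p_hcv,
          p_resistance_gt1 = p_resistance_gt1, p_aids = p_aids)
  if (any(pr < 0 | pr > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(pr)[pr < 0 | pr > 1], collapse = ", "), call. = FALSE)
  }
  anchors <- function(x, nm) {
    x <- setNames(as.numeric(x), c("median", "q1", "q3"))
    if (!(x["q1"] <= x["median"] && x["median"] <= x["q3"])) {
      stop(nm, ": anchors must satisfy q1 <= median <= q3", call. = FALSE)
    }
    x
  }
  structure(list(
    p_female = p_female,
    age = anchors(age, "age"), age_support = age_support,
    p_employed = p_employed,
    log10vl = anchors(log10vl, "log10vl"), log10vl_support = log10vl_support,
    cd4 = anchors(cd4, "cd4"), cd4_support = cd4_support,
    p_hcv = p_hcv,
    adherence_pct = anchors(adherence_pct, "adherence_pct"),
    year_init = year_init,
    nrti_table = .table_dist(nrti_table$values, nrti_table$probs),
    third_agent_table = .table_dist(third_agent_table$values,
                                    third_agent_table$probs),
    p_resistance_gt1 = p_resistance_gt1,
    transmission_table = .table_dist(transmission_table$values,
                                     transmission_table$probs),
    p_aids = p_aids), class = "baseline_profile")
}

#' Default baseline profile per arm
#'
#' Characteristics at ART initiation for each strategy arm: proportions and
#' median/IQR anchors of the treatment-naive cohort, with an assumed age IQR
#' (33-47; only the median 39 is anchored) and shared transmission-group mix.
#'
#' @param arm `"nnrti"` or `"pir"`.
#' @return A [baseline_profile()].
#' @export
default_baseline_profile <- function(arm = c("nnrti", "pir")) {
  arm <- match.arg(arm)
  if (arm == "nnrti") {
    baseline_profile(
      p_female = 0.323, age = c(39, 33, 47), p_employed = 0.66,
      log10vl = c(4.9, 4.3, 5.4), cd4 = c(234, 128, 349), p_hcv = 0.298,
      adherence_pct = c(89, 71, 98), year_init = 2003,
      nrti_table = list(values = c("AZT+3TC", "TDF+FTC", "TDF+3TC",
                                   "ABC+3TC", "other"),
                        probs = c(0.55, 0.19, 0.09, 0.03, 0.14)),
      third_agent_table = list(values = c("EFV", "NVP"),
                               probs = c(0.64, 0.36)),
      p_resistance_gt1 = 0.0127,
      transmission_table = list(values = c("idu", "homosexual", "hetero",
                                           "other"),
                                probs = c(0.278, 0.137, 0.575, 0.01)),
      p_aids = 0.322)
  } else {
    baseline_profile(
      p_female = 0.340, age = c(39, 33, 47), p_employed = 0.66,
      log10vl = c(5.1, 4.3, 5.5), cd4 = c(219, 108, 350), p_hcv = 0.296,
      adherence_pct = c(88, 73, 96), year_init = 2005,
      nrti_table = list(values = c("AZT+3TC", "TDF+FTC", "TDF+3TC",
                                   "ABC+3TC", "other"),
                        probs = c(0.52, 0.23, 0.09, 0.11, 0.05)),
      third_agent_table = list(values = c("LPVr", "otherPIr"),
                               probs = c(0.73, 0.27)),
      p_resistance_gt1 = 0.0063,
      transmission_table = list(values = c("idu", "homosexual", "hetero",
                                           "other"),
                                probs = c(0.278, 0.137, 0.575, 0.01)),
      p_aids = 0.322)
  }
}

.profile_to_list <- function(pf) {
  x <- unclass(pf)
  x$age <- as.list(x$age); x$log10vl <- as.list(x$log10vl)
  x$cd4 <- as.list(x$cd4); x$adherence_pct <- as.list(x$adherence_pct)
  x
}

.profile_from_list <- function(x) {
  an <- function(v) unlist(v)[c("median", "q1", "q3")]
  baseline_profile(
    p_female = x$p_female, age = an(x$age), p_employed = x$p_employed,
    log10vl = an(x$log10vl), cd4 = an(x$cd4), p_hcv = x$p_hcv,
    adherence_pct = an(x$adherence_pct), year_init = x$year_init,
    nrti_table = list(values = unlist(x$nrti_table$values),
                      probs = as.numeric(unlist(x$nrti_table$probs))),
    third_agent_table = list(
      values = unlist(x$third_agent_table$values),
      probs = as.numeric(unlist(x$third_agent_table$probs))),
    p_resistance_gt1 = x$p_resistance_gt1,
    transmission_table = list(
      values = unlist(x$transmission_table$values),
      probs = as.numeric(unlist(x$transmission_table$probs))),
    p_aids = x$p_aids,
    age_support = as.numeric(unlist(x$age_support)),
    log10vl_support = as.numeric(unlist(x$log10vl_support)),
    cd4_support = as.numeric(unlist(x$cd4_support)))
}

.sample_table <- function(tab, n) {
  if (length(tab$values) == 1L) return(rep(tab$values, n))
  tab$values[sample.int(length(tab$values), n, replace = TRUE,
                        prob = tab$probs)]
}

#' Sample a baseline cohort
#'
#' Draws `n` patients at ART initiation from a [baseline_profile()], each
#' field independently from its marginal distribution, plus baseline regimen
#' characteristics from the line-1 regimen tables and a scheduled non-HIV
#' death age from the life table (competing risk). Uses R's RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param profile A [baseline_profile()].
#' @param n Number of patients.
#' @param regimen_tables Per-line regimen tables as in [model_parameters()]
#'   (line 1 is used here); defaults to the packaged tables if `params` given.
#' @param life_table Life table (`age`, `sex`, `qx`); default
#'   [default_life_table()].
#' @param params Optional [model_parameters()] supplying `regimen_tables` and
#'   `life_table` in one go.
#' @return A data frame with one row per patient (class `patient_state`).
#' @export
sample_baseline <- function(profile, n = 1L, regimen_tables = NULL,
                            life_table = NULL, params = NULL) {
  stopifnot(inherits(profile, "baseline_profile"), n >= 1L)
  if (!is.null(params)) {
    regimen_tables <- params$regimen_tables
    life_table <- params$life_table
  }
  if (is.null(life_table)) life_table <- default_life_table()
  d_age <- quantile_distribution(profile$age["median"], profile$age["q1"],
                                 profile$age["q3"],
                                 profile$age_support[1], profile$age_support[2])
  d_vl <- quantile_distribution(profile$log10vl["median"],
                                profile$log10vl["q1"], profile$log10vl["q3"],
                                profile$log10vl_support[1],
                                profile$log10vl_support[2])
  d_cd4 <- quantile_distribution(profile$cd4["median"], profile$cd4["q1"],
                                 profile$cd4["q3"], profile$cd4_support[1],
                                 profile$cd4_support[2])
  d_adh <- quantile_distribution(profile$adherence_pct["median"],
                                 profile$adherence_pct["q1"],
                                 profile$adherence_pct["q3"], 0, 100)
  female <- as.integer(runif(n) < profile$p_female)
  age <- qdist_sample(d_age, n)
  res_gt1 <- runif(n) < profile$p_resistance_gt1
  res_level <- ifelse(res_gt1, runif(n, 1, 5), runif(n, 0, 1))
  st <- data.frame(
    female = female,
    age = age,
    employed = as.integer(runif(n) < profile$p_employed),
    hcv = as.integer(runif(n) < profile$p_hcv),
    transmission = .sample_table(profile$transmission_table, n),
    aids = as.integer(runif(n) < profile$p_aids),
    cd4 = qdist_sample(d_cd4, n),
    log10vl = qdist_sample(d_vl, n),
    adherence = qdist_sample(d_adh, n) / 100,
    resistance_level = res_level,
    resistance_class = ifelse(res_gt1, 2L, 1L),
    year_init = profile$year_init,
    nrti_pair = .sample_table(profile$nrti_table, n),
    third_agent = .sample_table(profile$third_agent_table, n),
    line = 1L, regimen_number = 1L, suppressed = FALSE,
    n_failures = 0L,
    stringsAsFactors = FALSE)
  if (!is.null(regimen_tables)) {
    tab1 <- regimen_tables[[1]]
    st$n_pis <- .sample_table(tab1$n_pis, n)
    st$doses_per_day <- .sample_table(tab1$doses, n)
    st$pills_per_day <- .sample_table(tab1$pills, n)
  } else {
    st$n_pis <- 0; st$doses_per_day <- 2; st$pills_per_day <- 3
  }
  st$nonhiv_death_age <- sample_nonhiv_death_age(
    st$age, ifelse(st$female == 1, "female", "male"), life_table)
  class(st) <- c("patient_state", "data.frame")
  st
}

#' Synthetic life table for non-HIV mortality
#'
#' A Gompertz-Makeham annual mortality schedule, shipped as a synthetic
#' stand-in for a national general-population life table (annual death
#' probability `qx = 1 - exp(-(a + b exp(c age)))`, with a lower `b` for
#' women). Replace with an observed table via the `life_table` field of
#' [model_parameters()] or a CSV with columns age, sex, qx.
#'
#' @param max_age Last tabulated age (absorbing cap).
#' @param a Makeham constant hazard.
#' @param b,theta Gompertz level and slope.
#' @param female_factor Multiplier on `b` for women.
#' @return Data frame with columns `age`, `sex`, `qx`.
#' @export
default_life_table <- function(max_age = 105, a = 5e-4, b = 2.8e-5,
                               theta = 0.098, female_factor = 0.55) {
  age <- 0:max_age
  qx_m <- 1 - exp(-(a + b * exp(theta * age)))
  qx_f <- 1 - exp(-(a + female_factor * b * exp(theta * age)))
  rbind(data.frame(age = age, sex = "male", qx = pmin(qx_m, 1),
                   stringsAsFactors = FALSE),
        data.frame(age = age, sex = "female", qx = pmin(qx_f, 1),
                   stringsAsFactors = FALSE))
}

#' Sample age at death from non-HIV causes
#'
#' Walks the life table from the current age, applying each annual death
#' probability in sequence; a death in year k occurs at a uniform point
#' within that year. Survivors beyond the table are assigned the cap age.
#' Vectorized over patients.
#'
#' @param current_age Current age(s) in years.
#' @param sex `"male"`/`"female"`, recycled.
#' @param life_table Data frame with `age`, `sex`, `qx`.
#' @return Age(s) at non-HIV death, strictly greater than `current_age`.
#' @export
sample_nonhiv_death_age <- function(current_age, sex, life_table) {
  n <- max(length(current_age), length(sex))
  current_age <- rep_len(current_age, n)
  sex <- rep_len(sex, n)
  max_age <- max(life_table$age)
  if (any(current_age > max_age)) {
    stop("current_age beyond the life table range", call. = FALSE)
  }
  qx <- matrix(0, nrow = max_age + 1L, ncol = 2,
               dimnames = list(NULL, c("male", "female")))
  for (s in c("male", "female")) {
    sub <- life_table[life_table$sex == s, ]
    qx[sub$age + 1L, s] <- sub$qx
  }
  death <- rep(max_age + 0.0, n)
  alive <- rep(TRUE, n)
  floor_age <- floor(current_age)
  for (a in min(floor_age):max_age) {
    idx <- which(alive & floor_age <= a)
    if (length(idx) == 0L) next
    q <- qx[a + 1L, ifelse(sex[idx] == "female", 2L, 1L)]
    dies <- runif(length(idx)) < q
    if (any(dies)) {
      di <- idx[dies]
      at <- pmax(a + runif(length(di)), current_age[di] + 1e-9)
      death[di] <- pmin(at, max_age)
      alive[di] <- FALSE
    }
  }
  pmax(death, current_age + 1e-9)
}

#' Validate sampled patient states
#'
#' Checks the structural invariants of a `patient_state` data frame
#' (adherence in `[0,1]`, CD4 >= 0, resistance level in `[0,25]` and
#' consistent with its class, flags 0/1).
#'
#' @param state A data frame from [sample_baseline()].
#' @return `TRUE` invisibly; stops otherwise.
#' @export
validate_patient_state <- function(state) {
  stopifnot(all(state$adherence >= 0 & state$adherence <= 1),
            all(state$cd4 >= 0),
            all(state$resistance_level >= 0 & state$resistance_level <= 25),
            all(state$aids %in% c(0, 1)),
            all(state$line %in% 1:4))
  cls <- resistance_class_of(state$resistance_level)
  stopifnot(all(cls == state$resistance_class))
  invisible(TRUE)
}

#' Resistance class of a resistance level
#'
#' Maps the inverted genotypic sensitivity score to its class: 1 for R < 1,
#' 2 for 1 <= R < 5, 3 for 5 <= R < 10, 4 for R > 10 (up to 25).
#'
#' @param level Resistance level(s) in `[0, 25]`.
#' @param bounds Class boundaries, default `c(1, 5, 10, 25)`.
#' @return Integer class(es) 1-4.
#' @export
resistance_class_of <- function(level, bounds = c(1, 5, 10, 25)) {
  findInterval(level, c(-Inf, bounds[1], bounds[2], bounds[3]))
}
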