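---
title: "Modelling HIV treatment pathways with artpath: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HIV treatment pathways with artpath: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`artpath` is a discrete-event microsimulation of HIV-infected adults from
the start of first-line antiretroviral therapy (ART) to death. Two initial
strategies are compared: two nucleoside reverse-transcriptase inhibitors
plus a non-nucleoside (2NRTI+NNRTI) versus two NRTIs plus a ritonavir-boosted
protease inhibitor (2NRTI+PI/r). Unlike cohort Markov models, time advances
from event to event: at every decision point the engine samples a candidate
time for each admissible clinical event and the earliest one fires.

Four driving forces shape each trajectory: CD4 cell count, log10 viral
load, drug resistance and adherence. The clinical events are viral
suppression (HIV-1 RNA < 50 copies/mL), virological failure after
suppression, regimen switch without failure, resistance development,
hospitalization, AIDS-defining events, HIV-related death, and death from
other causes (a competing risk scheduled from a life table at entry).

Disease progression is organised in therapy lines. On lines 1 and 2 a
patient switches to the next line when suppression is not reached within
the line deadline (12 months by default; 6 months is the modern guideline
value, and both are exposed in configuration) or when a confirmed failure
occurs after suppression. On line 3 the patient stays regardless of the
number of failures, reshuffling regimens, until resistance reaches the
highest class; then non-suppressive (maintenance) therapy begins and no
further suppression is attempted. At most two line switches can occur.

### Event times

Every event-time model is a Weibull distribution parameterised by its shape
`p` and its *median* at a reference patient. The scale is recovered in
closed form, `scale = median / log(2)^(1/p)` (`calibrate_weibull_scale()`),
so that configuration files can carry the quantity the literature reports.
Covariates act as additive shifts, in months, on the median
(`shifted_median()`); covariates are centred at the arm's reference values
(the baseline medians and reference categories), so the configured median
holds exactly at the reference patient. Each specification carries a
positive floor for the shifted median; the default floor is 0.1 months.
The hospitalization model uses a 12-month floor instead: its fitted
line-3, age and resistance shifts are large enough that an additive model
pushed the median to zero in late disease, and a 12-month floor caps the
implied rate at about one admission per year in the most severe states
rather than letting a boundary artefact dominate the cost ledger.

Times are re-sampled at every decision point from the *conditional*
distribution given the time already survived on the event's clock:
`t = scale * ((elapsed/scale)^p - log(u))^(1/p)`. Clock origins are chosen
per event type: suppression and failure clocks restart with the current
regimen/suppression episode; hospitalization, AIDS events and
resistance-class switches are renewal processes (clock restarts at each
occurrence); first resistance and HIV death accumulate from ART initiation.
Exact ties between candidates are broken by a fixed priority order in which
death preempts everything and suppression yields to all state-changing
events (`event_priority()`).

### Evolving state

CD4 follows a line-specific logarithmic curve, `a * log(1 + b * dt)`; the
default curvature is `b = 0.2`/month and the amplitudes are calibrated so
the first-year gains are +28, +24 and +21 cells/uL on lines 1-3, with a
linear 17 cells/uL/year decline on non-suppressive therapy. Suppression
drops log10 viral load instantly to the detectability floor (1.69, i.e.
log10 49); failure redraws it uniformly within the rebound bounds. The
default bounds have width 1 on the log10 scale and are centred, in closed
form against the arm's baseline viral-load distribution, so that the mean
ratio of rebound to baseline log10 viral load is 0.83.

Resistance is a single inverted genotypic sensitivity score (0-25) grouped
in four classes (R<1, 1-5, 5-10, >10); patients move only to the adjacent
class, redrawing the level uniformly within the new class, and class-4
levels update as the maximum of the current level and a triangular draw on
(10, 25). AIDS status is absorbing: the first AIDS-defining event or any
CD4 below 200 cells/uL classifies the patient permanently. Adherence is a
logit-link model whose percentage-point marginal effects are converted to
logit coefficients locally at the reference adherence (0.88), and each
patient keeps an individual intercept anchored at their sampled baseline
adherence.

### Economics

Costs are 2009 euro from the health-service perspective, direct medical
costs only. Monthly ART and non-ART outpatient costs are log-link GLMs with
per-line anchors; first-line anchors are the arm medians (613/1057 and
63/98 euro/month) and later-line anchors are shared across arms because
later-line treatment depends on the initial strategy only through carried
covariates. The later-line anchors (ART: the geometric mean of the arm
anchors escalated by the fitted line-2 coefficient, with a synthetic line-3
escalation; non-ART: 90/150/200 euro/month) are package defaults, not
literature values. Non-suppressive ART is costed per day from a lognormal
draw fixed at entry. Event costs: 582 (regimen change with failure), 495
(without failure, plus an inflation-adjusted 1126 euro adverse-event cost
when the cause is toxicity, probability 0.54), 4765 (AIDS event) and 4742
(hospitalization).

Discounting uses discrete annual compounding at 5%/year; continuously
accruing quantities (costs, life-years, QALYs) are discounted at the
midpoint of each inter-event interval, point costs at the event time.
QALYs weight each interval by a utility from a CD4-by-suppression table.
The shipped utility table is a synthetic placeholder (the published
utilities the original analysis used are not reproduced here) and should
be overridden for substantive work.

## The baseline cohort generator

`sample_baseline()` is the package's synthetic-data generator. Continuous
markers (age, CD4, log10 viral load, adherence) are drawn from
piecewise-linear quantile distributions fitted to median/IQR anchors
(`quantile_distribution()`), truncated at configurable support bounds;
categorical fields are Bernoulli/table draws. Default anchors are the
treatment-naive cohort values (e.g. 32.3%/34.0% female, CD4 234/219,
log10VL 4.9/5.1, 32.2% AIDS, 1.27%/0.63% baseline resistance above level
1). The age IQR is not reported anywhere, so a default of 33-47 years
around the median 39 is assumed. Fields are sampled independently - the
generator reproduces the *marginal* distributions only. Real cohorts
correlate CD4 with viral load and AIDS status; passing tests against this
generator therefore validates the mechanics and the marginal calibration,
not joint-distribution realism. Non-HIV death ages come from a
Gompertz-Makeham life table shipped as a synthetic stand-in for a national
table (`default_life_table()`); supply an observed table via the
`life_table` field for applied use.

## Quantities the sources leave open, and the defaults chosen

* Baseline medians of the event-time models are calibration inputs: first
  regimen switch 80.4/32.4 months (per arm), first resistance 336 months,
  class switch 84 months, suppression 7 months on line 1. These anchor the
  Kaplan-Meier recovery checks in the test suite.
* Line-2 suppression median is set to 10 months rather than shifted from
  line 1, so that suppression attainment decreases across lines as the
  line-wise pattern requires; the fitted +0.485 line-2 shift is absorbed
  into this anchor.
* Line-3 suppression is a trial-based unshifted Weibull (median 30 months)
  with a single 36-month attempt window from line-3 entry: if suppression
  is not reached within the window the attempt is declared failed (one
  failure-without-suppression, regimen reshuffle) and no further
  suppression is attempted on that line until a later suppression-failure
  cycle. The window makes line-3 attainment land below line 2 while
  keeping the mean time to line-3 suppression above a year.
* HIV-death Weibulls stratified by AIDS status are unreported; defaults
  (non-AIDS shape 1.4, median 396 months; AIDS shape 1.1, median 288
  months) were calibrated once so simulated undiscounted life expectancy
  is about 24.3 years at the default baseline mix, then frozen.
* The AIDS-event model stands in for a published Weibull
  proportional-hazards model whose coefficients are not available: shape
  1.2 with medians 48/96/192 months by CD4 stratum and transmission-group
  multipliers. It is documented as synthetic.
* Marginal effects printed for the death model are on an unclear scale and
  are off by default (configurable).
* Employment status is sampled at baseline and carried in the state but
  unused by default, matching the fitted models.
* PSA priors are not reported beyond "appropriate distributions"; the
  default prior set (`default_priors()`) uses lognormal multipliers
  (sd 0.1) on medians and cost anchors, a beta prior on the toxicity
  fraction, and a truncated lognormal on the utility scale. Headline PSA
  percentages therefore depend on these choices.

## Numerical choices

* Weibull scales are inverted in closed form; the round trip
  median -> scale -> median is exact to floating point.
* Conditional sampling uses one uniform per candidate; `u = 0.5` at zero
  elapsed time returns the median exactly, and the sampler is strictly
  decreasing in `u`.
* Tie-breaks among simultaneous candidates follow the documented priority
  order, making trajectories deterministic given the random stream.
* Each individual runs on a counter-based (splitmix64) substream derived
  from `(seed, index)`: cohorts are order-independent, reproducible
  bit-for-bit, and the two arms can share streams (common random numbers)
  by sharing the seed, which stabilises incremental estimates.
* Degenerate inputs are defined: point-mass quantile anchors, zero-width
  regimen tables, zero discount rates, zero hazards (death at the table
  cap), and a forced end of simulation at age 105 guard non-termination.
* Problem sizes in the shipped checks: distributional oracles run at
  10^5 draws; cohort-level property checks at 10^5 individuals; the
  paired-arm example at 10^5 per arm with a 20-set x 5,000-individual
  sensitivity analysis.

## Known limitations

* A single aggregate resistance score; no drug- or class-specific
  resistance, so regimen selection cannot react to resistance history.
* No transmission between individuals; individuals are simulated
  independently.
* No long-term safety markers (lipids, renal, bone).
* The non-ART later-line anchors, utility table, AIDS-event model and life
  table are synthetic defaults; absolute cost and QALY totals therefore
  depend on configuration, while the calibrated event-time machinery,
  accounting identities and incremental logic are the tested core.
* Fields are sampled independently at baseline (no copula); correlation
  hooks would need to be added to the profile for joint realism.

```{r example}
library(artpath)
nnrti <- default_parameters("nnrti")
pir <- default_parameters("pir")
a <- simulate_cohort(nnrti, 1e5, seed = 1)
b <- simulate_cohort(pir, 1e5, seed = 1)
compare_strategies(a, b)
```
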