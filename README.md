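# artpath

Discrete-event microsimulation of HIV treatment pathways for lifetime
cost-effectiveness analysis of initial antiretroviral therapy (ART).

## What it is for

Clinical guidelines allow two first-line strategies for treatment-naive
HIV-1 infected adults: two nucleoside reverse-transcriptase inhibitors plus
a non-nucleoside (2NRTI+NNRTI) or plus a ritonavir-boosted protease
inhibitor (2NRTI+PI/r). The classes are considered clinically equivalent
but differ substantially in daily drug cost, so the question of which to
start with is an economic one that plays out over a patient's remaining
lifetime: switching behaviour, resistance accumulation, therapy-line
progression, hospitalizations and AIDS events all feed back into costs and
quality-adjusted survival. `artpath` is aimed at health-economic modellers
who need an individual-level (microsimulation) alternative to cohort
Markov models for this problem.

## The model

Each simulated patient advances from event to event. At every decision
point the engine samples, for each admissible clinical event *e*, a time
from a Weibull distribution conditional on the time already survived on
that event's clock,

    S(t) = exp(-(t/lambda_e)^{p_e}),
    t_next = lambda_e * ((t_elapsed/lambda_e)^{p_e} - log U)^{1/p_e},

and the earliest candidate fires. Scales are parameterised through the
median, `lambda = m / (log 2)^{1/p}`, and patient covariates shift the
median additively (months per covariate unit). Events update CD4 count
(logarithmic per-line trajectories), log10 viral load
(suppression/rebound), adherence (logit-link model), a 0-25 resistance
score grouped in four classes, therapy line (two switches at most, then a
third line held until the top resistance class, then non-suppressive
therapy), and a cost/QALY ledger: log-link GLMs for monthly ART and
non-ART spending, unit costs per event, discounting at 5%/year
(mid-interval for accruals), and CD4-by-suppression utility weights.

Strategy comparison reports incremental cost, life-years and QALYs,
dominance classification, and ICERs (`delta C / delta E`). Probabilistic
sensitivity analysis re-draws uncertain parameters from priors, simulates
both arms with common random numbers, and summarises `(delta C, delta Q)`
pairs as dominance fractions and cost-effectiveness acceptability curves
(fraction of draws with positive net monetary benefit
`lambda * delta Q - delta C`).

The per-individual event loop is implemented in C++ (Rcpp) with one
counter-based RNG substream per `(seed, individual)`, so cohorts are
reproducible bit-for-bit and fast: a 100,000-individual arm simulates in a
few seconds.

## Worked example

```r
library(artpath)
nnrti <- default_parameters("nnrti")
pir   <- default_parameters("pir")

a <- simulate_cohort(nnrti, 1e5, seed = 1)
b <- simulate_cohort(pir,   1e5, seed = 1)
print(a)
#> Cohort summary: arm nnrti, n = 100000
#>   Discounted: cost 164938 EUR, LY 12.39, QALY 11.36
#>   Undiscounted: cost 344163 EUR, LY 24.02, QALY 21.97
#>   % attaining suppression by line: 75.8 / 65.0 / 51.1
#>   % reaching line 2 / 3 / non-suppressive: 78.2 / 63.7 / 29.8

compare_strategies(a, b)
#> Incremental result: dCost -37154 EUR, dLY -0.026, dQALY 0.032
#>   Classification: dominant
```

Reading this: under the default (partly synthetic - see the methods
vignette) parameters, a patient starting on the NNRTI strategy accrues a
discounted lifetime cost of about 165k EUR against 202k EUR on PI/r, with
essentially equal discounted life expectancy and a small QALY advantage,
so the cheaper strategy dominates: it costs less and is no less effective.
Undiscounted life expectancy is about 24 years from ART initiation, and
the fraction of patients attaining viral suppression falls from ~76% on
line 1 to ~51% on line 3.

A PSA and the acceptability curve:

```r
psa <- run_psa(list(nnrti = nnrti, pir = pir), default_priors(),
               n_sets = 20, n_individuals = 5000, base_seed = 1)
proportion_dominant(psa)
ceac(psa, seq(0, 1e5, by = 1e4))
```

A thin CLI over the same functions ships in `inst/cli/artpath.R`
(subcommands `simulate`, `psa`, `ceac`, `km`).

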