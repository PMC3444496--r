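Package: artpath
Title: Discrete-Event Microsimulation of Antiretroviral Therapy Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level discrete-event simulation of HIV disease
    progression from antiretroviral therapy (ART) initiation to death, for
    lifetime cost-effectiveness comparison of first-line strategies (two
    NRTIs plus an NNRTI versus two NRTIs plus a boosted protease
    inhibitor). Patient trajectories are driven by covariate-conditional
    Weibull time-to-event sampling across therapy lines, with evolving CD4
    count, viral load, adherence and drug resistance, discounted cost and
    quality-adjusted life-year accounting, strategy comparison (incremental
    costs, effects, dominance, ICERs), and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
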