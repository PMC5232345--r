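Package: pcsk9cea
Title: Lifetime Cost-Effectiveness and Payer Return-on-Investment Modelling
    of PCSK9 Inhibitor Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model comparing statin plus
    PCSK9-inhibitor lipid-lowering therapy with statin-only therapy over a
    lifetime horizon (ages 58 to 100, 1-year cycles). Computes discounted
    costs, quality-adjusted life years and incremental cost-effectiveness
    ratios from a health-system perspective, and discounted cash flows, net
    present value and return on investment for a private insurance payer
    with membership turnover, premiums and tiered drug cost sharing. Annual
    cardiovascular event probabilities derive from the Framingham general
    cardiovascular risk profile; treatment effects enter either as a trial
    relative risk reduction or by imputing an LDL-cholesterol reduction into
    the risk equation. Includes probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, breakeven price search, an
    individual-level microsimulation oracle for validating the cohort
    engine, and table and figure reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
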