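# pcsk9cea

Lifetime cost-effectiveness and private-payer return-on-investment
modelling of PCSK9 inhibitor therapy, for health economists and payers
evaluating high-cost preventive cardiovascular drugs.

PCSK9 inhibitors added to statin therapy roughly halve the annual rate of
cardiovascular (CVD) events, at a list price near \$14,000 per year. This
package implements a Markov cohort state-transition model that follows a
high-risk cohort from age 58 until death or age 100 on 1-year cycles,
through states for normal life on treatment, acute myocardial infarction,
stroke or other CVD, five-year post-CVD recovery tunnels, and death. It
answers three questions:

1. **Health system** — the incremental cost-effectiveness ratio,

   ICER = (ΔC_treatment − ΔC_avoided) / ΔQALY,

   with costs and quality-adjusted life years discounted at 3%/yr.
2. **Private payer** — discounted cash flows under 12.2% annual membership
   turnover, age-banded premiums, tiered drug copays and deductibles:

   NPV = avoided claims + premium revenue − treatment outlay, ROI = NPV / outlay.
3. **Pricing** — the annual drug price at which the ICER meets a
   willingness-to-pay threshold, and the price at which the payer breaks
   even (both unique roots of functions affine in price).

Annual event probabilities derive from the Framingham general
cardiovascular risk profile (D'Agostino et al., 2008) evaluated for the
ageing cohort; the treatment effect enters either as the trial's 49.2%
relative risk reduction or by imputing a 61% LDL-cholesterol reduction
into the risk equation. A probabilistic sensitivity analysis (beta-scaled
costs and utilities, normal turnover and risk coefficients) produces
cost-effectiveness acceptability curves, and an individual-level
microsimulation through the identical transition matrices serves as a
brute-force oracle for the cohort engine. Modelling choices and their
rationale are in `vignettes/model-methods.Rmd`.

## Worked example

```r
library(pcsk9cea)

params <- model_parameters()          # published point estimates and ranges
cea(params, price = 14000)
#> <pcsk9_cea> scenario=trial_rrr price=$14,000
#>   incremental treatment cost: $245,569
#>   avoided medical cost:       $5,595
#>   delta QALY: 0.730  delta LY: 0.920  delta events: -0.369
#>   ICER: $328,511 per QALY
```

Adding PCSK9 therapy at \$14,000/yr costs the health system about \$246k
per patient over a lifetime, avoids \$5.6k of event-related care, averts
0.37 CVD events and buys 0.73 discounted QALYs — about \$329k per QALY,
more than three times the usual \$100,000 willingness-to-pay threshold.

```r
payer_result(params, insurance_parameters(), price = 14000)
#> <pcsk9_payer> price=$14,000
#>   treatment cost: $75,831  avoided: $1,238  premium: $678
#>   NPV: $-73,915  ROI: -97.5%
```

A commercial insurer bears \$76k of that outlay (members leave at 12.2%
per year, so later costs and benefits fall away) but captures only \$1.2k
of avoided claims and \$0.7k of extra premium revenue from longer
survival: the payer loses essentially its whole investment (ROI −97.5%).

```r
breakeven_table(params)
#> # A tibble: 2 × 5
#>   perspective              price    icer    roi     npv
#> 1 payer_npv_zero            644.   8181.  0          0
#> 2 health_system_wtp_100000 4472. 100000  -0.917 -21187.
```

The therapy becomes cost-effective to the health system only below about
\$4,500/yr, yet the payer breaks even only near \$640/yr — the gap that
makes a cost-effective price still unprofitable to insurers. At \$2,500/yr
the probabilistic sensitivity analysis (`run_psa()`, 1,000 draws) finds
the therapy cost-effective at WTP \$100k in 99.8% of draws while the
payer's probability of positive ROI is zero
(`acceptability_surface()`, `autoplot()`).

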