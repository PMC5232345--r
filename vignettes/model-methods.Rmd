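---
title: "Model methods: lifetime cost-effectiveness and payer return of PCSK9 therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsk9cea)
```

## The decision problem

PCSK9 inhibitors lower LDL cholesterol by roughly 60% on top of statin
therapy, but at list prices around \$14,000 per year. Whether that buys
enough avoided cardiovascular disease (CVD) to be worth paying for depends
on who is asking: a health system values lifetime QALYs gained at a
willingness-to-pay (WTP) threshold, while a US commercial insurer only
captures benefits while the member stays enrolled, net of patient cost
sharing, against the full drug outlay. `pcsk9cea` implements both
perspectives on one Markov cohort model so the two answers — and the gap
between them — can be computed, stress-tested and priced.

## Cohort and states

The modelled cohort enters at age 58 with the risk-factor profile of a
secondary-prevention statin-trial population (52% male, mean total
cholesterol 202 mg/dL, HDL 51, LDL 120, SBP 128 treated / 133 untreated
with 88% treated, 16% smokers, 13% diabetic) and is followed on 1-year
cycles until age 100. States:

* **Normal life on treatment** (statin alone, or statin + PCSK9).
* **Acute event year** for each of three event types — myocardial
  infarction (MI), stroke, and "other CVD" (unstable angina, TIA, heart
  failure and similar) — occupying one full cycle.
* **Post-CVD tunnel**, five year-indexed states per event type capturing
  the slow return of costs and quality of life toward normal; survivors of
  post year 5 return to normal life.
* Two absorbing death states (CVD and non-CVD).

Within a cycle, non-CVD death resolves first in every alive state and the
CVD risks (events, case fatality, post-CVD mortality) apply to the
survivors. This single convention keeps every transition row summing to
one at all ages — including the oldest ages where the acute case-fatality
anchor reaches 98.5% — and makes the treated arm's survival weakly
dominate the comparator's at every cycle, as it should when the only
difference between arms is a proportional event-rate reduction.

A transition from a post-CVD state directly to CVD death is a *fatal
recurrence*: it counts as a CVD event and incurs the event type's acute
cost at the cycle it occurs, since a fatal MI still generates acute care.
A subsequent non-fatal event re-enters the acute state and restarts the
five-year post clock.

## Event probabilities

The printed inputs give, for each event type, the *range* of the annual
probability over ages 58–100, not the full curve. Two reconstruction rules
are implemented (`first_event_source`):

* **`"framingham_survival"`** (default): the total annual first-event
  probability of the ageing cohort comes from the Framingham general-CVD
  risk profile (D'Agostino et al., 2008) — both sex equations evaluated at
  the cohort-average covariates with the age term advancing each cycle,
  mixed 52/48, converted from 10-year risk to an annual probability by
  `1 - (1 - R10)^(1/10)` (constant hazard within the decade, the
  proportional-survival assumption). The per-type anchor profiles then set
  only the MI/stroke/other *split* at each age. This is the construction
  under which the package reproduces the published base-case economics; the
  anchor ranges alone, used as absolute curves, produce roughly half the
  event burden and an ICER nearly twice the published value.
* **`"anchors"`**: the per-type profiles are used directly as the
  statin-arm probabilities. This mode exists for transparency and for
  exploring the anchor-faithful variant; its probabilities lie inside the
  printed ranges by construction.

Subsequent-event probabilities and all mortality curves (acute case
fatality, post-CVD mortality, non-CVD background mortality) interpolate
their printed anchors directly. Interpolation is geometric
("exponential", the default), since CVD incidence and mortality grow
roughly exponentially over this age span; linear interpolation is a
sensitivity option (`profile_shape`).

Treatment effect by scenario:

* **`trial_rrr`** (base case): every first and subsequent event
  probability in the PCSK9 arm is the statin-arm value times
  `1 - 0.492`, the one-year relative risk reduction observed for
  evolocumab on CVD events excluding non-CVD death and revascularisation.
* **`framingham_ldl`**: the 61% LDL reduction is imputed into the risk
  equation. The general-CVD profile uses total and HDL cholesterol, not
  LDL, so the reduction is mapped to total cholesterol: TC falls by
  0.61 × LDL = 73.2 mg/dL with HDL held fixed (the ATP-III composition
  TC = LDL + HDL + TG/5 gives the same number). The PCSK9 arm's
  probabilities are the statin arm's times the per-age ratio of annualized
  risks, about 0.60–0.63. Published results for this scenario imply a
  much weaker imputed effect (a ratio near 0.73) than any standard
  lipid-fraction mapping of a 61% LDL reduction yields, so this scenario's
  ICER computes lower here (about \$417k/QALY vs the published \$618k);
  the mapping is kept explicit rather than tuned.

## Costs and utilities

Therapy costs (statin \$48/yr, baseline care \$215/yr, plus the PCSK9
price in the combination arm) accrue over alive non-acute occupancy.
Acute costs are \$11,071 (MI), \$18,516 (stroke) and their average
\$14,794 (other); the first post year costs \$7,747 / \$7,770 / \$7,759
and later post years decay by 25% per year. All costs and QALYs accrue at
cycle start with no half-cycle correction — the convention of the
spreadsheet genre this model belongs to — and discount at 3%/yr.

Utilities: 0.79 on treatment; the acute year sits at the event-type floor
(MI 0.58, stroke 0.46, other 0.63); post years follow a concave recovery
path `floor + (0.79 - floor) * ((y-1)/4)^0.5` reaching 0.79 at post year
5 (the exponent is configurable; only the endpoints are constrained by
the published inputs). All alive-state utilities decline with age by
0.0035 index points per year from age 58, the approximate age-60-to-90
slope of the US EQ-5D population-norm catalog from which the point
utilities are drawn. Without this decline the incremental QALY gain
overshoots the published value by ~25%, because the therapy's extra life
years accrue mostly after age 80.

```{r base-case}
params <- model_parameters()
cea(params, price = 14000)
```

## Payer perspective

The payer model reweights the same traces by enrollment under 12.2%
annual turnover and applies cost sharing:

* **Premiums** — \$520/month before 65 (individual commercial), \$835
  from 65 (Medicare Advantage) — are collected in advance: weighted by
  enrollment at cycle start, `(1 - turnover)^t`.
* **Claims** (drug outlays and medical costs) are paid for members carried
  through the year: weighted `(1 - turnover)^(t+1)`.
* **Drug copays**: statins are tier 1 (\$11/\$5 per month by age band),
  PCSK9 tier 2 (\$31/\$11); twelve months of copay offset each drug's
  annual cost, floored at zero — so the payer pays nothing for the \$48
  statin.
* **Deductible**: by default (`deductible_mode = "exempt"`) the annual
  deductible (\$3,731 / \$2,158) is treated as exhausted by routine member
  spending common to both arms, so it cancels out of incremental cash
  flows; this is the configuration that reproduces the published payer
  column, whose arithmetic is consistent with copay-only drug offsets and
  gross medical differences. `deductible_mode = "combined"` instead
  credits it against each member-year's modelled spend, which is also the
  configuration used by the perspective-collapse check (zero turnover,
  zero cost sharing, zero premiums makes the payer identical to the
  health system).

NPV is avoided cost plus premium revenue minus treatment cost; ROI is
NPV over treatment cost; both breakeven prices are unique roots of
functions affine in price.

```{r payer}
payer_result(params, insurance_parameters(), price = 14000)
breakeven_table(params)
```

## Probabilistic sensitivity analysis

Each of the (default 1,000) draws perturbs every uncertain quantity once,
shared by both arms:

* Costs and post-event utility floors: beta distributions rescaled to
  their printed intervals with mean at the point estimate
  (concentration 8, so a symmetric interval gives Beta(4,4)). The printed
  stroke-utility interval (0.52–0.87) does not contain its 0.46 point
  estimate; the sampled mean is clamped to the interval's edge region.
  Drawn floors are capped at the on-treatment utility.
* Turnover: normal (0.122, se 0.0071), truncated to [0, 1]. The 65+
  premium, deductible and all tier copays are drawn from their printed
  intervals; the pre-65 premium and deductible ranges are age-band
  descriptors, not uncertainty, and stay fixed.
* Risk-equation coefficients: independent normals around the published
  values. The source publishes no usable coefficient standard errors;
  the packaged values are a reconstruction set to 2% of each
  coefficient's magnitude, propagated through the uncentered linear
  predictor, a scale consistent with the published acceptability of the
  therapy at low prices. The draw enters as a per-age hazard ratio
  applied to first and subsequent event probabilities in both arms.
* The PCSK9 price is a scenario value, never drawn.

Acceptability at a price is the fraction of draws with ICER at or below
the WTP threshold (health system) or with positive ROI (payer), with
binomial standard errors. Surfaces are monotone in price and threshold,
and bit-reproducible given a seed.

```{r psa, eval = FALSE}
surf <- acceptability_surface(n_draws = 1000, seed = 1)
autoplot(surf)
```

A caveat on spread: the published acceptability figures at \$2,500,
\$5,000 and \$7,500 imply mutually inconsistent ICER dispersions (no
single uncertainty scale reproduces all three against the published
deterministic ICERs). The packaged scale anchors the \$2,500/WTP-100k
point (99.8%); the \$5,000 point then computes near 29% rather than the
published 38%.

## Validation by microsimulation

`simulate_population()` pushes individual patients through Bernoulli
draws from the *same* transition matrices and accrues the *same*
per-state costs and utilities, so its population means must converge to
the cohort engine's expectations. The test suite asserts agreement within
3 Monte Carlo standard errors at 200,000 patients per arm for discounted
cost, QALYs, life years and event counts — the package's central
correctness property. The microsimulation uses one seeded RNG stream for
the whole population (vectorised cycle updates), so a population is
reproducible by seed; per-patient stream independence is not claimed.

```{r validate, eval = FALSE}
validation_report(params, n = 200000, seed = 1)
```

## Problem sizes and numerics

The deterministic model is 43 cycles over 21 states and runs in ~0.1 s;
reported analyses use 1,000 PSA draws per price and 200,000
microsimulation patients per arm. Root searches bracket [0, 10^5]
(WTP breakeven) and [0, 3×10^4] (payer breakeven) with tolerance 1e-6;
both target functions are affine in price (the payer NPV has a kink at
the annual tier-2 copay, below which the payer's drug outlay is zero).
ICERs are undefined (and error) when the QALY difference is zero.
Ten-year risks are capped just below 1 before annualisation.

## Known limitations

* The true age-dependent probability curves behind the printed ranges are
  not public; two documented reconstructions are provided, and all
  reproduction claims are conditional on them.
* The per-type event split is proportional to the printed per-type
  profiles; how "other CVD" was separated in the source data is unknown.
* Patients completing five post-CVD years revert to normal life but keep
  first-event (not elevated) risk thereafter; the alternative was
  indistinguishable given the published constraints.
* No coronary revascularisation, no societal perspective, no premium
  re-pricing feedback, and treatment persistence is perfect — the model
  prices the therapy, it does not forecast utilisation.
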