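# a parameter set with every event and death probability zeroed, so the
# whole cohort stays in normal life for all 43 cycles
zero_risk_params <- function(...) {
  z <- c(0, 0)
  model_parameters(
    first_event_source = "anchors",
    first_event_anchors = list(
      sabatine = list(mi = z, stroke = z, other = z),
      framingham = list(mi = z, stroke = z, other = z)
    ),
    subsequent_event_anchors = list(mi = z, stroke = z, other = z),
    acute_mortality_anchors = list(mi = z, stroke = z, other = z),
    post_mortality_anchors = list(mi = z, stroke = z, other = z),
    non_cvd_mortality_anchors = z,
    ...
  )
}

# cost-sharing-free insurance, used by the perspective-collapse property
frictionless_insurance <- function(...) {
  insurance_parameters(
    turnover = 0,
    premium_monthly_pre65 = 0, premium_monthly_65plus = 0,
    deductible_pre65 = 0, deductible_65plus = 0,
    copay_tier1_pre65 = 0, copay_tier2_pre65 = 0,
    copay_tier1_65plus = 0, copay_tier2_65plus = 0,
    ...
  )
}
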