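test_that("registry holds every published model input at its printed value", {
  p <- model_parameters()
  # costs
  expect_equal(p$statin_annual_cost, 48)
  expect_equal(p$pcsk9_annual_cost, 12048)
  expect_equal(p$baseline_care_annual_cost, 215)
  expect_equal(unname(p$event_costs), c(11071, 18516, 14794))
  expect_equal(unname(p$post_event_first_year_costs), c(7747, 7770, 7759))
  # other-CVD acute cost is the MI/stroke average (printed rounded)
  expect_equal(p$event_costs[["other"]], round((11071 + 18516) / 2))
  # utilities
  expect_equal(p$utility_on_treatment, 0.79)
  expect_equal(unname(p$post_event_utility_floor), c(0.58, 0.46, 0.63))
  # effects and rates
  expect_equal(p$rrr_cvd, 0.492)
  expect_equal(p$ldl_reduction, 0.61)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$post_cost_decay, 0.25)
  expect_identical(c(p$start_age, p$end_age), c(58L, 100L))
  # event/mortality probability anchors
  expect_equal(p$first_event_anchors$sabatine$mi, c(0.0030, 0.0168))
  expect_equal(p$first_event_anchors$sabatine$stroke, c(0.0005, 0.0028))
  expect_equal(p$first_event_anchors$sabatine$other, c(0.0025, 0.0140))
  expect_equal(p$first_event_anchors$framingham$mi, c(0.0014, 0.0116))
  expect_equal(p$first_event_anchors$framingham$stroke, c(0.0008, 0.0063))
  expect_equal(p$first_event_anchors$framingham$other, c(0.0023, 0.0165))
  expect_equal(p$subsequent_event_anchors$mi, c(0.0048, 0.0186))
  expect_equal(p$subsequent_event_anchors$stroke, c(0.0032, 0.0102))
  expect_equal(p$subsequent_event_anchors$other, c(0.0093, 0.0283))
  expect_equal(p$acute_mortality_anchors$mi, c(0.082, 0.985))
  expect_equal(p$acute_mortality_anchors$stroke, c(0.059, 0.934))
  expect_equal(p$acute_mortality_anchors$other, c(0.070, 0.960))
  expect_equal(p$post_mortality_anchors$mi, c(0.036, 0.673))
  expect_equal(p$post_mortality_anchors$stroke, c(0.033, 0.609))
  expect_equal(p$post_mortality_anchors$other, c(0.034, 0.641))
  expect_equal(p$non_cvd_mortality_anchors, c(0.005, 0.183))
  # cohort risk-factor profile
  rp <- p$risk_profile
  expect_equal(rp$male_fraction, 0.52)
  expect_equal(rp$treated_htn_fraction, 0.88)
  expect_equal(c(rp$sbp_treated, rp$sbp_untreated), c(128, 133))
  expect_equal(c(rp$smoker_fraction, rp$diabetes_fraction), c(0.16, 0.13))
  expect_equal(c(rp$hdl, rp$ldl, rp$total_chol), c(51, 120, 202))
  # insurance
  ins <- insurance_parameters()
  expect_equal(ins$turnover, 0.122)
  expect_equal(ins$turnover_se, 0.0071)
  expect_equal(c(ins$premium_monthly_pre65, ins$premium_monthly_65plus),
               c(520, 835))
  expect_equal(c(ins$deductible_pre65, ins$deductible_65plus), c(3731, 2158))
  expect_equal(c(ins$copay_tier1_pre65, ins$copay_tier2_pre65), c(11, 31))
  expect_equal(c(ins$copay_tier1_65plus, ins$copay_tier2_65plus), c(5, 11))
})

test_that("cost uncertainty ranges follow the +/-25 percent convention", {
  dist <- parameter_distributions()
  cost_rows <- dist[grepl("cost", dist$parameter), ]
  expect_gt(nrow(cost_rows), 6)
  expect_equal(cost_rows$low, 0.75 * cost_rows$base)
  expect_equal(cost_rows$high, 1.25 * cost_rows$base)
  # the statin row reproduces the printed 36-60 interval
  statin <- dist[dist$parameter == "statin_annual_cost", ]
  expect_equal(c(statin$low, statin$high), c(36, 60))
  pcsk9 <- dist[dist$parameter == "pcsk9_annual_cost", ]
  expect_equal(c(pcsk9$low, pcsk9$high), c(9036, 15060))
})

test_that("age profiles hit both anchors and are monotone", {
  pr <- build_age_profile(0.003, 0.0168, "exponential")
  expect_equal(pr$value[pr$age == 58], 0.003)
  expect_equal(pr$value[pr$age == 100], 0.0168)
  expect_true(all(diff(pr$value) >= 0))
  expect_equal(min(pr$value), 0.003)
  expect_equal(max(pr$value), 0.0168)
  lin <- build_age_profile(0.01, 0.01, "linear")
  expect_equal(lin$value, rep(0.01, 43))
  expect_error(build_age_profile(0.02, 0.01), "invalid-anchor")
  # linear shape is exact arithmetic interpolation
  lin2 <- build_age_profile(0, 0.42, "linear")
  expect_equal(lin2$value, seq(0, 0.42, by = 0.01))
})

test_that("configs round-trip and invalid values are rejected by key", {
  p <- model_parameters()
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(p, path)
  p2 <- read_config(path)
  for (f in c("pcsk9_price", "discount_rate", "rrr_cvd", "scenario",
              "event_costs", "post_event_utility_floor")) {
    expect_equal(p2[[f]], p[[f]], info = f)
  }
  # override survives the round trip
  write_config(model_parameters(pcsk9_price = 2500), path)
  expect_equal(read_config(path)$pcsk9_price, 2500)
  # invariant violations name the offending field
  expect_error(model_parameters(utility_on_treatment = 1.5),
               "utility_on_treatment")
  expect_error(model_parameters(post_event_utility_floor =
                                  c(mi = 0.9, stroke = 0.46, other = 0.63)),
               "post_event_utility_floor")
  expect_error(model_parameters(start_age = 101L), "start_age")
  # unknown keys are a parse error
  writeLines("not_a_field: 3", path)
  expect_error(read_config(path), "parse-error.*not_a_field")
})

test_that("resolved age profile table covers every profile over all ages", {
  ap <- age_profiles()
  expect_equal(sort(unique(ap$age)), 58:100)
  expect_equal(sum(ap$quantity == "first_event_sabatine"), 3 * 43)
  expect_true(all(ap$value >= 0 & ap$value <= 1))
})
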