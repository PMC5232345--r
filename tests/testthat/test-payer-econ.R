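test_that("enrollment weights decay geometrically with turnover", {
  expect_equal(enrollment_weight(0, 0.122), 1)
  expect_equal(enrollment_weight(1, 0.122), 0.878)
  expect_equal(enrollment_weight(5, 0.122), 0.878^5)
  expect_equal(enrollment_weight(3, 1), 0)
})

test_that("payer-borne cost applies tier copays and the deductible floor", {
  ins <- insurance_parameters()
  # PCSK9 member aged 60: annual tier-2 copay offset is 12 x 31 = 372
  expect_equal(payer_borne_cost(list(pcsk9 = 14000), 60, ins), 14000 - 372)
  # statins cost less than their copay: payer pays zero
  expect_equal(payer_borne_cost(list(statin = 48), 60, ins), 0)
  expect_equal(payer_borne_cost(list(statin = 48), 70, ins), 0)
  # combined mode credits the age-band deductible against medical spend
  ins2 <- insurance_parameters(deductible_mode = "combined")
  expect_equal(payer_borne_cost(list(medical = 11071), 70, ins2),
               11071 - 2158)
  expect_equal(payer_borne_cost(list(medical = 11071), 60, ins2),
               11071 - 3731)
  # spend below copay plus deductible: payer pays zero
  expect_equal(payer_borne_cost(list(pcsk9 = 300, medical = 200), 60, ins2), 0)
})

test_that("identical survival yields zero incremental premium revenue", {
  p <- zero_risk_params()
  traces <- pcsk9cea:::cohort_pair(p)
  res <- compute_payer_result(traces$statin_pcsk9, traces$statin_only,
                              p, insurance_parameters(), price = 14000)
  expect_equal(res$premium_revenue, 0)
  expect_equal(res$avoided_cost, 0)
})

test_that("full churn leaves only first-cycle premiums", {
  p <- model_parameters()
  ins <- insurance_parameters(turnover = 1)
  tr <- run_cohort(p, "statin_only")
  expect_equal(premium_revenue(tr, ins, p), 520 * 12)
  # claims are weighted by enrollment carried through the cycle: none remain
  flows <- pcsk9cea:::payer_cash_flows(tr, p, ins)
  expect_equal(flows$treatment, 0)
  expect_equal(flows$medical, 0)
})

test_that("NPV and ROI satisfy their defining identities", {
  p <- model_parameters()
  ins <- insurance_parameters()
  res <- payer_result(p, ins, price = 14000)
  expect_equal(res$npv,
               res$avoided_cost + res$premium_revenue - res$treatment_cost)
  expect_equal(res$roi, res$npv / res$treatment_cost)
})

test_that("NPV is exactly affine and strictly decreasing in price", {
  p <- model_parameters()
  ins <- insurance_parameters()
  traces <- pcsk9cea:::cohort_pair(p)
  prices <- c(1000, 7000, 13000)  # above the copay kink
  npvs <- vapply(prices, function(pr)
    payer_result(p, ins, price = pr, traces = traces)$npv, numeric(1))
  slope1 <- (npvs[2] - npvs[1]) / (prices[2] - prices[1])
  slope2 <- (npvs[3] - npvs[2]) / (prices[3] - prices[2])
  expect_lt(slope1, 0)
  expect_equal(slope1, slope2, tolerance = 1e-9)
  # the affine root agrees with the search root, and ROI crosses zero there
  root_affine <- prices[1] - npvs[1] / slope1
  root <- payer_breakeven_price(p, ins)
  expect_equal(root, root_affine, tolerance = 1e-4)
  expect_equal(payer_result(p, ins, price = root, traces = traces)$roi, 0,
               tolerance = 1e-6)
})

test_that("payer reduces to the health system without frictions", {
  p <- model_parameters()
  ins <- frictionless_insurance(deductible_mode = "combined")
  traces <- pcsk9cea:::cohort_pair(p)
  pay <- compute_payer_result(traces$statin_pcsk9, traces$statin_only, p,
                              ins, price = 14000)
  h <- cea(p, price = 14000, traces = traces)
  expect_equal(pay$treatment_cost, h$treatment_cost)
  expect_equal(pay$avoided_cost, h$avoided_cost)
  expect_equal(pay$premium_revenue, 0)
})

test_that("payer benefits never exceed the health system's", {
  p <- model_parameters()
  ins <- insurance_parameters()
  traces <- pcsk9cea:::cohort_pair(p)
  pay <- compute_payer_result(traces$statin_pcsk9, traces$statin_only, p,
                              ins, price = 14000)
  h <- cea(p, price = 14000, traces = traces)
  expect_lt(pay$avoided_cost, h$avoided_cost)
  expect_lt(pay$treatment_cost, h$treatment_cost)
})
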