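test_that("discounting follows present-value arithmetic", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(103, 1, 0.03), 100)
  expect_equal(discount(100, 2, 0), 100)
})

test_that("state cost and utility schedules match the published rules", {
  p <- model_parameters()
  decay <- (1 - p$post_cost_decay)^(0:4)
  # post-MI year 2 cost: 25% off the first post year
  expect_equal(7747 * decay[2], 5810.25)
  # utility recovery path: floors at post year 1, full recovery at year 5
  u <- pcsk9cea:::state_utilities(p)
  expect_equal(unname(u["post_stroke_1"]), 0.46)
  expect_equal(unname(u["post_mi_5"]), 0.79)
  expect_equal(unname(u["post_other_5"]), 0.79)
  expect_equal(unname(u["acute_mi"]), 0.58)
  expect_equal(unname(u[c("dead_cvd", "dead_other")]), c(0, 0))
  # concave and monotone along each tunnel
  path <- unname(u[paste0("post_stroke_", 1:5)])
  expect_true(all(diff(path) > 0))
  expect_true(all(diff(diff(path)) < 0))
})

test_that("a risk-free cohort accrues pure therapy costs and utilities", {
  p <- zero_risk_params(utility_age_gradient = 0)
  tr <- run_cohort(p, "statin_pcsk9", price = 14000)
  d <- (1.03)^-(0:42)
  expect_equal(accrue_costs(tr, p, price = 14000),
               sum((48 + 215 + 14000) * d))
  expect_equal(accrue_qalys(tr, p), sum(0.79 * d))
  # with the age gradient, QALYs fall linearly with age
  p2 <- zero_risk_params()
  tr2 <- run_cohort(p2, "statin_only")
  expect_equal(accrue_qalys(tr2, p2), sum((0.79 - 0.0035 * (0:42)) * d))
})

test_that("ICER matches its defining identity and rejects equal arms", {
  p <- model_parameters()
  traces <- pcsk9cea:::cohort_pair(p)
  h <- cea(p, price = 14000, traces = traces)
  expect_equal(h$icer, (h$treatment_cost - h$avoided_cost) / h$delta_qaly)
  a <- arm_economics(traces$statin_pcsk9, p, 14000)
  b <- arm_economics(traces$statin_only, p, 14000)
  expect_equal(compute_icer(a, b), h$icer)
  expect_error(compute_icer(a, a), "undefined-icer")
})

test_that("ICER is exactly affine and strictly increasing in price", {
  p <- model_parameters()
  traces <- pcsk9cea:::cohort_pair(p)
  prices <- c(1000, 7000, 13000)
  icers <- vapply(prices, function(pr)
    cea(p, price = pr, traces = traces)$icer, numeric(1))
  slope1 <- (icers[2] - icers[1]) / (prices[2] - prices[1])
  slope2 <- (icers[3] - icers[2]) / (prices[3] - prices[2])
  expect_gt(slope1, 0)
  expect_equal(slope1, slope2, tolerance = 1e-9)
  # the affine fit predicts the root-search breakeven
  p_affine <- prices[1] + (1e5 - icers[1]) / slope1
  expect_equal(wtp_breakeven_price(p, 1e5), p_affine, tolerance = 1e-4)
})

test_that("avoided cost is price-independent and positive", {
  p <- model_parameters()
  traces <- pcsk9cea:::cohort_pair(p)
  av <- vapply(c(500, 5000, 15000), function(pr)
    cea(p, price = pr, traces = traces)$avoided_cost, numeric(1))
  expect_equal(av[1], av[2])
  expect_equal(av[1], av[3])
  expect_gt(av[1], 0)
})

test_that("the breakeven search solves its own fixed point", {
  p <- model_parameters()
  icer500 <- cea(p, price = 500)$icer
  expect_equal(wtp_breakeven_price(p, wtp = icer500), 500, tolerance = 1e-3)
  expect_error(wtp_breakeven_price(p, wtp = 1, interval = c(5000, 6000)),
               "no-breakeven")
})
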