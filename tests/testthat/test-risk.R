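test_that("10-year risk reduces to the baseline risk at the covariate mean", {
  eq <- framingham_gcvd()$men
  rp <- model_parameters()$risk_profile
  # force the linear predictor to equal the stored mean
  x <- pcsk9cea:::risk_covariates(rp, age = 58)
  eq$mean_lp <- sum(eq$coefficients[names(x)] * x)
  expect_equal(ten_year_cvd_risk(rp, eq, age = 58),
               1 - eq$baseline_survival_10yr)
  # all-zero coefficients: any profile sits at the baseline
  eq0 <- list(coefficients = 0 * eq$coefficients,
              baseline_survival_10yr = 0.9, mean_lp = 0)
  expect_equal(ten_year_cvd_risk(rp, eq0, age = 73), 0.1)
})

test_that("packaged equations match an independent arithmetic evaluation", {
  # spreadsheet-style evaluation of the published coefficients at the
  # cohort-average covariates, frozen before the engine was written
  lp_men <- 3.06117 * log(58) + 1.12370 * log(202) - 0.93263 * log(51) +
    0.88 * 1.99881 * log(128) + 0.12 * 1.93303 * log(133) +
    0.65451 * 0.16 + 0.57367 * 0.13
  expect_equal(lp_men, 24.5758421098, tolerance = 1e-10)
  rp <- model_parameters()$risk_profile
  eqs <- framingham_gcvd()
  expect_equal(ten_year_cvd_risk(rp, eqs$men, age = 58),
               0.1916176949, tolerance = 1e-9)
  expect_equal(ten_year_cvd_risk(rp, eqs$women, age = 58),
               0.1020003477, tolerance = 1e-9)
  expect_equal(pcsk9cea:::cohort_ten_year_risk(rp, 58),
               0.1486013682, tolerance = 1e-9)
  expect_equal(annualize_risk(0.1486013682), 0.0159587708,
               tolerance = 1e-8)
})

test_that("annualization inverts the 10-year compounding", {
  expect_equal(annualize_risk(0), 0)
  expect_equal(annualize_risk(1 - (1 - 0.01)^10), 0.01)
  expect_equal(annualize_risk(0.10), 1 - 0.9^0.1)
  expect_error(annualize_risk(1), "degenerate-risk")
})

test_that("relative risk reduction is multiplicative", {
  expect_equal(apply_relative_risk(0.01, 0.492), 0.00508)
  expect_equal(apply_relative_risk(0.37, 0), 0.37)
  expect_equal(apply_relative_risk(0, 0.9), 0)
})

test_that("anchor mode reproduces the printed probabilities at the anchors", {
  p <- model_parameters(first_event_source = "anchors")
  pr58 <- annual_event_probabilities(58, "statin_only", params = p)
  expect_equal(pr58$p_mi, 0.0030)
  expect_equal(pr58$p_stroke, 0.0005)
  expect_equal(pr58$p_mi_subsequent, 0.0048)
  pr100 <- annual_event_probabilities(100, "statin_only", params = p)
  expect_equal(pr100$p_mi, 0.0168)
  # generated probabilities stay within the printed ranges at every age
  tab <- event_probability_table("statin_only", params = p)
  first <- tab[tab$quantity == "first_event", ]
  for (ev in c("mi", "stroke", "other")) {
    anc <- p$first_event_anchors$sabatine[[ev]]
    v <- first$probability[first$event == ev]
    expect_true(all(v >= anc[1] - 1e-12 & v <= anc[2] + 1e-12))
  }
})

test_that("PCSK9 arm probabilities equal statin arm times 1 - RRR", {
  p <- model_parameters()
  for (age in c(58, 70, 100)) {
    a <- annual_event_probabilities(age, "statin_pcsk9", params = p)
    b <- annual_event_probabilities(age, "statin_only", params = p)
    for (col in c("p_mi", "p_stroke", "p_other", "p_mi_subsequent",
                  "p_stroke_subsequent", "p_other_subsequent")) {
      expect_equal(a[[col]] / b[[col]], 1 - 0.492, info = col)
    }
  }
})

test_that("LDL imputation weakly lowers every event probability", {
  p <- model_parameters(scenario = "framingham_ldl")
  for (age in c(58, 80, 100)) {
    a <- annual_event_probabilities(age, "statin_pcsk9", params = p)
    b <- annual_event_probabilities(age, "statin_only", params = p)
    expect_true(all(unlist(a[-1]) <= unlist(b[-1])))
    expect_true(all(unlist(a[-1]) < unlist(b[-1])))
  }
  # a larger LDL reduction cannot raise risk
  p2 <- model_parameters(scenario = "framingham_ldl", ldl_reduction = 0.8)
  a61 <- annual_event_probabilities(70, "statin_pcsk9", params = p)
  a80 <- annual_event_probabilities(70, "statin_pcsk9", params = p2)
  expect_true(all(unlist(a80[-1]) <= unlist(a61[-1])))
})

test_that("mortality probabilities sit on their anchors and are monotone", {
  expect_equal(mortality_probability(58, "after_mi"), 0.082)
  expect_equal(mortality_probability(100, "after_mi"), 0.985)
  expect_equal(mortality_probability(58, "non_cvd"), 0.005)
  expect_equal(mortality_probability(100, "non_cvd"), 0.183)
  expect_equal(mortality_probability(58, "after_post_stroke"), 0.033)
  for (st in c("after_mi", "after_post_other", "non_cvd")) {
    v <- mortality_probability(58:100, st)
    expect_true(all(diff(v) >= 0), info = st)
  }
  expect_error(mortality_probability(58, "zombie"), "domain-error")
  expect_error(mortality_probability(101, "non_cvd"), "domain-error")
})
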