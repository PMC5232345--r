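#' Framingham general cardiovascular risk equations
#'
#' Sex-specific Cox-model coefficients, 10-year baseline survival and mean
#' linear predictor of the Framingham general-CVD risk profile (D'Agostino
#' et al., 2008), packaged as constants. Covariates are log age, log total
#' cholesterol, log HDL cholesterol, log systolic blood pressure (separate
#' coefficients for treated and untreated hypertension), current smoking and
#' diabetes.
#'
#' `coef_se` holds the per-coefficient standard deviations used when the
#' probabilistic sensitivity analysis perturbs the equation; the source does
#' not publish usable coefficient standard errors, so these are a package
#' reconstruction set to 2 percent of each coefficient's magnitude (see the
#' methods vignette).
#'
#' @return A list with elements `men` and `women`, each containing
#'   `coefficients` (named numeric), `baseline_survival_10yr`, `mean_lp` and
#'   `coef_se`.
#' @examples
#' framingham_gcvd()$men$baseline_survival_10yr   # 0.88936
#' @export
framingham_gcvd <- function() {
  men_beta <- c(ln_age = 3.06117, ln_total_chol = 1.12370,
                ln_hdl = -0.93263, ln_sbp_treated = 1.99881,
                ln_sbp_untreated = 1.93303, smoker = 0.65451,
                diabetes = 0.57367)
  women_beta <- c(ln_age = 2.32888, ln_total_chol = 1.20904,
                  ln_hdl = -0.70833, ln_sbp_treated = 2.82263,
                  ln_sbp_untreated = 2.76157, smoker = 0.52873,
                  diabetes = 0.69154)
  list(
    men = list(coefficients = men_beta, baseline_survival_10yr = 0.88936,
               mean_lp = 23.9802, coef_se = 0.02 * abs(men_beta)),
    women = list(coefficients = women_beta, baseline_survival_10yr = 0.95012,
                 mean_lp = 26.1931, coef_se = 0.02 * abs(women_beta))
  )
}

# covariate vector matching the coefficient order, from a cohort-average
# risk-factor profile; binary covariates enter as cohort fractions
risk_covariates <- function(profile, age = NULL, total_chol = NULL) {
  age <- age %||% profile$age
  tc <- total_chol %||% profile$total_chol
  tr <- profile$treated_htn_fraction
  c(ln_age = log(age),
    ln_total_chol = log(tc),
    ln_hdl = log(profile$hdl),
    ln_sbp_treated = tr * log(profile$sbp_treated),
    ln_sbp_untreated = (1 - tr) * log(profile$sbp_untreated),
    smoker = profile$smoker_fraction,
    diabetes = profile$diabetes_fraction)
}

#' 10-year cardiovascular risk from a proportional-hazards risk equation
#'
#' Evaluates `1 - S0(10) ^ exp(LP - mean_lp)` where `LP` is the linear
#' predictor of the profile's covariates under the equation's coefficients.
#' A profile whose linear predictor equals the equation's mean has exactly
#' the baseline risk `1 - S0(10)`.
#'
#' @param profile a risk-factor profile: a list with fields `age` (or pass
#'   `age`), `total_chol`, `hdl`, `sbp_treated`, `sbp_untreated`,
#'   `treated_htn_fraction`, `smoker_fraction`, `diabetes_fraction`.
#' @param equation one sex's equation from [framingham_gcvd()] (elements
#'   `coefficients`, `baseline_survival_10yr`, `mean_lp`).
#' @param age,total_chol optional overrides of the profile fields.
#' @return 10-year risk, a probability in \[0, 1\].
#' @export
ten_year_cvd_risk <- function(profile, equation, age = NULL,
                              total_chol = NULL) {
  x <- risk_covariates(profile, age = age, total_chol = total_chol)
  lp <- sum(equation$coefficients[names(x)] * x)
  risk <- 1 - equation$baseline_survival_10yr ^ exp(lp - equation$mean_lp)
  min(max(risk, 0), 1)
}

# male-fraction-weighted cohort risk across the two sex equations
cohort_ten_year_risk <- function(profile, age, total_chol = NULL,
                                 equations = framingham_gcvd()) {
  mf <- profile$male_fraction
  mf * ten_year_cvd_risk(profile, equations$men, age, total_chol) +
    (1 - mf) * ten_year_cvd_risk(profile, equations$women, age, total_chol)
}

# vectorized over the model ages: covariate matrix (only log age varies)
cohort_covariate_matrix <- function(params, total_chol = NULL) {
  rp <- params$risk_profile
  ages <- model_ages(params)
  tc <- total_chol %||% rp$total_chol
  tr <- rp$treated_htn_fraction
  cbind(ln_age = log(ages), ln_total_chol = log(tc), ln_hdl = log(rp$hdl),
        ln_sbp_treated = tr * log(rp$sbp_treated),
        ln_sbp_untreated = (1 - tr) * log(rp$sbp_untreated),
        smoker = rp$smoker_fraction, diabetes = rp$diabetes_fraction)
}

# cohort 10-year risk at every model age; beta overrides support the PSA's
# coefficient perturbation (mean_lp stays at the published value)
cohort_risk10_by_age <- function(params, equations = framingham_gcvd(),
                                 total_chol = NULL, beta_men = NULL,
                                 beta_women = NULL) {
  X <- cohort_covariate_matrix(params, total_chol)
  one_sex <- function(eq, beta) {
    beta <- beta %||% eq$coefficients
    lp <- drop(X %*% beta[colnames(X)])
    pmin(pmax(1 - eq$baseline_survival_10yr ^ exp(lp - eq$mean_lp), 0), 1)
  }
  mf <- params$risk_profile$male_fraction
  mf * one_sex(equations$men, beta_men) +
    (1 - mf) * one_sex(equations$women, beta_women)
}

#' Convert a 10-year risk to an annual probability
#'
#' Under a constant hazard over the decade, the annual probability `p`
#' satisfies `(1 - p)^10 = 1 - risk10`, i.e. `p = 1 - (1 - risk10)^(1/10)`.
#'
#' @param risk10 10-year risk in \[0, 1).
#' @return annual probability.
#' @examples
#' annualize_risk(0)                       # 0
#' annualize_risk(1 - (1 - 0.01)^10)       # 0.01
#' @export
annualize_risk <- function(risk10) {
  if (any(risk10 >= 1)) {
    stop("degenerate-risk: 10-year risk must be below 1", call. = FALSE)
  }
  if (any(risk10 < 0)) stop("risk must be non-negative", call. = FALSE)
  1 - (1 - risk10)^(1 / 10)
}

#' Apply a relative risk reduction to a probability
#'
#' @param p annual event probability in \[0, 1\].
#' @param rrr relative risk reduction in \[0, 1\].
#' @return `p * (1 - rrr)`.
#' @examples
#' apply_relative_risk(0.01, 0.492)   # 0.00508
#' @export
apply_relative_risk <- function(p, rrr) {
  stopifnot(all(p >= 0 & p <= 1), all(rrr >= 0 & rrr <= 1))
  p * (1 - rrr)
}

# ---- internal hazard tables ------------------------------------------------

# Per-age (rows) x event-type (columns mi/stroke/other) probability tables
# for one scenario, plus the PCSK9-arm hazard multiplier per age.
#
# First events: under "framingham_survival", the total annual CVD probability
# of the ageing cohort comes from the risk equation (annualized 10-year
# risk), distributed across event types proportionally to the scenario's
# per-type anchor profiles. Under "anchors", the per-type anchor profiles
# are the statin-arm probabilities directly.
#
# PCSK9-arm multiplier: trial_rrr applies (1 - rrr_cvd) to first and
# subsequent events at every age; framingham_ldl applies the per-age ratio
# of annualized risks with total cholesterol lowered by
# ldl_reduction * ldl, holding HDL fixed.
hazard_tables <- function(params, scenario = params$scenario,
                          hazard_scale = NULL, equations = framingham_gcvd()) {
  ages <- model_ages(params)
  shape <- params$profile_shape
  prof <- function(anchors) {
    vapply(anchors, function(a) profile_values(a[1], a[2], shape, ages),
           numeric(length(ages)))
  }
  split_source <- switch(scenario, trial_rrr = "sabatine",
                         framingham_ldl = "framingham",
                         stop("unknown scenario: ", scenario, call. = FALSE))
  split_prof <- prof(params$first_event_anchors[[split_source]])
  rp <- params$risk_profile
  if (params$first_event_source == "framingham_survival") {
    risk10 <- cohort_risk10_by_age(params, equations)
    p_total <- annualize_risk(pmin(risk10, 1 - 1e-9))
    if (!is.null(hazard_scale)) p_total <- pmin(p_total * hazard_scale, 0.999)
    first <- split_prof / rowSums(split_prof) * p_total
  } else {
    first <- split_prof
    if (!is.null(hazard_scale)) first <- pmin(first * hazard_scale, 0.999)
  }
  subs <- prof(params$subsequent_event_anchors)
  if (!is.null(hazard_scale)) subs <- pmin(subs * hazard_scale, 0.999)
  pcsk9_multiplier <- if (scenario == "trial_rrr") {
    rep(1 - params$rrr_cvd, length(ages))
  } else {
    tc_reduced <- rp$total_chol - params$ldl_reduction * rp$ldl
    risk10_base <- cohort_risk10_by_age(params, equations)
    risk10_red <- cohort_risk10_by_age(params, equations, tc_reduced)
    annualize_risk(pmin(risk10_red, 1 - 1e-9)) /
      annualize_risk(pmin(risk10_base, 1 - 1e-9))
  }
  list(
    ages = ages,
    first = first,
    subsequent = subs,
    acute_mortality = prof(params$acute_mortality_anchors),
    post_mortality = prof(params$post_mortality_anchors),
    non_cvd_mortality = profile_values(params$non_cvd_mortality_anchors[1],
                                       params$non_cvd_mortality_anchors[2],
                                       shape, ages),
    pcsk9_multiplier = pcsk9_multiplier
  )
}

arm_multiplier <- function(tables, arm) {
  if (arm == "statin_pcsk9") tables$pcsk9_multiplier
  else rep(1, length(tables$ages))
}

check_age <- function(age, params) {
  if (any(age < params$start_age | age > params$end_age)) {
    stop(sprintf("domain-error: age must lie in [%d, %d]",
                 params$start_age, params$end_age), call. = FALSE)
  }
  invisible(age)
}

#' Annual event probabilities by age and arm
#'
#' First and subsequent CVD event probabilities (myocardial infarction,
#' stroke, other CVD) for one or more ages under a treatment arm and
#' scenario. Under `trial_rrr` the PCSK9 arm equals the statin arm times
#' `1 - rrr_cvd` for every event type at every age; under `framingham_ldl`
#' the PCSK9 arm is recomputed from the risk equation with LDL cholesterol
#' reduced by `ldl_reduction`.
#'
#' @param age integer age(s) within the model horizon.
#' @param arm `"statin_only"` or `"statin_pcsk9"`.
#' @param scenario `"trial_rrr"` or `"framingham_ldl"` (defaults to the
#'   parameter set's scenario).
#' @param params A `pcsk9_params` object.
#' @return A tibble with columns `age`, `p_mi`, `p_stroke`, `p_other`,
#'   `p_mi_subsequent`, `p_stroke_subsequent`, `p_other_subsequent`.
#' @export
annual_event_probabilities <- function(age,
                                       arm = c("statin_only", "statin_pcsk9"),
                                       scenario = NULL,
                                       params = model_parameters()) {
  arm <- match.arg(arm)
  scenario <- scenario %||% params$scenario
  check_age(age, params)
  tab <- hazard_tables(params, scenario)
  m <- arm_multiplier(tab, arm)
  i <- match(age, tab$ages)
  tibble::tibble(
    age = as.integer(age),
    p_mi = unname(tab$first[i, 1] * m[i]),
    p_stroke = unname(tab$first[i, 2] * m[i]),
    p_other = unname(tab$first[i, 3] * m[i]),
    p_mi_subsequent = unname(tab$subsequent[i, 1] * m[i]),
    p_stroke_subsequent = unname(tab$subsequent[i, 2] * m[i]),
    p_other_subsequent = unname(tab$subsequent[i, 3] * m[i])
  )
}

#' Annual mortality probability by age and state
#'
#' Mortality probabilities anchored to the printed age-dependent ranges:
#' acute event-year CVD case fatality (`after_mi`, `after_stroke`,
#' `after_other`), post-CVD annual mortality (`after_post_mi`, ...), and
#' non-CVD background mortality (`non_cvd`).
#'
#' @param age integer age(s) within the model horizon.
#' @param state one of `"after_mi"`, `"after_stroke"`, `"after_other"`,
#'   `"after_post_mi"`, `"after_post_stroke"`, `"after_post_other"`,
#'   `"non_cvd"`.
#' @param params A `pcsk9_params` object.
#' @return numeric probability vector.
#' @examples
#' mortality_probability(58, "after_mi")    # 0.082, the lower anchor
#' mortality_probability(100, "non_cvd")    # 0.183, the upper anchor
#' @export
mortality_probability <- function(age, state, params = model_parameters()) {
  check_age(age, params)
  states <- c("after_mi", "after_stroke", "after_other", "after_post_mi",
              "after_post_stroke", "after_post_other", "non_cvd")
  if (!state %in% states) {
    stop("domain-error: unknown mortality state '", state, "'",
         call. = FALSE)
  }
  anchors <- switch(state,
    after_mi = params$acute_mortality_anchors$mi,
    after_stroke = params$acute_mortality_anchors$stroke,
    after_other = params$acute_mortality_anchors$other,
    after_post_mi = params$post_mortality_anchors$mi,
    after_post_stroke = params$post_mortality_anchors$stroke,
    after_post_other = params$post_mortality_anchors$other,
    non_cvd = params$non_cvd_mortality_anchors)
  ages <- model_ages(params)
  profile_values(anchors[1], anchors[2], params$profile_shape,
                 ages)[match(age, ages)]
}

#' Annual probability table for an arm and scenario
#'
#' All per-age transition ingredients for one arm in long format:
#' first-event, subsequent-event and mortality probabilities.
#'
#' @inheritParams annual_event_probabilities
#' @return A tibble with columns `age`, `arm`, `scenario`, `quantity`,
#'   `event`, `probability`.
#' @export
event_probability_table <- function(arm = c("statin_only", "statin_pcsk9"),
                                    scenario = NULL,
                                    params = model_parameters()) {
  arm <- match.arg(arm)
  scenario <- scenario %||% params$scenario
  tab <- hazard_tables(params, scenario)
  m <- arm_multiplier(tab, arm)
  ev <- event_types()
  long <- function(mat, quantity, mult = rep(1, length(tab$ages))) {
    purrr::map_dfr(seq_along(ev), function(k) {
      tibble::tibble(age = as.integer(tab$ages), quantity = quantity,
                     event = ev[k], probability = mat[, k] * mult)
    })
  }
  dplyr::bind_rows(
    long(tab$first, "first_event", m),
    long(tab$subsequent, "subsequent_event", m),
    long(tab$acute_mortality, "acute_mortality"),
    long(tab$post_mortality, "post_mortality"),
    tibble::tibble(age = as.integer(tab$ages), quantity = "mortality",
                   event = "non_cvd", probability = tab$non_cvd_mortality)
  ) |>
    dplyr::mutate(arm = arm, scenario = scenario, .after = "age")
}
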