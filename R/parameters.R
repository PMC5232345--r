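#' Base model parameters
#'
#' Returns the complete set of point estimates and uncertainty ranges used by
#' the cohort model: therapy and event costs, health-state utilities, the
#' relative risk reduction of cardiovascular (CVD) events under PCSK9
#' inhibitor therapy, the age-anchored probability profiles, and the baseline
#' risk-factor profile of the modelled cohort.
#'
#' Two drug-cost fields coexist deliberately: `pcsk9_annual_cost` ($12,048)
#' is the point estimate that seeds the probabilistic sensitivity analysis
#' distribution, while `pcsk9_price` ($14,000) is the market-price scenario
#' used by the base-case analysis and the price grids. They are never
#' harmonised.
#'
#' @param ... named overrides for any field, e.g. `pcsk9_price = 2500` or
#'   `discount_rate = 0`.
#'
#' @return An object of class `pcsk9_params`: a named list validated by
#'   [validate_parameters()].
#'
#' @examples
#' p <- model_parameters()
#' p$pcsk9_annual_cost      # 12048
#' p$utility_on_treatment   # 0.79
#' model_parameters(pcsk9_price = 2500)$pcsk9_price
#' @export
model_parameters <- function(...) {
  p <- list(
    start_age = 58L,
    end_age = 100L,
    discount_rate = 0.03,
    # treatment effect: 1-year relative risk reduction of CVD events under
    # evolocumab + statin vs statin only, excluding non-CVD death and
    # coronary revascularisation
    rrr_cvd = 0.492,
    # LDL-cholesterol reduction used by the risk-equation imputation scenario
    ldl_reduction = 0.61,
    scenario = "trial_rrr",
    # "framingham_survival": total first-event probability from the general
    # CVD risk equation of the ageing cohort, split across event types by the
    # per-type anchor profiles. "anchors": per-type anchor profiles used
    # directly as the statin-arm probabilities.
    first_event_source = "framingham_survival",
    profile_shape = "exponential",
    # annual costs (USD)
    statin_annual_cost = 48,
    pcsk9_annual_cost = 12048,
    pcsk9_price = 14000,
    baseline_care_annual_cost = 215,
    event_costs = c(mi = 11071, stroke = 18516, other = 14794),
    post_event_first_year_costs = c(mi = 7747, stroke = 7770, other = 7759),
    post_cost_decay = 0.25,
    # utilities (EQ-5D index)
    utility_on_treatment = 0.79,
    post_event_utility_floor = c(mi = 0.58, stroke = 0.46, other = 0.63),
    utility_recovery_exponent = 0.5,
    # EQ-5D population-norm decline with age, index points per year from the
    # start age, applied to every alive state
    utility_age_gradient = 0.0035,
    # 1-year first-event probability anchors at ages 58 and 100, by source
    first_event_anchors = list(
      sabatine = list(mi = c(0.0030, 0.0168), stroke = c(0.0005, 0.0028),
                      other = c(0.0025, 0.0140)),
      framingham = list(mi = c(0.0014, 0.0116), stroke = c(0.0008, 0.0063),
                        other = c(0.0023, 0.0165))
    ),
    subsequent_event_anchors = list(mi = c(0.0048, 0.0186),
                                    stroke = c(0.0032, 0.0102),
                                    other = c(0.0093, 0.0283)),
    acute_mortality_anchors = list(mi = c(0.082, 0.985),
                                   stroke = c(0.059, 0.934),
                                   other = c(0.070, 0.960)),
    post_mortality_anchors = list(mi = c(0.036, 0.673),
                                  stroke = c(0.033, 0.609),
                                  other = c(0.034, 0.641)),
    non_cvd_mortality_anchors = c(0.005, 0.183),
    # cohort-average risk-factor profile (trial population)
    risk_profile = list(
      male_fraction = 0.52,
      sbp_treated = 128,
      sbp_untreated = 133,
      treated_htn_fraction = 0.88,
      smoker_fraction = 0.16,
      diabetes_fraction = 0.13,
      hdl = 51,
      ldl = 120,
      total_chol = 202
    )
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  class(p) <- "pcsk9_params"
  validate_parameters(p)
}

#' Private-payer insurance parameters
#'
#' Premiums, deductibles, tiered drug copayments and the annual membership
#' turnover rate for the payer perspective. Members younger than
#' `medicare_age` hold an individual commercial plan; from `medicare_age`
#' onwards a Medicare Advantage plan applies. Statins are covered as tier-1
#' drugs, PCSK9 inhibitors as tier-2.
#'
#' `deductible_mode` controls how the annual deductible enters incremental
#' cash flows: `"exempt"` (default) treats it as exhausted by routine member
#' spending common to both arms, so it cancels between arms; `"combined"`
#' credits it against each member-year's modelled medical spend,
#' `max(0, cost - deductible)`.
#'
#' @param ... named overrides for any field, e.g. `turnover = 0`.
#' @return An object of class `pcsk9_insurance` (named list).
#' @examples
#' insurance_parameters()$turnover        # 0.122
#' insurance_parameters(turnover = 0)
#' @export
insurance_parameters <- function(...) {
  ins <- list(
    turnover = 0.122,
    turnover_se = 0.0071,
    premium_monthly_pre65 = 520,
    premium_monthly_65plus = 835,
    deductible_pre65 = 3731,
    deductible_65plus = 2158,
    copay_tier1_pre65 = 11,
    copay_tier2_pre65 = 31,
    copay_tier1_65plus = 5,
    copay_tier2_65plus = 11,
    medicare_age = 65L,
    deductible_mode = "exempt"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(ins))
    if (length(bad)) {
      stop("unknown insurance field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    ins[names(dots)] <- dots
  }
  class(ins) <- "pcsk9_insurance"
  validate_insurance(ins)
}

event_types <- function() c("mi", "stroke", "other")

stop_invalid <- function(key, msg) {
  stop(sprintf("invalid parameter '%s': %s", key, msg), call. = FALSE)
}

#' Validate a model parameter set
#'
#' Checks range and coherence invariants: probabilities and fractions in
#' \[0, 1\], costs non-negative, utilities in \[0, 1\] with every post-event
#' utility floor at or below the on-treatment utility, `start_age <
#' end_age`, and anchor pairs ordered low <= high. Errors name the offending
#' field.
#'
#' @param p A `pcsk9_params` object.
#' @return `p`, invisibly unchanged, if valid.
#' @export
validate_parameters <- function(p) {
  frac_fields <- c("discount_rate", "rrr_cvd", "ldl_reduction",
                   "post_cost_decay", "utility_on_treatment")
  for (f in frac_fields) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop_invalid(f, "must be a fraction in [0, 1]")
    }
  }
  cost_fields <- c("statin_annual_cost", "pcsk9_annual_cost", "pcsk9_price",
                   "baseline_care_annual_cost")
  for (f in cost_fields) {
    if (!is.numeric(p[[f]]) || any(p[[f]] < 0)) {
      stop_invalid(f, "costs must be non-negative")
    }
  }
  if (any(p$event_costs < 0) || any(p$post_event_first_year_costs < 0)) {
    stop_invalid("event_costs", "costs must be non-negative")
  }
  u <- p$post_event_utility_floor
  if (any(u < 0) || any(u > 1)) {
    stop_invalid("post_event_utility_floor", "utilities must lie in [0, 1]")
  }
  if (any(u > p$utility_on_treatment)) {
    stop_invalid("post_event_utility_floor",
                 "must not exceed utility_on_treatment")
  }
  if (p$start_age >= p$end_age) {
    stop_invalid("start_age", "start_age must be below end_age")
  }
  if (!p$scenario %in% c("trial_rrr", "framingham_ldl")) {
    stop_invalid("scenario", "must be 'trial_rrr' or 'framingham_ldl'")
  }
  if (!p$first_event_source %in% c("framingham_survival", "anchors")) {
    stop_invalid("first_event_source",
                 "must be 'framingham_survival' or 'anchors'")
  }
  if (!p$profile_shape %in% c("exponential", "linear")) {
    stop_invalid("profile_shape", "must be 'exponential' or 'linear'")
  }
  anchor_sets <- c(p$first_event_anchors$sabatine,
                   p$first_event_anchors$framingham,
                   p$subsequent_event_anchors, p$acute_mortality_anchors,
                   p$post_mortality_anchors,
                   list(non_cvd = p$non_cvd_mortality_anchors))
  for (nm in names(anchor_sets)) {
    a <- anchor_sets[[nm]]
    if (length(a) != 2 || any(a < 0) || any(a > 1) || a[1] > a[2]) {
      stop_invalid(nm, "anchors must be probabilities with low <= high")
    }
  }
  rp <- p$risk_profile
  for (f in c("male_fraction", "treated_htn_fraction", "smoker_fraction",
              "diabetes_fraction")) {
    if (rp[[f]] < 0 || rp[[f]] > 1) {
      stop_invalid(f, "must be a fraction in [0, 1]")
    }
  }
  for (f in c("sbp_treated", "sbp_untreated", "hdl", "ldl", "total_chol")) {
    if (rp[[f]] <= 0) stop_invalid(f, "must be positive")
  }
  invisible(p)
}

validate_insurance <- function(ins) {
  if (ins$turnover < 0 || ins$turnover > 1) {
    stop_invalid("turnover", "must be a fraction in [0, 1]")
  }
  money <- c("premium_monthly_pre65", "premium_monthly_65plus",
             "deductible_pre65", "deductible_65plus", "copay_tier1_pre65",
             "copay_tier2_pre65", "copay_tier1_65plus", "copay_tier2_65plus")
  for (f in money) {
    if (!is.numeric(ins[[f]]) || ins[[f]] < 0) {
      stop_invalid(f, "must be a non-negative amount")
    }
  }
  if (!ins$deductible_mode %in% c("exempt", "combined")) {
    stop_invalid("deductible_mode", "must be 'exempt' or 'combined'")
  }
  invisible(ins)
}

#' @export
print.pcsk9_params <- function(x, ...) {
  cat("<pcsk9_params>\n")
  cat(sprintf("  horizon: ages %d-%d, discount %.1f%%/yr\n",
              x$start_age, x$end_age, 100 * x$discount_rate))
  cat(sprintf("  scenario: %s (first events: %s)\n",
              x$scenario, x$first_event_source))
  cat(sprintf("  PCSK9 price: $%s/yr (PSA cost base $%s)\n",
              format(x$pcsk9_price, big.mark = ","),
              format(x$pcsk9_annual_cost, big.mark = ",")))
  cat(sprintf("  RRR: %.1f%%, LDL reduction: %.0f%%\n",
              100 * x$rrr_cvd, 100 * x$ldl_reduction))
  invisible(x)
}

#' @export
print.pcsk9_insurance <- function(x, ...) {
  cat("<pcsk9_insurance>\n")
  cat(sprintf("  turnover: %.1f%%/yr (se %.2f%%)\n",
              100 * x$turnover, 100 * x$turnover_se))
  cat(sprintf("  premium: $%d/mo (<65), $%d/mo (65+)\n",
              x$premium_monthly_pre65, x$premium_monthly_65plus))
  cat(sprintf("  deductible: $%d / $%d, mode '%s'\n",
              x$deductible_pre65, x$deductible_65plus, x$deductible_mode))
  invisible(x)
}

#' Age-anchored probability profile
#'
#' Builds a per-age probability (or cost) profile over the model horizon
#' from its two printed anchors: the value at the start age and the value at
#' the end age. The `"exponential"` shape interpolates geometrically
#' (Gompertz-like, the default for event and mortality probabilities, which
#' grow roughly exponentially with age); `"linear"` interpolates
#' arithmetically. Both shapes hit the anchors exactly and are monotone
#' non-decreasing when `anchor_low <= anchor_high`.
#'
#' @param anchor_low value at `min(ages)`.
#' @param anchor_high value at `max(ages)`.
#' @param shape `"exponential"` or `"linear"`.
#' @param ages integer vector of ages (default 58 to 100).
#' @return A tibble with columns `age` and `value`, carrying the anchors as
#'   attributes.
#' @examples
#' pr <- build_age_profile(0.003, 0.0168, "exponential")
#' pr$value[1]            # 0.003 at age 58
#' pr$value[nrow(pr)]     # 0.0168 at age 100
#' @export
build_age_profile <- function(anchor_low, anchor_high,
                              shape = c("exponential", "linear"),
                              ages = 58:100) {
  shape <- match.arg(shape)
  if (anchor_low > anchor_high) {
    stop("invalid-anchor: anchor_low must not exceed anchor_high",
         call. = FALSE)
  }
  out <- tibble::tibble(age = as.integer(ages),
                        value = profile_values(anchor_low, anchor_high,
                                               shape, ages))
  attr(out, "anchor_low") <- anchor_low
  attr(out, "anchor_high") <- anchor_high
  attr(out, "shape") <- shape
  out
}

# plain numeric profile over `ages`; the engine's workhorse
profile_values <- function(anchor_low, anchor_high, shape, ages) {
  span <- max(ages) - min(ages)
  s <- if (span == 0) rep(0, length(ages)) else (ages - min(ages)) / span
  if (shape == "linear" || anchor_low == anchor_high) {
    return(anchor_low + (anchor_high - anchor_low) * s)
  }
  if (anchor_low <= 0) {
    # geometric interpolation is undefined from a zero anchor
    return(anchor_low + (anchor_high - anchor_low) * s)
  }
  anchor_low * (anchor_high / anchor_low)^s
}

model_ages <- function(p) seq.int(p$start_age, p$end_age)

#' Resolved age profiles as a tidy table
#'
#' Expands every age-anchored probability profile of a parameter set into a
#' long table suitable for inspection or CSV export.
#'
#' @param params A `pcsk9_params` object.
#' @return A tibble with columns `age`, `quantity`, `event`, `value`.
#' @export
age_profiles <- function(params = model_parameters()) {
  ages <- model_ages(params)
  shape <- params$profile_shape
  pull <- function(anchors, quantity) {
    purrr::imap_dfr(anchors, function(a, ev) {
      tibble::tibble(age = as.integer(ages), quantity = quantity, event = ev,
                     value = profile_values(a[1], a[2], shape, ages))
    })
  }
  dplyr::bind_rows(
    pull(params$first_event_anchors$sabatine, "first_event_sabatine"),
    pull(params$first_event_anchors$framingham, "first_event_framingham"),
    pull(params$subsequent_event_anchors, "subsequent_event"),
    pull(params$acute_mortality_anchors, "acute_mortality"),
    pull(params$post_mortality_anchors, "post_mortality"),
    pull(list(non_cvd = params$non_cvd_mortality_anchors), "mortality")
  )
}

#' Parameter uncertainty distributions
#'
#' The registry of sampled quantities for the probabilistic sensitivity
#' analysis: costs and post-event utility floors follow beta distributions
#' rescaled to their printed \[low, high\] ranges with mean equal to the
#' point estimate; the insurance turnover rate is normal with its published
#' standard error; risk-equation coefficients are perturbed normally (see
#' [run_psa()]).
#'
#' Cost ranges follow the +/-25 percent convention around the point
#' estimates. The pre-65 premium and deductible are age-band descriptors
#' rather than uncertainty intervals and are held fixed. Where a printed
#' interval does not contain its point estimate (the stroke utility floor),
#' the beta mean is clamped to the nearest interior point of the interval.
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @return A tibble with columns `parameter`, `base`, `low`, `high`,
#'   `family`, `se`.
#' @export
parameter_distributions <- function(params = model_parameters(),
                                    insurance = insurance_parameters()) {
  pm25 <- function(base) c(0.75 * base, 1.25 * base)
  row <- function(parameter, base, low, high, family, se = NA_real_) {
    tibble::tibble(parameter = parameter, base = base, low = low, high = high,
                   family = family, se = se)
  }
  beta_row <- function(parameter, base, range) {
    row(parameter, base, range[1], range[2], "beta_scaled")
  }
  dplyr::bind_rows(
    beta_row("statin_annual_cost", params$statin_annual_cost,
             pm25(params$statin_annual_cost)),
    beta_row("pcsk9_annual_cost", params$pcsk9_annual_cost,
             pm25(params$pcsk9_annual_cost)),
    beta_row("baseline_care_annual_cost", params$baseline_care_annual_cost,
             pm25(params$baseline_care_annual_cost)),
    beta_row("event_cost_mi", params$event_costs[["mi"]],
             pm25(params$event_costs[["mi"]])),
    beta_row("event_cost_stroke", params$event_costs[["stroke"]],
             pm25(params$event_costs[["stroke"]])),
    beta_row("event_cost_other", params$event_costs[["other"]],
             pm25(params$event_costs[["other"]])),
    beta_row("post_cost_mi", params$post_event_first_year_costs[["mi"]],
             pm25(params$post_event_first_year_costs[["mi"]])),
    beta_row("post_cost_stroke", params$post_event_first_year_costs[["stroke"]],
             pm25(params$post_event_first_year_costs[["stroke"]])),
    beta_row("post_cost_other", params$post_event_first_year_costs[["other"]],
             pm25(params$post_event_first_year_costs[["other"]])),
    row("utility_floor_mi", params$post_event_utility_floor[["mi"]],
        0.54, 0.91, "beta_scaled"),
    row("utility_floor_stroke", params$post_event_utility_floor[["stroke"]],
        0.52, 0.87, "beta_scaled"),
    row("utility_floor_other", params$post_event_utility_floor[["other"]],
        0.57, 0.96, "beta_scaled"),
    row("turnover", insurance$turnover, 0, 1, "normal", insurance$turnover_se),
    row("premium_monthly_65plus", insurance$premium_monthly_65plus,
        751.6, 1043.9, "beta_scaled"),
    row("deductible_65plus", insurance$deductible_65plus,
        1942.2, 2697.5, "beta_scaled"),
    row("copay_tier1_pre65", insurance$copay_tier1_pre65,
        9.9, 13.75, "beta_scaled"),
    row("copay_tier2_pre65", insurance$copay_tier2_pre65,
        27.9, 38.75, "beta_scaled"),
    row("copay_tier1_65plus", insurance$copay_tier1_65plus,
        4.5, 6.25, "beta_scaled"),
    row("copay_tier2_65plus", insurance$copay_tier2_65plus,
        9.9, 13.75, "beta_scaled")
  )
}

config_fields <- function() {
  c("start_age", "end_age", "discount_rate", "rrr_cvd", "ldl_reduction",
    "scenario", "first_event_source", "profile_shape", "statin_annual_cost",
    "pcsk9_annual_cost", "pcsk9_price", "baseline_care_annual_cost",
    "event_costs", "post_event_first_year_costs", "post_cost_decay",
    "utility_on_treatment", "post_event_utility_floor",
    "utility_recovery_exponent", "utility_age_gradient", "risk_profile")
}

#' Write a run configuration to YAML
#'
#' Serialises the tunable scalar and per-event fields of a parameter set
#' (anchor tables are package constants and are not serialised). The file
#' round-trips through [read_config()].
#'
#' @param params A `pcsk9_params` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  keep <- config_fields()
  cfg <- lapply(params[keep], function(x) if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reads a flat YAML configuration written by [write_config()] (or by hand)
#' and merges it over the package defaults. Unknown keys raise a parse error
#' naming the key; invalid values fail validation with the offending field.
#'
#' @param path file path to read.
#' @return A validated `pcsk9_params` object.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("parse-error: cannot read config '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(cfg)) stop("parse-error: config is not a mapping", call. = FALSE)
  bad <- setdiff(names(cfg), config_fields())
  if (length(bad)) {
    stop("parse-error: unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vec_fields <- c("event_costs", "post_event_first_year_costs",
                  "post_event_utility_floor")
  for (f in intersect(vec_fields, names(cfg))) {
    cfg[[f]] <- unlist(cfg[[f]])[event_types()]
  }
  if ("risk_profile" %in% names(cfg)) {
    base_rp <- model_parameters()$risk_profile
    base_rp[names(cfg$risk_profile)] <- cfg$risk_profile
    cfg$risk_profile <- base_rp
  }
  do.call(model_parameters, cfg)
}
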