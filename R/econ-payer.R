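#' Enrollment weight under membership turnover
#'
#' Fraction of an initial membership cohort still enrolled with the payer
#' `years_from_start` years in, `(1 - turnover)^years_from_start`. It
#' multiplies every payer cash flow alongside survival and discounting:
#' premiums use the enrollment at cycle start (collected in advance), claims
#' use the enrollment carried through the cycle (one further turnover step);
#' see the methods vignette.
#'
#' @param years_from_start non-negative years since the start age.
#' @param turnover annual disenrollment fraction in \[0, 1\].
#' @return enrollment fraction.
#' @examples
#' enrollment_weight(0, 0.122)   # 1
#' enrollment_weight(1, 0.122)   # 0.878
#' @export
enrollment_weight <- function(years_from_start, turnover) {
  stopifnot(all(turnover >= 0 & turnover <= 1), all(years_from_start >= 0))
  (1 - turnover)^years_from_start
}

# age-band insurance quantities over the model ages
insurance_by_age <- function(ages, insurance) {
  pre <- ages < insurance$medicare_age
  list(
    copay1 = ifelse(pre, insurance$copay_tier1_pre65,
                    insurance$copay_tier1_65plus) * 12,
    copay2 = ifelse(pre, insurance$copay_tier2_pre65,
                    insurance$copay_tier2_65plus) * 12,
    deductible = ifelse(pre, insurance$deductible_pre65,
                        insurance$deductible_65plus),
    premium = ifelse(pre, insurance$premium_monthly_pre65,
                     insurance$premium_monthly_65plus) * 12
  )
}

#' Payer-borne cost of one member-year
#'
#' Splits a member-year's billed costs into the part the insurance payer
#' bears after patient cost sharing. Each drug's annual cost is offset by
#' twelve months of its formulary-tier copayment (statins tier 1, PCSK9
#' inhibitors tier 2), floored at zero. Under `deductible_mode = "combined"`
#' the age-band annual deductible is then credited against the member's
#' combined modelled spend (not below zero); under `"exempt"` (default) the
#' deductible is assumed exhausted by routine spending common to both arms
#' and does not reduce the modelled claims.
#'
#' @param components list with numeric elements `statin`, `pcsk9`,
#'   `medical` (annual amounts; missing elements count as zero).
#' @param age member age (selects the pre-65 or 65+ band).
#' @param insurance A `pcsk9_insurance` object.
#' @return payer-borne annual cost (scalar, >= 0).
#' @examples
#' # PCSK9 member aged 60: copay offset = 12 x 31 = 372
#' payer_borne_cost(list(pcsk9 = 14000), 60, insurance_parameters())
#' @export
payer_borne_cost <- function(components, age,
                             insurance = insurance_parameters()) {
  ib <- insurance_by_age(age, insurance)
  statin <- components$statin %||% 0
  pcsk9 <- components$pcsk9 %||% 0
  medical <- components$medical %||% 0
  drug <- pmax(0, statin - ib$copay1) + pmax(0, pcsk9 - ib$copay2)
  total <- drug + medical
  if (insurance$deductible_mode == "combined") {
    total <- pmax(0, total - ib$deductible)
  }
  total
}

# discounted, enrollment-weighted payer cash flows for one arm's trace:
# drug and care outlays net of copays, medical claims, premium income
payer_cash_flows <- function(trace, params, insurance,
                             price = params$pcsk9_price, tables = NULL) {
  occ <- as.matrix(trace[, state_names()])
  tab <- tables %||%
    hazard_tables(params, attr(trace, "scenario") %||% params$scenario)
  payer_flows_core(occ, tab, params, insurance, price,
                   pcsk9_arm = attr(trace, "arm") == "statin_pcsk9")
}

# numeric core over an occupancy matrix
payer_flows_core <- function(occ, tab, params, insurance, price, pcsk9_arm) {
  n <- nrow(occ)
  ages <- tab$ages
  cycles <- seq_len(n) - 1
  ib <- insurance_by_age(ages, insurance)
  disc <- (1 + params$discount_rate)^-cycles
  w_claim <- disc * enrollment_weight(cycles + 1, insurance$turnover)
  w_premium <- disc * enrollment_weight(cycles, insurance$turnover)

  non_acute <- rowSums(occ[, .S$non_acute, drop = FALSE])
  statin_net <- pmax(0, params$statin_annual_cost - ib$copay1)
  pcsk9_net <- if (pcsk9_arm) pmax(0, price - ib$copay2) else 0
  treatment <- (statin_net + pcsk9_net + params$baseline_care_annual_cost) *
    non_acute

  fatal <- cohort_flows(occ, tab,
                        arm_multiplier(tab, if (pcsk9_arm) "statin_pcsk9"
                                       else "statin_only"))$fatal
  evc <- params$event_costs[event_types()]
  pc1 <- params$post_event_first_year_costs[event_types()]
  decay <- (1 - params$post_cost_decay)^(0:4)
  bind_ded <- insurance$deductible_mode == "combined"
  ded <- if (bind_ded) ib$deductible else 0
  medical <- numeric(n)
  for (k in 1:3) {
    medical <- medical + pmax(0, evc[k] - ded) * (occ[, .S$acute[k]] + fatal[, k])
    for (y in 1:5) {
      medical <- medical +
        pmax(0, pc1[k] * decay[y] - ded) * occ[, .S$post_first[k] + y - 1]
    }
  }
  premiums <- ib$premium * rowSums(occ[, .S$alive, drop = FALSE])
  list(treatment = sum(treatment * w_claim),
       medical = sum(medical * w_claim),
       premium = sum(premiums * w_premium))
}

#' Discounted premium revenue of one arm
#'
#' Twelve monthly premiums per alive, enrolled member-year (the commercial
#' premium before `medicare_age`, the Medicare Advantage premium
#' afterwards), discounted and weighted by start-of-cycle enrollment.
#'
#' @param trace a trace from [run_cohort()].
#' @param insurance A `pcsk9_insurance` object.
#' @param params A `pcsk9_params` object (supplies the discount rate).
#' @return total discounted premium revenue (scalar).
#' @export
premium_revenue <- function(trace, insurance = insurance_parameters(),
                            params = model_parameters()) {
  payer_cash_flows(trace, params, insurance)$premium
}

#' Incremental payer result for an arm pair
#'
#' Incremental (PCSK9 arm minus statin arm) discounted payer cash flows:
#' treatment outlays net of copays, avoided medical claims, premium revenue
#' from differential survival, the net present value
#' `NPV = avoided + premium - treatment`, and `ROI = NPV / treatment`.
#'
#' @param trace_a,trace_b traces for the PCSK9 and statin arms.
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param price annual PCSK9 price.
#' @return An object of class `pcsk9_payer`.
#' @export
compute_payer_result <- function(trace_a, trace_b,
                                 params = model_parameters(),
                                 insurance = insurance_parameters(),
                                 price = params$pcsk9_price) {
  stopifnot(price >= 0)
  a <- payer_cash_flows(trace_a, params, insurance, price)
  b <- payer_cash_flows(trace_b, params, insurance, price)
  treatment <- a$treatment - b$treatment
  avoided <- b$medical - a$medical
  premium <- a$premium - b$premium
  npv <- avoided + premium - treatment
  out <- list(price = price, treatment_cost = treatment,
              avoided_cost = avoided, premium_revenue = premium, npv = npv,
              roi = if (treatment > 0) npv / treatment else NA_real_)
  class(out) <- "pcsk9_payer"
  out
}

#' Payer analysis at a price
#'
#' Convenience wrapper running both arms and calling
#' [compute_payer_result()].
#'
#' @inheritParams compute_payer_result
#' @param scenario model scenario.
#' @param traces optional precomputed trace pair (see [cea()]).
#' @return An object of class `pcsk9_payer`.
#' @examples
#' payer_result(price = 14000)
#' @export
payer_result <- function(params = model_parameters(),
                         insurance = insurance_parameters(),
                         price = params$pcsk9_price, scenario = NULL,
                         traces = NULL) {
  traces <- traces %||% cohort_pair(params, scenario)
  compute_payer_result(traces$statin_pcsk9, traces$statin_only, params,
                       insurance, price)
}

#' @export
print.pcsk9_payer <- function(x, ...) {
  cat(sprintf("<pcsk9_payer> price=$%s\n", format(x$price, big.mark = ",")))
  cat(sprintf("  treatment cost: $%s  avoided: $%s  premium: $%s\n",
              format(round(x$treatment_cost), big.mark = ","),
              format(round(x$avoided_cost), big.mark = ","),
              format(round(x$premium_revenue), big.mark = ",")))
  cat(sprintf("  NPV: $%s  ROI: %.1f%%\n",
              format(round(x$npv), big.mark = ","), 100 * x$roi))
  invisible(x)
}

#' @export
tidy.pcsk9_payer <- function(x, ...) {
  tibble::tibble(
    quantity = c("treatment_cost", "avoided_cost", "premium_revenue", "npv",
                 "roi"),
    value = c(x$treatment_cost, x$avoided_cost, x$premium_revenue, x$npv,
              x$roi)
  )
}

#' @export
glance.pcsk9_payer <- function(x, ...) {
  tibble::tibble(price = x$price, treatment_cost = x$treatment_cost,
                 avoided_cost = x$avoided_cost,
                 premium_revenue = x$premium_revenue, npv = x$npv,
                 roi = x$roi)
}

#' Payer breakeven price
#'
#' The annual PCSK9 price at which the payer's incremental NPV is zero,
#' found by root search. NPV is continuous, affine and strictly decreasing
#' in price above the copay floor, so the root is unique.
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param interval search bracket.
#' @param scenario model scenario.
#' @return breakeven annual price (scalar).
#' @export
payer_breakeven_price <- function(params = model_parameters(),
                                  insurance = insurance_parameters(),
                                  interval = c(0, 3e4), scenario = NULL) {
  traces <- cohort_pair(params, scenario)
  f <- function(p) payer_result(params, insurance, price = p,
                                traces = traces)$npv
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0) {
    stop("no-breakeven: NPV does not change sign on the bracket",
         call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-6)$root
}
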