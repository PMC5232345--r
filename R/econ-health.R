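#' Present value of a future amount
#'
#' @param value amount accruing `years_from_start` years after the start.
#' @param years_from_start non-negative number of years.
#' @param rate annual discount rate (>= 0).
#' @return `value / (1 + rate)^years_from_start`.
#' @examples
#' discount(103, 1, 0.03)   # 100
#' @export
discount <- function(value, years_from_start, rate = 0.03) {
  stopifnot(rate >= 0)
  value / (1 + rate)^years_from_start
}

# shared per-cycle component table for a trace: undiscounted treatment and
# medical cost and QALYs, with the discount factor
cost_components <- function(trace, params, price) {
  arm <- attr(trace, "arm")
  occ <- as.matrix(trace[, state_names()])
  tab <- hazard_tables(params, attr(trace, "scenario") %||% params$scenario)
  fatal <- cohort_flows(occ, tab, arm_multiplier(tab, arm))$fatal
  cc <- state_cost_cycle(occ, fatal, params, arm, price)
  tibble::tibble(
    cycle = trace$cycle,
    discount_factor = (1 + params$discount_rate)^-(trace$cycle),
    treatment = cc$treatment,
    medical = cc$medical,
    qaly = state_qaly_cycle(occ, params)
  )
}

#' Discounted lifetime cost of a trace
#'
#' Accrues the health-system cost of one arm: annual therapy cost (statin
#' plus baseline care, plus the PCSK9 price for the combination arm) over
#' alive non-acute occupancy, acute event costs over acute occupancy and
#' fatal recurrences, and post-event costs decaying by `post_cost_decay`
#' per post year. Costs accrue at cycle start and are discounted at the
#' parameter set's rate.
#'
#' @param trace a trace from [run_cohort()].
#' @param params A `pcsk9_params` object.
#' @param price annual PCSK9 price (ignored for the statin-only arm).
#' @return total discounted lifetime cost (scalar).
#' @export
accrue_costs <- function(trace, params = model_parameters(),
                         price = params$pcsk9_price) {
  stopifnot(price >= 0)
  cc <- cost_components(trace, params, price)
  sum((cc$treatment + cc$medical) * cc$discount_factor)
}

#' Discounted lifetime QALYs of a trace
#'
#' Normal life on treatment accrues `utility_on_treatment` per year; the
#' acute event year accrues the event-type utility floor; post years follow
#' the concave five-point recovery path from the floor back to the
#' on-treatment utility; death accrues zero. All alive utilities decline
#' with age by `utility_age_gradient` per year.
#'
#' @inheritParams accrue_costs
#' @return total discounted QALYs (scalar).
#' @export
accrue_qalys <- function(trace, params = model_parameters()) {
  cc <- cost_components(trace, params, price = 0)
  sum(cc$qaly * cc$discount_factor)
}

#' Per-arm health-system economics
#'
#' Discounted lifetime treatment cost, medical (event) cost, QALYs and life
#' years for one arm's trace.
#'
#' @inheritParams accrue_costs
#' @return An object of class `pcsk9_arm_econ`: a one-row tibble with
#'   columns `arm`, `treatment_cost`, `medical_cost`, `qaly`, `life_years`,
#'   `events`.
#' @export
arm_economics <- function(trace, params = model_parameters(),
                          price = params$pcsk9_price) {
  cc <- cost_components(trace, params, price)
  ev <- trace$new_events_mi + trace$new_events_stroke + trace$new_events_other
  out <- tibble::tibble(
    arm = attr(trace, "arm"),
    treatment_cost = sum(cc$treatment * cc$discount_factor),
    medical_cost = sum(cc$medical * cc$discount_factor),
    qaly = sum(cc$qaly * cc$discount_factor),
    life_years = sum(trace$alive * cc$discount_factor),
    events = sum(ev)
  )
  class(out) <- c("pcsk9_arm_econ", class(out))
  out
}

#' Incremental cost-effectiveness ratio from two per-arm results
#'
#' `ICER = (delta treatment cost - delta avoided cost) / delta QALY`, where
#' the avoided cost is the reduction in medical costs under arm A.
#'
#' @param result_a,result_b per-arm results from [arm_economics()]; A is the
#'   intervention arm.
#' @return ICER in dollars per QALY (scalar).
#' @export
compute_icer <- function(result_a, result_b) {
  dq <- result_a$qaly - result_b$qaly
  if (abs(dq) < .Machine$double.eps^0.5) {
    stop("undefined-icer: QALY difference is zero", call. = FALSE)
  }
  dcost <- (result_a$treatment_cost - result_b$treatment_cost) +
    (result_a$medical_cost - result_b$medical_cost)
  dcost / dq
}

#' Cost-effectiveness analysis of PCSK9 therapy versus statin only
#'
#' Runs both arms of the cohort model and assembles incremental discounted
#' treatment cost, avoided medical cost, QALYs, life years, CVD events and
#' the ICER at a given annual PCSK9 price.
#'
#' @param params A `pcsk9_params` object.
#' @param price annual PCSK9 price (defaults to the scenario price).
#' @param scenario `"trial_rrr"` or `"framingham_ldl"`.
#' @param traces optional precomputed pair `list(statin_pcsk9 =, statin_only =)`
#'   of traces, to reuse occupancies across prices.
#' @return An object of class `pcsk9_cea`.
#' @examples
#' cea(model_parameters(), price = 14000)
#' @export
cea <- function(params = model_parameters(), price = params$pcsk9_price,
                scenario = NULL, traces = NULL) {
  scenario <- scenario %||% params$scenario
  traces <- traces %||% cohort_pair(params, scenario)
  a <- arm_economics(traces$statin_pcsk9, params, price)
  b <- arm_economics(traces$statin_only, params, price)
  inc <- incremental_outcomes(traces$statin_pcsk9, traces$statin_only,
                              params$discount_rate)
  out <- list(
    price = price,
    scenario = scenario,
    arm_a = a, arm_b = b,
    treatment_cost = a$treatment_cost - b$treatment_cost,
    avoided_cost = b$medical_cost - a$medical_cost,
    delta_qaly = inc$delta_qaly,
    delta_life_years = inc$delta_life_years,
    delta_events = inc$delta_events,
    icer = compute_icer(a, b)
  )
  class(out) <- "pcsk9_cea"
  out
}

# both arms' traces for a scenario
cohort_pair <- function(params, scenario = NULL) {
  scenario <- scenario %||% params$scenario
  list(statin_pcsk9 = run_cohort(params, "statin_pcsk9", scenario),
       statin_only = run_cohort(params, "statin_only", scenario))
}

#' @export
print.pcsk9_cea <- function(x, ...) {
  cat(sprintf("<pcsk9_cea> scenario=%s price=$%s\n", x$scenario,
              format(x$price, big.mark = ",")))
  cat(sprintf("  incremental treatment cost: $%s\n",
              format(round(x$treatment_cost), big.mark = ",")))
  cat(sprintf("  avoided medical cost:       $%s\n",
              format(round(x$avoided_cost), big.mark = ",")))
  cat(sprintf("  delta QALY: %.3f  delta LY: %.3f  delta events: %.3f\n",
              x$delta_qaly, x$delta_life_years, x$delta_events))
  cat(sprintf("  ICER: $%s per QALY\n", format(round(x$icer), big.mark = ",")))
  invisible(x)
}

#' @export
tidy.pcsk9_cea <- function(x, ...) {
  tibble::tibble(
    quantity = c("treatment_cost", "avoided_cost", "delta_qaly",
                 "delta_life_years", "delta_events", "icer"),
    value = c(x$treatment_cost, x$avoided_cost, x$delta_qaly,
              x$delta_life_years, x$delta_events, x$icer)
  )
}

#' @export
glance.pcsk9_cea <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, price = x$price,
                 treatment_cost = x$treatment_cost,
                 avoided_cost = x$avoided_cost, delta_qaly = x$delta_qaly,
                 delta_life_years = x$delta_life_years,
                 delta_events = x$delta_events, icer = x$icer)
}

#' Breakeven PCSK9 price at a willingness-to-pay threshold
#'
#' Finds the annual price at which the health-system ICER equals the
#' willingness-to-pay threshold by root search. Because treatment cost is
#' affine in price and QALYs are price-independent, the ICER is affine and
#' strictly increasing in price, so the root is unique.
#'
#' @param params A `pcsk9_params` object.
#' @param wtp willingness-to-pay threshold in dollars per QALY (> 0).
#' @param interval search bracket for the price.
#' @param scenario model scenario.
#' @return breakeven annual price (scalar).
#' @export
wtp_breakeven_price <- function(params = model_parameters(), wtp = 1e5,
                                interval = c(0, 1e5), scenario = NULL) {
  stopifnot(wtp > 0)
  traces <- cohort_pair(params, scenario)
  f <- function(p) cea(params, price = p, scenario = scenario,
                       traces = traces)$icer - wtp
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0) {
    stop("no-breakeven: ICER does not cross the threshold on the bracket",
         call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-6)$root
}
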