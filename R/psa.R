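#' Draw from a beta distribution rescaled to an interval
#'
#' Samples `X ~ Beta(a, b)` rescaled to `[low, high]` with mean equal to
#' `base` (concentration `a + b = 8`, so a symmetric range yields
#' `Beta(4, 4)`). A zero-width interval returns `base`; a mean outside the
#' open interval is clamped to a 5 percent inset before shaping (needed
#' where a printed interval does not contain its point estimate).
#'
#' @param base target mean.
#' @param low,high interval endpoints, `low <= high`.
#' @param n number of draws.
#' @param concentration `a + b` of the underlying beta.
#' @return numeric vector of `n` draws within `[low, high]`.
#' @export
rbeta_scaled <- function(base, low, high, n = 1, concentration = 8) {
  if (low > high) {
    stop("distribution-error: low must not exceed high", call. = FALSE)
  }
  if (high == low) return(rep(base, n))
  m <- (base - low) / (high - low)
  m <- min(max(m, 0.05), 0.95)
  low + (high - low) * stats::rbeta(n, concentration * m,
                                    concentration * (1 - m))
}

#' Sample one parameter set for the probabilistic sensitivity analysis
#'
#' Draws all uncertain quantities once, using the current RNG state: costs
#' and post-event utility floors from beta distributions over their printed
#' ranges (means at the point estimates), the turnover rate from a normal
#' with its published standard error (truncated to \[0, 1\]), 65+ insurance
#' parameters and tier copayments from their printed intervals, and the
#' risk-equation coefficients from normals with the packaged standard
#' deviations. The perturbed coefficients enter as a per-age hazard scale on
#' first and subsequent event probabilities (ratio of perturbed to base
#' annualized cohort risk).
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param distributions the distribution registry, by default
#'   [parameter_distributions()] of the inputs (precompute it when drawing
#'   in a loop).
#' @return A list with elements `params`, `insurance` (perturbed copies) and
#'   `hazard_scale` (numeric vector over the model ages).
#' @export
sample_parameter_set <- function(params = model_parameters(),
                                 insurance = insurance_parameters(),
                                 distributions =
                                   parameter_distributions(params, insurance)) {
  base_v <- distributions$base
  low_v <- distributions$low
  high_v <- distributions$high
  fam_v <- distributions$family
  se_v <- distributions$se
  idx <- stats::setNames(seq_len(nrow(distributions)),
                         distributions$parameter)
  draw1 <- function(name) {
    i <- idx[[name]]
    if (fam_v[i] == "beta_scaled") rbeta_scaled(base_v[i], low_v[i], high_v[i])
    else min(max(stats::rnorm(1, base_v[i], se_v[i]), 0), 1)
  }
  p <- params
  p$statin_annual_cost <- draw1("statin_annual_cost")
  p$pcsk9_annual_cost <- draw1("pcsk9_annual_cost")
  p$baseline_care_annual_cost <- draw1("baseline_care_annual_cost")
  p$event_costs <- c(mi = draw1("event_cost_mi"),
                     stroke = draw1("event_cost_stroke"),
                     other = draw1("event_cost_other"))
  p$post_event_first_year_costs <- c(mi = draw1("post_cost_mi"),
                                     stroke = draw1("post_cost_stroke"),
                                     other = draw1("post_cost_other"))
  floors <- c(mi = draw1("utility_floor_mi"),
              stroke = draw1("utility_floor_stroke"),
              other = draw1("utility_floor_other"))
  p$post_event_utility_floor <- pmin(floors, p$utility_on_treatment)
  ins <- insurance
  ins$turnover <- draw1("turnover")
  ins$premium_monthly_65plus <- draw1("premium_monthly_65plus")
  ins$deductible_65plus <- draw1("deductible_65plus")
  ins$copay_tier1_pre65 <- draw1("copay_tier1_pre65")
  ins$copay_tier2_pre65 <- draw1("copay_tier2_pre65")
  ins$copay_tier1_65plus <- draw1("copay_tier1_65plus")
  ins$copay_tier2_65plus <- draw1("copay_tier2_65plus")
  eq <- framingham_gcvd()
  beta_men <- stats::rnorm(length(eq$men$coefficients),
                           eq$men$coefficients, eq$men$coef_se)
  names(beta_men) <- names(eq$men$coefficients)
  beta_women <- stats::rnorm(length(eq$women$coefficients),
                             eq$women$coefficients, eq$women$coef_se)
  names(beta_women) <- names(eq$women$coefficients)
  base_p <- annualize_risk(pmin(cohort_risk10_by_age(params, eq), 1 - 1e-9))
  draw_p <- annualize_risk(pmin(
    cohort_risk10_by_age(params, eq, beta_men = beta_men,
                         beta_women = beta_women), 1 - 1e-9))
  list(params = p, insurance = ins, hazard_scale = draw_p / base_p)
}

#' Probabilistic sensitivity analysis at one price
#'
#' Runs `n_draws` Monte Carlo simulations of the full model. Each draw
#' perturbs every uncertain quantity once (see [sample_parameter_set()]),
#' runs both arms with common random parameters, and records the resulting
#' ICER and payer NPV/ROI at the given annual PCSK9 price. The price itself
#' is a scenario value and is not drawn.
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param price annual PCSK9 price.
#' @param n_draws number of Monte Carlo draws (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param scenario model scenario.
#' @return A tibble of class `pcsk9_psa` with columns `draw`, `icer`,
#'   `delta_qaly`, `npv`, `roi`, `hazard_scale_58` (the draw's hazard scale
#'   at the start age); `price` and `n_draws` are attached as attributes.
#' @export
run_psa <- function(params = model_parameters(),
                    insurance = insurance_parameters(),
                    price = params$pcsk9_price, n_draws = 1000, seed = NULL,
                    scenario = NULL) {
  stopifnot(n_draws >= 1)
  scenario <- scenario %||% params$scenario
  if (!is.null(seed)) set.seed(seed)
  dist <- parameter_distributions(params, insurance)
  res <- matrix(NA_real_, n_draws, 5)
  for (i in seq_len(n_draws)) {
    s <- sample_parameter_set(params, insurance, distributions = dist)
    tab <- hazard_tables(s$params, scenario, hazard_scale = s$hazard_scale)
    occ_a <- cohort_occupancy(s$params, "statin_pcsk9", scenario, tab)
    occ_b <- cohort_occupancy(s$params, "statin_only", scenario, tab)
    fat_a <- cohort_flows(occ_a, tab, arm_multiplier(tab, "statin_pcsk9"))$fatal
    fat_b <- cohort_flows(occ_b, tab, arm_multiplier(tab, "statin_only"))$fatal
    d <- (1 + s$params$discount_rate)^-(seq_len(nrow(occ_a)) - 1)
    cost_a <- state_cost_cycle(occ_a, fat_a, s$params, "statin_pcsk9", price)
    cost_b <- state_cost_cycle(occ_b, fat_b, s$params, "statin_only", price)
    dq <- sum((state_qaly_cycle(occ_a, s$params) -
                 state_qaly_cycle(occ_b, s$params)) * d)
    dc <- sum((cost_a$total - cost_b$total) * d)
    pf_a <- payer_flows_core(occ_a, tab, s$params, s$insurance, price, TRUE)
    pf_b <- payer_flows_core(occ_b, tab, s$params, s$insurance, price, FALSE)
    treat <- pf_a$treatment - pf_b$treatment
    npv <- (pf_b$medical - pf_a$medical) + (pf_a$premium - pf_b$premium) -
      treat
    res[i, ] <- c(dc / dq, dq, npv, npv / treat, s$hazard_scale[1])
  }
  out <- tibble::tibble(draw = seq_len(n_draws), icer = res[, 1],
                        delta_qaly = res[, 2], npv = res[, 3],
                        roi = res[, 4], hazard_scale_58 = res[, 5])
  attr(out, "price") <- price
  attr(out, "n_draws") <- n_draws
  class(out) <- c("pcsk9_psa", class(out))
  out
}

#' Acceptability of the therapy from a set of PSA draws
#'
#' From the health-system perspective, the probability that the therapy is
#' cost-effective is the fraction of draws with ICER at or below the
#' willingness-to-pay threshold; from the payer perspective it is the
#' fraction of draws with a positive ROI (the threshold is ignored).
#' Binomial standard errors accompany each probability.
#'
#' @param draws a `pcsk9_psa` tibble from [run_psa()].
#' @param threshold willingness-to-pay threshold(s) in dollars per QALY.
#' @param perspective `"health_system"` or `"payer"`.
#' @return A tibble with columns `price`, `perspective`, `threshold`,
#'   `probability`, `se`, `n_draws`.
#' @export
acceptability <- function(draws, threshold = c(2e4, 5e4, 1e5),
                          perspective = c("health_system", "payer")) {
  perspective <- match.arg(perspective)
  n <- nrow(draws)
  if (perspective == "payer") {
    p <- mean(draws$roi > 0)
    return(tibble::tibble(price = attr(draws, "price"),
                          perspective = perspective, threshold = NA_real_,
                          probability = p, se = sqrt(p * (1 - p) / n),
                          n_draws = n))
  }
  purrr::map_dfr(threshold, function(th) {
    p <- mean(draws$icer <= th)
    tibble::tibble(price = attr(draws, "price"), perspective = perspective,
                   threshold = th, probability = p,
                   se = sqrt(p * (1 - p) / n), n_draws = n)
  })
}

#' Acceptability surface over a price grid
#'
#' Runs the PSA at each price on a grid and evaluates acceptability at each
#' willingness-to-pay threshold (health system) and for a positive ROI
#' (payer). Each price reuses the same derived seed sequence, so the surface
#' is reproducible given `seed`.
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param price_grid annual prices to evaluate.
#' @param thresholds willingness-to-pay thresholds.
#' @param n_draws Monte Carlo draws per price.
#' @param seed integer seed.
#' @param scenario model scenario.
#' @return A tibble of class `pcsk9_acceptability` with one row per price x
#'   threshold (plus a payer row per price).
#' @export
acceptability_surface <- function(params = model_parameters(),
                                  insurance = insurance_parameters(),
                                  price_grid = c(500, 1000, 2500, 5000, 7500,
                                                 10000, 12500, 14000, 15000),
                                  thresholds = c(2e4, 5e4, 1e5),
                                  n_draws = 1000, seed = 1,
                                  scenario = NULL) {
  out <- purrr::map_dfr(seq_along(price_grid), function(j) {
    draws <- run_psa(params, insurance, price = price_grid[j],
                     n_draws = n_draws, seed = seed + j - 1,
                     scenario = scenario)
    dplyr::bind_rows(acceptability(draws, thresholds, "health_system"),
                     acceptability(draws, perspective = "payer"))
  })
  class(out) <- c("pcsk9_acceptability", class(out))
  out
}

#' @export
autoplot.pcsk9_psa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$icer)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "ICER ($/QALY)", y = "Draws") +
    ggplot2::theme_minimal()
}

#' Acceptability-curve plot
#'
#' @param object a `pcsk9_acceptability` surface from
#'   [acceptability_surface()].
#' @param ... unused.
#' @return A ggplot of acceptability against price, one curve per threshold
#'   and one for the payer perspective.
#' @export
autoplot.pcsk9_acceptability <- function(object, ...) {
  df <- dplyr::mutate(object, curve = ifelse(
    .data$perspective == "payer", "Payer (ROI > 0)",
    paste0("WTP $", format(.data$threshold, big.mark = ",", trim = TRUE))))
  ggplot2::ggplot(df, ggplot2::aes(.data$price, .data$probability,
                                   colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Annual PCSK9 price ($)",
                  y = "Probability of acceptability", colour = NULL) +
    ggplot2::theme_minimal()
}
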