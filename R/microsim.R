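#' Simulate individual patient trajectories
#'
#' Individual-level Bernoulli microsimulation through the identical state
#' process as the cohort engine: each cycle every patient samples their next
#' state from the same transition-matrix row [run_cohort()] uses, and
#' accrues the same per-state costs and utilities. The population mean
#' converges to the cohort expectation as `n` grows, which is the package's
#' central validation property.
#'
#' Fatal recurrences (post-CVD to CVD-death transitions) incur the
#' event-type acute cost and count as events, mirroring the cohort engine.
#'
#' @param params A `pcsk9_params` object.
#' @param arm `"statin_only"` or `"statin_pcsk9"`.
#' @param scenario model scenario.
#' @param n number of patients (>= 1).
#' @param seed integer seed; the whole population is reproducible given the
#'   seed.
#' @param price annual PCSK9 price.
#' @param keep_patients if `TRUE`, also return the per-patient table.
#' @return A list of class `pcsk9_microsim` with elements `summary` (a
#'   one-row tibble: means and standard errors of discounted cost, QALYs,
#'   life years and event counts) and, if requested, `patients`.
#' @export
simulate_population <- function(params = model_parameters(),
                                arm = c("statin_only", "statin_pcsk9"),
                                scenario = NULL, n = 1000, seed = NULL,
                                price = params$pcsk9_price,
                                keep_patients = FALSE) {
  arm <- match.arg(arm)
  scenario <- scenario %||% params$scenario
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tab <- hazard_tables(params, scenario)
  mats <- transition_array(params, arm, scenario, tables = tab)
  n_cycles <- length(tab$ages)
  cum_rows <- lapply(mats, function(M) t(apply(M, 1, cumsum)))

  therapy_annual <- params$statin_annual_cost +
    params$baseline_care_annual_cost +
    if (arm == "statin_pcsk9") price else 0
  evc <- params$event_costs[event_types()]
  pc1 <- params$post_event_first_year_costs[event_types()]
  decay <- (1 - params$post_cost_decay)^(0:4)
  state_cost <- c(therapy_annual, evc,
                  therapy_annual + pc1[1] * decay,
                  therapy_annual + pc1[2] * decay,
                  therapy_annual + pc1[3] * decay, 0, 0)
  u0 <- state_utilities(params)

  state <- rep(1L, n)
  cost <- numeric(n); qaly <- numeric(n); ly <- numeric(n)
  events <- numeric(n)
  states_hist <- if (keep_patients && n == 1) integer(n_cycles) else NULL
  post_states <- .S$post
  for (t in seq_len(n_cycles)) {
    d <- (1 + params$discount_rate)^-(t - 1)
    agedec <- params$utility_age_gradient * (t - 1)
    alive <- state <= 19L
    cost <- cost + state_cost[state] * d
    qaly <- qaly + pmax(u0[state] - ifelse(alive, agedec, 0), 0) * d
    ly <- ly + as.numeric(alive)
    if (!is.null(states_hist)) states_hist[t] <- state[1]
    # entries into acute states this cycle are events; the final cycle's
    # transition is sampled for event accounting only, matching the cohort
    # engine's per-cycle flows
    cr <- cum_rows[[t]]
    u <- stats::runif(n)
    new_state <- state
    for (s in sort(unique(state[alive]))) {
      idx <- which(state == s)
      new_state[idx] <- findInterval(u[idx], cr[s, ], left.open = TRUE) + 1L
    }
    had_event <- new_state %in% .S$acute
    fatal_rec <- state %in% post_states & new_state == .S$dead_cvd
    events <- events + had_event + fatal_rec
    # fatal recurrences incur the acute cost of the post state's own type
    if (any(fatal_rec)) {
      type_idx <- findInterval(state[fatal_rec], c(5L, 10L, 15L))
      cost[fatal_rec] <- cost[fatal_rec] + evc[type_idx] * d
    }
    state <- new_state
  }
  summary <- tibble::tibble(
    arm = arm, n = n,
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
    mean_life_years = mean(ly), se_life_years = stats::sd(ly) / sqrt(n),
    mean_events = mean(events), se_events = stats::sd(events) / sqrt(n)
  )
  out <- list(summary = summary)
  if (keep_patients) {
    out$patients <- tibble::tibble(patient = seq_len(n),
                                   discounted_cost = cost,
                                   discounted_qaly = qaly, life_years = ly,
                                   events = events)
    if (!is.null(states_hist)) {
      out$trajectory <- tibble::tibble(cycle = 0:(n_cycles - 1),
                                       age = as.integer(tab$ages),
                                       state = state_names()[states_hist])
    }
  }
  class(out) <- "pcsk9_microsim"
  out
}

#' Simulate one patient trajectory
#'
#' Runs [simulate_population()] with a single patient, returning the state
#' sequence and discounted totals.
#'
#' @inheritParams simulate_population
#' @return A list with `trajectory` (tibble: cycle, age, state), `summary`
#'   and `patients`.
#' @export
simulate_individual <- function(params = model_parameters(),
                                arm = c("statin_only", "statin_pcsk9"),
                                scenario = NULL, seed = NULL,
                                price = params$pcsk9_price) {
  arm <- match.arg(arm)
  simulate_population(params, arm, scenario, n = 1, seed = seed,
                      price = price, keep_patients = TRUE)
}

#' @export
print.pcsk9_microsim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pcsk9_microsim> arm=%s n=%d\n", s$arm, s$n))
  cat(sprintf("  cost  %10.0f (se %.0f)\n", s$mean_cost, s$se_cost))
  cat(sprintf("  qaly  %10.3f (se %.4f)\n", s$mean_qaly, s$se_qaly))
  cat(sprintf("  LY    %10.3f (se %.4f)\n", s$mean_life_years,
              s$se_life_years))
  cat(sprintf("  events %9.3f (se %.4f)\n", s$mean_events, s$se_events))
  invisible(x)
}

#' Cohort-versus-microsimulation validation report
#'
#' Compares the cohort engine's expected discounted cost, QALYs, life years
#' and event counts with microsimulation means for both arms, reporting the
#' z-score of each difference in Monte Carlo standard errors.
#'
#' @param params A `pcsk9_params` object.
#' @param n patients per arm.
#' @param seed integer seed.
#' @param scenario model scenario.
#' @param price annual PCSK9 price.
#' @return A tibble with columns `arm`, `quantity`, `cohort`, `microsim`,
#'   `se`, `z`.
#' @export
validation_report <- function(params = model_parameters(), n = 20000,
                              seed = 1, scenario = NULL,
                              price = params$pcsk9_price) {
  scenario <- scenario %||% params$scenario
  purrr::map_dfr(c("statin_only", "statin_pcsk9"), function(arm) {
    tr <- run_cohort(params, arm, scenario, price = price)
    d <- (1 + params$discount_rate)^-(tr$cycle)
    cohort <- c(cost = sum(tr$cost_undisc * d),
                qaly = sum(tr$qaly_undisc * d),
                life_years = sum(tr$alive),
                events = sum(tr$new_events_mi + tr$new_events_stroke +
                               tr$new_events_other))
    ms <- simulate_population(params, arm, scenario, n = n, seed = seed,
                              price = price)$summary
    micro <- c(ms$mean_cost, ms$mean_qaly, ms$mean_life_years,
               ms$mean_events)
    se <- c(ms$se_cost, ms$se_qaly, ms$se_life_years, ms$se_events)
    tibble::tibble(arm = arm,
                   quantity = c("cost", "qaly", "life_years", "events"),
                   cohort = unname(cohort), microsim = micro, se = se,
                   z = (micro - unname(cohort)) / se)
  })
}
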