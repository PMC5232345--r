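#' Health states of the Markov model
#'
#' The 21 mutually exclusive states: normal life on lipid-lowering
#' treatment, three acute event states occupying one full cycle (myocardial
#' infarction, stroke, other CVD), three five-year post-CVD tunnels
#' (`post_<event>_1` through `post_<event>_5`), and two absorbing death
#' states (CVD and non-CVD).
#'
#' @return A tibble with columns `state`, `kind`, `event`, `post_year`.
#' @export
health_states <- function() {
  ev <- event_types()
  tibble::tibble(
    state = c("on_treatment", paste0("acute_", ev),
              paste0("post_", rep(ev, each = 5), "_", rep(1:5, 3)),
              "dead_cvd", "dead_other"),
    kind = c("on_treatment", rep("acute", 3), rep("post", 15), "dead", "dead"),
    event = c(NA, ev, rep(ev, each = 5), NA, NA),
    post_year = c(rep(NA_integer_, 4), rep(1:5, 3), NA, NA)
  )
}

.state_names <- c("on_treatment", paste0("acute_", c("mi", "stroke", "other")),
                  paste0("post_", rep(c("mi", "stroke", "other"), each = 5),
                         "_", rep(1:5, 3)),
                  "dead_cvd", "dead_other")

state_names <- function() .state_names

# index helpers
.S <- list(on = 1L, acute = 2:4, post = 5:19, dead_cvd = 20L, dead_other = 21L,
           post_first = c(5L, 10L, 15L), alive = 1:19, non_acute = c(1L, 5:19))

#' Transition matrix at one age
#'
#' Assembles the 21 x 21 one-cycle transition matrix for a given age, arm
#' and scenario. From normal life: acute events at the first-event
#' probabilities, then non-CVD death among those without an event. From an
#' acute state: event-type case fatality, then non-CVD death, survivors
#' enter post year 1. From a post state: subsequent events (restarting the
#' acute/post clock), post-CVD mortality, non-CVD death among the remainder,
#' then advancement along the tunnel, returning to normal life after post
#' year 5. Death states are absorbing.
#'
#' In the normal-life and post-CVD rows, events, CVD death and non-CVD death
#' are exclusive competing risks and the remainder carries on; in the acute
#' rows, where case fatality is large, the event-type fatality resolves
#' first and non-CVD death applies to the survivors. Rows sum to one by
#' construction; a row whose probabilities exceed one signals a parameter
#' conflict.
#'
#' @param age integer age within the horizon.
#' @param arm `"statin_only"` or `"statin_pcsk9"`.
#' @param scenario `"trial_rrr"` or `"framingham_ldl"`.
#' @param params A `pcsk9_params` object.
#' @return A 21 x 21 matrix with state dimnames; rows sum to 1.
#' @export
build_transition_matrix <- function(age, arm = c("statin_only", "statin_pcsk9"),
                                    scenario = NULL,
                                    params = model_parameters()) {
  arm <- match.arg(arm)
  scenario <- scenario %||% params$scenario
  check_age(age, params)
  tab <- hazard_tables(params, scenario)
  t <- match(age, tab$ages)
  transition_matrix_at(tab, t, arm_multiplier(tab, arm)[t])
}

# matrix assembly from precomputed tables; t indexes the age row
transition_matrix_at <- function(tab, t, mult) {
  M <- matrix(0, 21, 21, dimnames = list(state_names(), state_names()))
  first <- tab$first[t, ] * mult
  subs <- tab$subsequent[t, ] * mult
  nc <- tab$non_cvd_mortality[t]
  if (sum(first) > 1 || sum(subs) + max(tab$post_mortality[t, ]) > 1) {
    stop("parameter-conflict: event/mortality probabilities exceed 1 in a row",
         call. = FALSE)
  }
  surv <- 1 - nc
  # on_treatment: non-CVD death first, events among the survivors
  M[1, .S$acute] <- first * surv
  M[1, .S$dead_other] <- nc
  M[1, 1] <- surv * (1 - sum(first))
  # acute states: non-CVD death, then the event-type case fatality
  for (k in 1:3) {
    q <- tab$acute_mortality[t, k]
    i <- .S$acute[k]
    M[i, .S$dead_other] <- nc
    M[i, .S$dead_cvd] <- surv * q
    M[i, .S$post_first[k]] <- surv * (1 - q)
  }
  # post tunnels: non-CVD death, then subsequent events and CVD death; the
  # remainder advances along the tunnel
  for (k in 1:3) {
    r <- tab$post_mortality[t, k]
    for (y in 1:5) {
      i <- .S$post_first[k] + y - 1L
      M[i, .S$dead_other] <- nc
      M[i, .S$acute] <- surv * subs
      M[i, .S$dead_cvd] <- surv * r
      dest <- if (y < 5) i + 1L else .S$on
      M[i, dest] <- surv * (1 - sum(subs) - r)
    }
  }
  M[.S$dead_cvd, .S$dead_cvd] <- 1
  M[.S$dead_other, .S$dead_other] <- 1
  M
}

# list of one transition matrix per model age
transition_array <- function(params, arm, scenario = NULL,
                             tables = NULL) {
  scenario <- scenario %||% params$scenario
  tab <- tables %||% hazard_tables(params, scenario)
  mult <- arm_multiplier(tab, arm)
  lapply(seq_along(tab$ages), function(t)
    transition_matrix_at(tab, t, mult[t]))
}

#' Run the Markov cohort for one arm
#'
#' Iterates the cohort occupancy over 1-year cycles from the start age
#' (cycle 0, everyone in normal life on treatment) to the end age, recording
#' per-cycle state occupancy, new CVD events, undiscounted cost and QALY
#' accrual, and the alive fraction.
#'
#' New events per cycle count entries into the acute states plus fatal
#' recurrences (post-CVD to CVD-death transitions), which also incur the
#' event-type acute cost; see the methods vignette.
#'
#' @param params A `pcsk9_params` object.
#' @param arm `"statin_only"` or `"statin_pcsk9"`.
#' @param scenario `"trial_rrr"` or `"framingham_ldl"`.
#' @param price annual PCSK9 price used for the trace's undiscounted cost
#'   column (defaults to `params$pcsk9_price`; ignored for the statin arm).
#' @return A tibble of class `pcsk9_trace` with columns `cycle`, `age`, one
#'   occupancy column per state, `alive`, `new_events_mi/stroke/other`
#'   (expected counts during the cycle, including fatal recurrences),
#'   `cost_undisc` and `qaly_undisc`. The arm and scenario are attached as
#'   attributes.
#' @examples
#' tr <- run_cohort(model_parameters(), "statin_only")
#' sum(tr$alive <= 1)   # 43 cycles
#' @export
run_cohort <- function(params = model_parameters(),
                       arm = c("statin_only", "statin_pcsk9"),
                       scenario = NULL, price = params$pcsk9_price) {
  arm <- match.arg(arm)
  scenario <- scenario %||% params$scenario
  tab <- hazard_tables(params, scenario)
  run_cohort_engine(params, arm, scenario, tab, price)
}

# occupancy matrix (cycles x states) for one arm
cohort_occupancy <- function(params, arm, scenario, tab) {
  mats <- transition_array(params, arm, scenario, tables = tab)
  n <- length(tab$ages)
  occ <- matrix(0, n, 21, dimnames = list(NULL, state_names()))
  occ[1, 1] <- 1
  for (t in seq_len(n - 1)) {
    occ[t + 1, ] <- occ[t, ] %*% mats[[t]]
  }
  occ
}

# expected flows during each cycle, consistent with the transition rows:
# non-CVD survivors of each state generate events / fatal recurrences
cohort_flows <- function(occ, tab, mult) {
  n <- nrow(occ)
  surv <- 1 - tab$non_cvd_mortality
  post_by_type <- vapply(1:3, function(k)
    rowSums(occ[, .S$post_first[k] + 0:4, drop = FALSE]), numeric(n))
  fatal <- post_by_type * tab$post_mortality * surv          # n x 3
  acute_inflow <- vapply(1:3, function(k) {
    (occ[, 1] * tab$first[, k] +
       rowSums(post_by_type) * tab$subsequent[, k]) * mult * surv
  }, numeric(n))
  list(fatal = fatal, new_events = acute_inflow + fatal)
}

# engine shared by run_cohort and the PSA (which passes perturbed tables)
run_cohort_engine <- function(params, arm, scenario, tab, price) {
  occ <- cohort_occupancy(params, arm, scenario, tab)
  n <- nrow(occ)
  fl <- cohort_flows(occ, tab, arm_multiplier(tab, arm))
  fatal <- fl$fatal
  new_events <- fl$new_events
  cost <- state_cost_cycle(occ, fatal, params, arm, price)
  qaly <- state_qaly_cycle(occ, params)
  out <- tibble::as_tibble(occ)
  out <- dplyr::bind_cols(
    tibble::tibble(cycle = 0:(n - 1), age = as.integer(tab$ages)), out,
    tibble::tibble(alive = rowSums(occ[, .S$alive]),
                   new_events_mi = new_events[, 1],
                   new_events_stroke = new_events[, 2],
                   new_events_other = new_events[, 3],
                   cost_undisc = cost$total,
                   qaly_undisc = qaly))
  attr(out, "arm") <- arm
  attr(out, "scenario") <- scenario
  attr(out, "price") <- price
  class(out) <- c("pcsk9_trace", class(out))
  out
}

# per-cycle undiscounted health-system cost components for a trace's
# occupancy: therapy on alive non-acute occupancy; acute event costs on
# acute occupancy and on fatal recurrences; decaying post-event costs
state_cost_cycle <- function(occ, fatal, params, arm, price) {
  therapy_annual <- params$statin_annual_cost +
    params$baseline_care_annual_cost +
    if (arm == "statin_pcsk9") price else 0
  evc <- params$event_costs[event_types()]
  pc1 <- params$post_event_first_year_costs[event_types()]
  decay <- (1 - params$post_cost_decay)^(0:4)
  post_cost_vec <- c(pc1[1] * decay, pc1[2] * decay, pc1[3] * decay)
  treatment <- therapy_annual * rowSums(occ[, .S$non_acute])
  medical <- occ[, .S$acute, drop = FALSE] %*% evc +
    occ[, .S$post, drop = FALSE] %*% post_cost_vec +
    fatal %*% evc
  list(treatment = treatment, medical = drop(medical),
       total = treatment + drop(medical))
}

# per-cycle undiscounted QALY accrual: on-treatment utility, acute year at
# the event-type floor, post years on the concave recovery path, all alive
# utilities reduced by the EQ-5D age gradient
state_qaly_cycle <- function(occ, params) {
  u <- state_utilities(params)
  agedec <- params$utility_age_gradient * (seq_len(nrow(occ)) - 1)
  umat <- outer(rep(1, nrow(occ)), u[.S$alive]) - agedec
  umat[umat < 0] <- 0
  rowSums(occ[, .S$alive, drop = FALSE] * umat)
}

# utility by state at the start age (before the age decrement)
state_utilities <- function(params) {
  u_on <- params$utility_on_treatment
  fl <- params$post_event_utility_floor[event_types()]
  g <- params$utility_recovery_exponent
  path <- function(floor) floor + (u_on - floor) * ((0:4) / 4)^g
  u <- c(u_on, fl, path(fl[1]), path(fl[2]), path(fl[3]), 0, 0)
  names(u) <- state_names()
  u
}

#' Incremental outcomes between two arms
#'
#' Differences (arm A minus arm B) in discounted QALYs, discounted life
#' years and expected lifetime CVD event counts between two cohort traces.
#' QALYs and life years are discounted at `discount_rate`; event counts are
#' undiscounted expected numbers of events.
#'
#' @param trace_a,trace_b traces from [run_cohort()] of equal length.
#' @param discount_rate annual discount rate (default 3 percent).
#' @return A tibble with columns `delta_qaly`, `delta_life_years`,
#'   `delta_events`.
#' @export
incremental_outcomes <- function(trace_a, trace_b, discount_rate = 0.03) {
  if (nrow(trace_a) != nrow(trace_b)) {
    stop("trace-error: traces must have the same number of cycles",
         call. = FALSE)
  }
  d <- (1 + discount_rate)^-(trace_a$cycle)
  ev <- function(tr) tr$new_events_mi + tr$new_events_stroke +
    tr$new_events_other
  tibble::tibble(
    delta_qaly = sum(trace_a$qaly_undisc * d) - sum(trace_b$qaly_undisc * d),
    delta_life_years = sum(trace_a$alive * d) - sum(trace_b$alive * d),
    delta_events = sum(ev(trace_a)) - sum(ev(trace_b))
  )
}

#' @export
print.pcsk9_trace <- function(x, ...) {
  cat(sprintf("<pcsk9_trace> arm=%s scenario=%s cycles=%d\n",
              attr(x, "arm"), attr(x, "scenario"), nrow(x)))
  NextMethod()
}

#' Occupancy plot for a cohort trace
#'
#' @param object a `pcsk9_trace`.
#' @param ... unused.
#' @return A ggplot of state-group occupancy over age.
#' @export
autoplot.pcsk9_trace <- function(object, ...) {
  kinds <- health_states()
  df <- tidyr::pivot_longer(as.data.frame(object)[, c("age", state_names())],
                            -"age", names_to = "state",
                            values_to = "occupancy")
  df$group <- kinds$kind[match(df$state, kinds$state)]
  df <- dplyr::summarise(dplyr::group_by(df, .data$age, .data$group),
                         occupancy = sum(.data$occupancy), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$occupancy,
                                   fill = .data$group)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age", y = "Cohort fraction", fill = NULL) +
    ggplot2::theme_minimal()
}
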