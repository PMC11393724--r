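# Accrual: turn a cohort trace into discounted costs, life-years and QALYs
# under payer and societal perspectives. State-membership costs and utilities
# are weighted by start-of-cycle occupancy; one-time costs by incident flows;
# scheduled cost events (testing, surgery, screening, ...) by the probability
# of being well when they fall due. No half-cycle correction is applied.

#' Build the accrual rules for one subgroup and intervention profile
#'
#' Assembles per-cycle utility and annual-cost vectors over the engine state
#' space, one-time event costs, and the dated cost events of
#' [upfront_costs()]. Utilities compose multiplicatively: the state utility
#' (Well = 1) times the RRM disutility multiplier (0.88 from the RRM age)
#' times the RRSO multiplier (0.95 from the RRSO age), capped at 1. Annual
#' breast-cancer costs use the carrier or general-population tariff by true
#' carrier status; ovarian-cancer annual costs differ between post-diagnosis
#' years 1-2 and 3-5. Women with RRSO and no HRT carry the annual excess-CHD
#' morbidity cost while in Well during the excess-risk window.
#'
#' @inheritParams build_matrix
#' @return An object of class `accrual_rules` with matrices `utilities` and
#'   `state_costs` (`n_cycles x 31`), vector `event_costs`, data.frame
#'   `cost_events` and the productivity flag fields.
#' @export
accrual_rules <- function(sub, profile, ps, epi) {
  start <- ps$settings$start_age
  horizon <- ps$settings$horizon_age
  ages <- start:(horizon - 1)   # age at the start of each accrual cycle
  n <- length(ages)
  S <- length(.engine_states)
  pv <- function(nm) parameter_value(ps, nm)

  u_state <- setNames(numeric(S), .engine_states)
  u_state["Well"] <- 1
  u_state[paste0("BC_E", 1:5)] <- pv("utility_bc_early")
  u_state[paste0("BC_A", 1:5)] <- pv("utility_bc_advanced")
  u_state["BC_Rem"] <- pv("utility_bc_remission")
  u_state["BC_Rec"] <- pv("utility_bc_recurrent")
  u_state["BC_Term"] <- pv("utility_bc_terminal")
  u_state[paste0("OC_E", 1:5)] <- pv("utility_oc_early")
  u_state[paste0("OC_A", 1:5)] <- pv("utility_oc_advanced")
  u_state["OC_Rem"] <- pv("utility_oc_remission")
  u_state["OC_Rec"] <- pv("utility_oc_recurrent")
  u_state["OC_Term"] <- pv("utility_oc_terminal")

  # Surgery utility multipliers apply during a post-surgery recovery window
  # (default one year); overlapping windows compose multiplicatively.
  surg_mult <- rep(1, n)
  sch <- ps$schedules
  if (isTRUE(profile$rrm)) {
    w <- ages >= sch$rrm_age & ages < sch$rrm_age + sch$rrm_disutility_years
    surg_mult[w] <- surg_mult[w] * pv("utility_rrm")
  }
  if (isTRUE(profile$rrso)) {
    w <- ages >= sch$rrso_age & ages < sch$rrso_age + sch$rrso_disutility_years
    surg_mult[w] <- surg_mult[w] * pv("utility_rrso")
  }
  utilities <- pmin(outer(surg_mult, u_state), 1)
  colnames(utilities) <- .engine_states

  bc_annual <- if (isTRUE(sub$carrier)) pv("cost_bc_annual_carrier")
               else pv("cost_bc_annual_general")
  c_state <- setNames(numeric(S), .engine_states)
  c_state[c(paste0("BC_E", 1:5), paste0("BC_A", 1:5), "BC_Rec")] <- bc_annual
  c_state[c("OC_E1", "OC_E2", "OC_A1", "OC_A2", "OC_Rec")] <- pv("cost_oc_annual_y1_2")
  c_state[c(paste0("OC_E", 3:5), paste0("OC_A", 3:5))] <- pv("cost_oc_annual_y3_5")
  state_costs <- matrix(rep(c_state, each = n), n, S,
                        dimnames = list(NULL, .engine_states))
  mods <- hazard_modifiers(profile, ps)
  if (mods$chd_excess > 0) {
    in_window <- ages >= mods$chd_window[1] & ages < mods$chd_window[2]
    state_costs[in_window, "Well"] <-
      state_costs[in_window, "Well"] + pv("cost_chd_annual")
  }

  event_costs <- c(
    dx_bc = if (isTRUE(sub$carrier)) pv("cost_bc_diagnosis_carrier")
            else pv("cost_bc_diagnosis_general"),
    dx_oc = pv("cost_oc_diagnosis"),
    term_bc = pv("cost_bc_terminal"),
    term_oc = pv("cost_oc_terminal"),
    death_chd = pv("cost_chd_fatal")
  )

  structure(list(
    utilities = utilities, state_costs = state_costs,
    event_costs = event_costs,
    cost_events = upfront_costs(sub, profile, ps),
    ages = ages
  ), class = "accrual_rules")
}

#' Accrue discounted costs, life-years and QALYs from a trace
#'
#' Applies the accrual rules cycle by cycle: life-years and QALYs from
#' start-of-cycle occupancy, annual state costs likewise, one-time event
#' costs from the incident flows of the cycle in which they occur, and
#' scheduled cost events at their due age (entry-age events undiscounted at
#' cycle 0). The societal perspective adds the productivity losses of
#' [productivity_loss()]; the payer perspective excludes them.
#'
#' @param trace A `cohort_trace`.
#' @param rules An `accrual_rules` object.
#' @param ps A `brca_params` object (for settings).
#' @param epi A `brca_epi` object (for productivity inputs).
#' @return A list with `payer` and `societal` sub-lists (`cost`, `ly`,
#'   `qaly`, each with `_undiscounted` twins) and `events` (cumulative
#'   per-woman probabilities of BC/OC diagnosis, BC/OC death, excess CHD
#'   death).
#' @export
accrue <- function(trace, rules, ps, epi) {
  settings <- ps$settings
  occ <- trace$occupancy
  n <- nrow(occ) - 1
  disc <- (1 + settings$discount_rate)^-(0:(n - 1))

  occ_cycle <- occ[1:n, , drop = FALSE]
  ly_t <- rowSums(occ_cycle[, .alive_states, drop = FALSE])
  qaly_t <- rowSums(occ_cycle * rules$utilities)
  state_cost_t <- rowSums(occ_cycle * rules$state_costs)
  fl <- trace$flows
  event_cost_t <- rules$event_costs[["dx_bc"]] * fl$dx_bc +
    rules$event_costs[["dx_oc"]] * fl$dx_oc +
    rules$event_costs[["term_bc"]] * fl$term_bc +
    rules$event_costs[["term_oc"]] * fl$term_oc +
    rules$event_costs[["death_chd"]] * fl$death_chd

  sched_t <- numeric(n)
  ce <- rules$cost_events
  if (nrow(ce) > 0) {
    cyc <- ce$age - settings$start_age + 1
    w <- ifelse(ce$weight_by == "cohort", 1, occ[cbind(cyc, .sidx("Well"))])
    amounts <- ce$amount * w
    sched_t <- as.numeric(tapply(amounts, factor(cyc, levels = 1:n), sum,
                                 default = 0))
  }

  cost_t <- state_cost_t + event_cost_t + sched_t
  prod <- productivity_loss(trace, epi$productivity, settings)

  events <- c(bc_dx = sum(fl$dx_bc), oc_dx = sum(fl$dx_oc),
              bc_deaths = sum(fl$death_bc), oc_deaths = sum(fl$death_oc),
              chd_deaths = sum(fl$death_chd))

  list(
    payer = list(cost = sum(cost_t * disc), ly = sum(ly_t * disc),
                 qaly = sum(qaly_t * disc),
                 cost_undiscounted = sum(cost_t), ly_undiscounted = sum(ly_t),
                 qaly_undiscounted = sum(qaly_t)),
    societal = list(cost = sum(cost_t * disc) + prod$discounted,
                    ly = sum(ly_t * disc), qaly = sum(qaly_t * disc),
                    cost_undiscounted = sum(cost_t) + prod$undiscounted,
                    ly_undiscounted = sum(ly_t), qaly_undiscounted = sum(qaly_t)),
    events = events
  )
}

#' Productivity losses under the human-capital approach
#'
#' Values three components against age-specific earnings and employment
#' rates, all zero at or after the retirement age: temporary disability
#' (a fixed fraction of diagnosed women absent for a fixed fraction of a
#' year at diagnosis), permanent disability (a fixed fractional reduction of
#' earnings while alive in post-diagnosis cancer states), and premature
#' mortality (the discounted stream of foregone earnings from cancer or
#' excess-CHD death until retirement). Background (other-cause) deaths do
#' not enter: only the modelled disease pathways generate productivity loss.
#'
#' @param trace A `cohort_trace`.
#' @param productivity The `productivity` element of a `brca_epi`.
#' @param settings A `brca_settings`.
#' @return List with `discounted` and `undiscounted` totals per woman.
#' @export
productivity_loss <- function(trace, productivity, settings) {
  occ <- trace$occupancy
  n <- nrow(occ) - 1
  ages <- settings$start_age + 0:(n - 1)
  disc <- (1 + settings$discount_rate)^-(0:(n - 1))
  tab <- productivity$table
  earn <- .lookup(tab, "earnings", ages) * .lookup(tab, "employment", ages)
  working <- ages < productivity$retirement_age
  earn[!working] <- 0
  fl <- trace$flows

  dx <- fl$dx_bc + fl$dx_oc
  temp_t <- productivity$temporary_fraction_affected *
    productivity$temporary_absence_years * earn * dx

  post_dx_states <- setdiff(.alive_states, "Well")
  post_occ <- rowSums(occ[1:n, post_dx_states, drop = FALSE])
  perm_t <- productivity$permanent_reduction_fraction * earn * post_occ

  # Present value at each age of the earnings stream to retirement.
  pv_stream <- function(rate) {
    dfac <- (1 + rate)^-(0:(n - 1))
    pv <- numeric(n)
    acc <- 0
    for (t in n:1) {
      acc <- earn[t] * dfac[t] + if (t < n) acc else 0
      pv[t] <- acc / dfac[t]   # value discounted to cycle t
    }
    pv
  }
  deaths <- fl$death_bc + fl$death_oc + fl$death_chd
  # a death during cycle t forgoes earnings from cycle t+1 onward
  stream_disc <- pv_stream(settings$discount_rate)
  stream_undisc <- pv_stream(0)
  mort_disc <- sum(deaths[1:(n - 1)] * stream_disc[2:n] *
                     disc[2:n] / 1)  # discount to cycle 0
  mort_undisc <- sum(deaths[1:(n - 1)] * stream_undisc[2:n])

  list(
    discounted = sum((temp_t + perm_t) * disc) + mort_disc,
    undiscounted = sum(temp_t + perm_t) + mort_undisc
  )
}
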