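# Decision-tree front end: who is tested under each strategy, what result
# they receive, which prevention/screening package follows, and what that
# package does to cancer and coronary hazards and to dated costs.

#' Enumerate the decision-tree subgroups of a testing strategy
#'
#' Expands the testing decision tree into exhaustive, mutually exclusive
#' leaves over family-history (FH) status, carrier status and test outcome.
#' Under the population strategy all women are tested; under the FH-based
#' strategy only women meeting the clinical/FH criteria are. Carriers are
#' classified as pathogenic-variant (PV) positive with probability equal to
#' the test sensitivity, otherwise missed (false negative, managed as
#' untested). Non-carriers can receive a variant-of-uncertain-significance
#' (VUS) result or, with probability 1 - specificity, a false-positive PV
#' result. Carrier prevalence is conditioned on FH in both arms, so the total
#' carrier mass is identical across strategies.
#'
#' @param strategy `"population"` or `"fh_based"`.
#' @param ps A `brca_params` object.
#' @return A data.frame with one row per leaf: `strategy`, `fh`, `carrier`,
#'   `tested`, `result` (`"pv"`, `"neg"`, `"vus"`, `"fp"`, `"untested"`),
#'   `detected`, `vus`, `weight`.
#' @export
enumerate_subgroups <- function(strategy = c("population", "fh_based"), ps) {
  strategy <- match.arg(strategy)
  p_fh <- parameter_value(ps, "p_fh")
  sens <- parameter_value(ps, "test_sensitivity")
  spec <- parameter_value(ps, "test_specificity")
  p_vus <- parameter_value(ps, "vus_probability")

  rows <- list()
  add <- function(fh, carrier, tested, result, weight) {
    rows[[length(rows) + 1]] <<- data.frame(
      strategy = strategy, fh = fh, carrier = carrier, tested = tested,
      result = result, detected = result %in% c("pv", "fp"),
      vus = result == "vus", weight = weight
    )
  }
  for (fh in c(TRUE, FALSE)) {
    w_fh <- if (fh) p_fh else 1 - p_fh
    prev <- parameter_value(ps, if (fh) "prevalence_fh" else "prevalence_no_fh")
    tested <- strategy == "population" || fh
    if (tested) {
      add(fh, TRUE, TRUE, "pv", w_fh * prev * sens)
      if (sens < 1) add(fh, TRUE, TRUE, "neg", w_fh * prev * (1 - sens))
      add(fh, FALSE, TRUE, "vus", w_fh * (1 - prev) * p_vus)
      if (spec < 1)
        add(fh, FALSE, TRUE, "fp", w_fh * (1 - prev) * (1 - p_vus) * (1 - spec))
      add(fh, FALSE, TRUE, "neg", w_fh * (1 - prev) * (1 - p_vus) * spec)
    } else {
      add(fh, TRUE, FALSE, "untested", w_fh * prev)
      add(fh, FALSE, FALSE, "untested", w_fh * (1 - prev))
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(abs(sum(out$weight) - 1) < 1e-12)
  out
}

#' Intervention uptake distribution for one subgroup
#'
#' Women with a positive PV result (true or false positive) choose among
#' risk-reducing mastectomy (RRM), risk-reducing salpingo-oophorectomy
#' (RRSO) and breast-cancer chemoprevention independently at the published
#' uptake rates; women undergoing RRSO before the HRT stop age take hormone
#' replacement therapy with the published compliance. Everyone else (missed
#' carriers, true negatives, VUS results, untested women) receives general
#' population screening only.
#'
#' @param sub One row of [enumerate_subgroups()].
#' @param ps A `brca_params` object.
#' @return A data.frame of intervention profiles: `rrm`, `rrso`, `chemo`,
#'   `hrt` (logicals), `screening` (`"carrier"` or `"general"`), `prob`
#'   (summing to 1).
#' @export
assign_interventions <- function(sub, ps) {
  if (!isTRUE(sub$detected)) {
    return(data.frame(rrm = FALSE, rrso = FALSE, chemo = FALSE, hrt = FALSE,
                      screening = "general", prob = 1))
  }
  u_rrm <- parameter_value(ps, "uptake_rrm")
  u_rrso <- parameter_value(ps, "uptake_rrso")
  u_chemo <- parameter_value(ps, "uptake_chemoprevention")
  # HRT is only meaningful when RRSO happens before natural menopause age.
  p_hrt <- if (ps$schedules$rrso_age < ps$schedules$hrt_stop_age)
    parameter_value(ps, "hrt_compliance") else 0

  grid <- expand.grid(rrm = c(TRUE, FALSE), rrso = c(TRUE, FALSE),
                      chemo = c(TRUE, FALSE), hrt = c(TRUE, FALSE))
  grid <- grid[!(grid$hrt & !grid$rrso), , drop = FALSE]
  grid$prob <- with(grid,
    ifelse(rrm, u_rrm, 1 - u_rrm) *
    ifelse(rrso, u_rrso, 1 - u_rrso) *
    ifelse(chemo, u_chemo, 1 - u_chemo) *
    ifelse(rrso, ifelse(hrt, p_hrt, 1 - p_hrt), 1))
  grid$screening <- "carrier"
  grid <- grid[grid$prob > 0, , drop = FALSE]
  rownames(grid) <- NULL
  stopifnot(abs(sum(grid$prob) - 1) < 1e-12)
  grid[, c("rrm", "rrso", "chemo", "hrt", "screening", "prob")]
}

#' Hazard modifiers implied by an intervention profile
#'
#' Translates a prevention package into multiplicative modifiers of the
#' annual cancer hazards and an excess coronary heart disease (CHD) risk.
#' RRSO removes 96% of ovarian-cancer risk from the RRSO age onward. Breast
#' cancer risk is multiplied by 0.09 after RRM alone, 0.49 after RRSO alone,
#' and 0.05 after both (each component active from its surgery age), and by a
#' further 0.71 during the chemoprevention window; components compose
#' multiplicatively. RRSO without HRT carries an annual excess CHD risk
#' (fatal with the published case-fatality fraction) from the RRSO age until
#' the HRT stop age.
#'
#' @param profile One row of [assign_interventions()].
#' @param ps A `brca_params` object.
#' @return An object of class `hazard_modifiers`: list with `bc_multiplier`
#'   and `oc_multiplier` functions of age evaluated by the engine via
#'   [modifier_vectors()], plus the CHD fields.
#' @export
hazard_modifiers <- function(profile, ps) {
  sch <- ps$schedules
  rrso_active <- isTRUE(profile$rrso)
  mods <- structure(list(
    rrm = isTRUE(profile$rrm), rrso = rrso_active,
    chemo = isTRUE(profile$chemo), hrt = isTRUE(profile$hrt),
    rrm_age = sch$rrm_age, rrso_age = sch$rrso_age,
    rrm_mult = 1 - parameter_value(ps, "rrm_bc_reduction"),
    rrso_mult = parameter_value(ps, "hr_bc_rrso"),
    rrm_rrso_mult = 1 - parameter_value(ps, "rrm_rrso_bc_reduction"),
    oc_mult = 1 - parameter_value(ps, "rrso_oc_reduction"),
    chemo_mult = parameter_value(ps, "hr_bc_chemoprevention"),
    chemo_window = c(sch$chemoprevention_start_age,
                     sch$chemoprevention_start_age +
                       sch$chemoprevention_duration_years),
    chd_excess = if (rrso_active && !isTRUE(profile$hrt))
      parameter_value(ps, "chd_excess_risk") else 0,
    chd_fatal_fraction = parameter_value(ps, "chd_fatal_fraction"),
    chd_window = c(sch$rrso_age, sch$hrt_stop_age)
  ), class = "hazard_modifiers")
  mods
}

#' Evaluate hazard modifiers on an age grid
#'
#' Returns, for each age, the breast- and ovarian-cancer hazard multipliers
#' and the annual fatal excess CHD probability implied by a
#' [hazard_modifiers()] object. Age intervals are half-open: a surgery at age
#' a modifies hazards from age a onward, and windows `[start, stop)` include
#' the start age but not the stop age.
#'
#' @param mods A `hazard_modifiers` object.
#' @param ages Integer vector of ages.
#' @return A list of numeric vectors `bc`, `oc`, `chd_fatal` (one value per
#'   age).
#' @export
modifier_vectors <- function(mods, ages) {
  bc <- rep(1, length(ages))
  if (mods$rrm && mods$rrso) {
    both_age <- max(mods$rrm_age, mods$rrso_age)
    first_age <- min(mods$rrm_age, mods$rrso_age)
    first_mult <- if (mods$rrm_age <= mods$rrso_age) mods$rrm_mult else mods$rrso_mult
    bc[ages >= first_age] <- first_mult
    bc[ages >= both_age] <- mods$rrm_rrso_mult
  } else if (mods$rrm) {
    bc[ages >= mods$rrm_age] <- mods$rrm_mult
  } else if (mods$rrso) {
    bc[ages >= mods$rrso_age] <- mods$rrso_mult
  }
  if (mods$chemo) {
    in_window <- ages >= mods$chemo_window[1] & ages < mods$chemo_window[2]
    bc[in_window] <- bc[in_window] * mods$chemo_mult
  }
  bc <- pmin(bc, 1)

  oc <- rep(1, length(ages))
  if (mods$rrso) oc[ages >= mods$rrso_age] <- mods$oc_mult

  chd <- rep(0, length(ages))
  if (mods$chd_excess > 0) {
    in_window <- ages >= mods$chd_window[1] & ages < mods$chd_window[2]
    chd[in_window] <- mods$chd_excess * mods$chd_fatal_fraction
  }
  list(bc = bc, oc = oc, chd_fatal = chd)
}

# Stable cache key: traces depend only on these hazard-relevant fields.
.modifier_key <- function(carrier, mods, sub = NULL) {
  paste(carrier, mods$rrm, mods$rrso, mods$chemo, mods$hrt,
        mods$rrm_age, mods$rrso_age,
        signif(c(mods$rrm_mult, mods$rrso_mult, mods$rrm_rrso_mult,
                 mods$oc_mult, mods$chemo_mult, mods$chd_excess,
                 mods$chd_fatal_fraction), 12),
        collapse = "|")
}

#' Dated cost events for a subgroup and intervention profile
#'
#' Lists every scheduled (non-state) cost the pathway incurs: testing and
#' pretest counselling at entry for tested women, posttest counselling for PV
#' and VUS results, surgery costs at the RRM/RRSO ages, annual HRT until the
#' stop age, annual chemoprevention during its window, and the screening
#' schedule (biennial mammography at ages 50-74 for the general population;
#' annual mammography at 40-69 plus annual MRI at 30-49 for detected
#' carriers, truncated at the RRM age for women who undergo RRM). Events at
#' the entry age are booked against the whole subgroup; later events are
#' weighted by the probability of still being well when they fall due.
#'
#' @param sub One row of [enumerate_subgroups()].
#' @param profile One row of [assign_interventions()].
#' @param ps A `brca_params` object.
#' @return A data.frame with columns `age`, `item`, `amount`, `weight_by`
#'   (`"cohort"` for entry-age events, `"well"` for conditional ones).
#' @export
upfront_costs <- function(sub, profile, ps) {
  sch <- ps$schedules
  start <- ps$settings$start_age
  horizon <- ps$settings$horizon_age
  e_age <- integer(0); e_item <- character(0)
  e_amount <- numeric(0); e_wb <- character(0)
  add <- function(age, item, amount, weight_by = "well") {
    k <- length(age)
    e_age <<- c(e_age, age)
    e_item <<- c(e_item, rep_len(item, k))
    e_amount <<- c(e_amount, rep_len(amount, k))
    e_wb <<- c(e_wb, rep_len(weight_by, k))
  }
  if (isTRUE(sub$tested)) {
    add(start, "genetic_test", parameter_value(ps, "cost_genetic_testing"), "cohort")
    add(start, "pretest_counselling",
        parameter_value(ps, "cost_genetic_counselling"), "cohort")
    if (sub$result %in% c("pv", "fp", "vus"))
      add(start, "posttest_counselling",
          parameter_value(ps, "cost_genetic_counselling"), "cohort")
    if (sub$result == "vus") {
      p_rc <- parameter_value(ps, "vus_reclassification_probability")
      c_rc <- parameter_value(ps, "cost_vus_reclassification")
      if (p_rc * c_rc > 0)
        add(start, "vus_reclassification", p_rc * c_rc, "cohort")
    }
  }
  if (isTRUE(profile$rrm) && sch$rrm_age <= horizon)
    add(max(sch$rrm_age, start), "rrm", parameter_value(ps, "cost_rrm"))
  if (isTRUE(profile$rrso) && sch$rrso_age <= horizon)
    add(max(sch$rrso_age, start), "rrso", parameter_value(ps, "cost_rrso"))
  if (isTRUE(profile$hrt)) {
    add(seq2(max(sch$rrso_age, start), sch$hrt_stop_age - 1), "hrt",
        parameter_value(ps, "cost_hrt_annual"))
  }
  if (isTRUE(profile$chemo)) {
    w <- c(max(sch$chemoprevention_start_age, start),
           sch$chemoprevention_start_age + sch$chemoprevention_duration_years - 1)
    add(seq2(w[1], min(w[2], horizon)), "chemoprevention",
        parameter_value(ps, "cost_chemoprevention_annual"))
  }
  scr <- if (identical(profile$screening, "carrier")) sch$screening$carrier
         else sch$screening$general
  stop_at <- if (isTRUE(profile$rrm)) sch$rrm_age - 1 else horizon
  for (modality in names(scr)) {
    def <- scr[[modality]]
    cost <- parameter_value(ps, paste0("cost_", if (modality == "mri") "mri"
                                       else "mammography"))
    ages <- seq(def$start, def$stop, by = def$every)
    ages <- ages[ages >= start & ages <= min(stop_at, horizon)]
    add(ages, modality, cost)
  }
  out <- data.frame(age = e_age, item = e_item, amount = e_amount,
                    weight_by = e_wb)
  out[order(out$age), , drop = FALSE]
}

# seq() that returns integer(0) when from > to (avoids seq()'s backwards runs)
seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)
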