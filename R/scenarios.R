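# Named scenario analyses: each scenario is a small set of overrides on the
# base-case parameters and schedules, run through the full dual-arm model.

#' Named scenario definitions
#'
#' The scenario grid: `base`; genetic testing offered at ages 40/50/60/70
#' (model entry moves to that age and both risk-reducing surgeries occur in
#' the next cycle); older surgery ages (RRM 48 / RRSO 50, with the variant
#' RRM 49 / RRSO 50 also provided); no breast-cancer risk reduction from
#' RRSO; no HRT use; half RRM uptake; half RRSO uptake; and 97% test
#' sensitivity.
#'
#' @return Named list of scenario descriptors (`label` and an `apply`
#'   function taking and returning a `brca_params`).
#' @export
scenario_definitions <- function() {
  test_age <- function(a) {
    force(a)
    function(ps) {
      ps$settings$start_age <- as.integer(a)
      ps$schedules$rrm_age <- a + 1
      ps$schedules$rrso_age <- a + 1
      ps$schedules$chemoprevention_start_age <- a
      ps
    }
  }
  halve <- function(name) {
    force(name)
    function(ps) set_parameter(ps, name, parameter_value(ps, name) / 2)
  }
  defs <- list(
    base = list(label = "Base case", apply = identity),
    test_age_40 = list(label = "Age 40 at genetic testing; age 41 at RRM and RRSO",
                       apply = test_age(40)),
    test_age_50 = list(label = "Age 50 at genetic testing; age 51 at RRM and RRSO",
                       apply = test_age(50)),
    test_age_60 = list(label = "Age 60 at genetic testing; age 61 at RRM and RRSO",
                       apply = test_age(60)),
    test_age_70 = list(label = "Age 70 at genetic testing; age 71 at RRM and RRSO",
                       apply = test_age(70)),
    late_surgery = list(label = "RRM at age 48; RRSO at age 50",
                        apply = function(ps) {
                          ps$schedules$rrm_age <- 48
                          ps$schedules$rrso_age <- 50
                          ps
                        }),
    late_surgery_49 = list(label = "RRM at age 49; RRSO at age 50",
                           apply = function(ps) {
                             ps$schedules$rrm_age <- 49
                             ps$schedules$rrso_age <- 50
                             ps
                           }),
    no_rrso_bc_effect = list(label = "No reduction in BC risk from RRSO",
                             apply = function(ps) {
                               ps <- set_parameter(ps, "hr_bc_rrso", 1)
                               set_parameter(ps, "rrm_rrso_bc_reduction",
                                             parameter_value(ps, "rrm_bc_reduction"))
                             }),
    no_hrt = list(label = "No adherence with HRT",
                  apply = function(ps) set_parameter(ps, "hrt_compliance", 0)),
    half_rrm = list(label = "Half RRM uptake", apply = halve("uptake_rrm")),
    half_rrso = list(label = "Half RRSO uptake", apply = halve("uptake_rrso")),
    sens97 = list(label = "97% sensitivity of genetic testing",
                  apply = function(ps) set_parameter(ps, "test_sensitivity", 0.97))
  )
  defs
}

#' Run a named scenario
#'
#' Applies the scenario's overrides to the parameter set and runs the full
#' dual-arm comparison (both perspectives are always computed).
#'
#' @param name Scenario name; see [scenario_definitions()].
#' @param ps A `brca_params` object (base case).
#' @param epi A `brca_epi` object.
#' @return A `comparison_result` with the scenario name and label attached
#'   as attributes.
#' @export
run_scenario <- function(name, ps, epi) {
  defs <- scenario_definitions()
  if (!name %in% names(defs))
    stop("unknown scenario '", name, "'; valid scenarios: ",
         paste(names(defs), collapse = ", "))
  ps2 <- defs[[name]]$apply(ps)
  res <- compare_strategies(ps2, epi)
  attr(res, "scenario") <- name
  attr(res, "scenario_label") <- defs[[name]]$label
  res
}

#' Run the whole scenario grid
#'
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @param names Scenario names (default: all).
#' @return Named list of `comparison_result` objects.
#' @export
run_all_scenarios <- function(ps, epi, names = names(scenario_definitions())) {
  setNames(lapply(names, run_scenario, ps = ps, epi = epi), names)
}
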