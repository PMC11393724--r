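#' @importFrom stats rbeta rgamma rlnorm setNames uniroot rbinom
#' @importFrom utils read.csv write.csv modifyList
NULL

# Parameter names the model cannot run without (every probability, cost and
# utility of the base-case table). Hooks with packaged defaults are listed
# separately and filled in (flagged as assumptions) when a config omits them.
.mandatory_params <- c(
  "prevalence_overall", "prevalence_fh", "prevalence_no_fh", "p_fh",
  "uptake_rrm", "uptake_rrso", "uptake_chemoprevention", "hrt_compliance",
  "rrso_oc_reduction", "hr_bc_rrso", "rrm_bc_reduction",
  "rrm_rrso_bc_reduction", "hr_bc_chemoprevention",
  "chd_excess_risk", "chd_fatal_fraction",
  "cost_genetic_testing", "cost_genetic_counselling", "cost_rrso", "cost_rrm",
  "cost_oc_diagnosis", "cost_oc_annual_y1_2", "cost_oc_annual_y3_5",
  "cost_oc_terminal", "cost_bc_diagnosis_general", "cost_bc_diagnosis_carrier",
  "cost_bc_annual_general", "cost_bc_annual_carrier", "cost_bc_terminal",
  "cost_hrt_annual", "cost_mammography", "cost_mri", "cost_chd_fatal",
  "cost_chd_annual", "cost_chemoprevention_annual",
  "utility_rrm", "utility_rrso",
  "utility_bc_early", "utility_bc_advanced", "utility_bc_recurrent",
  "utility_bc_remission", "utility_bc_terminal",
  "utility_oc_early", "utility_oc_advanced", "utility_oc_recurrent",
  "utility_oc_remission", "utility_oc_terminal"
)

.hook_defaults <- list(
  test_sensitivity = list(base = 0.9995, rule = "fixed"),
  test_specificity = list(base = 0.9995, rule = "fixed"),
  vus_probability = list(base = 0.02, rule = "pct10"),
  vus_reclassification_probability = list(base = 0.005, rule = "fixed"),
  cost_vus_reclassification = list(base = 0, rule = "fixed")
)

.param_kind <- function(name) {
  if (startsWith(name, "cost_")) "cost" else if (startsWith(name, "utility_")) "utility" else "probability"
}

#' Analysis settings
#'
#' Container for the global settings of the evaluation: the annual discount
#' rate applied to costs and health outcomes, willingness-to-pay thresholds
#' (CAD per QALY), the cohort entry age and horizon age (annual cycles run
#' from `start_age` to `horizon_age`), the population scale used for
#' per-million impact numbers, the number of probabilistic sensitivity
#' analysis draws, the reporting perspective and the master random seed.
#'
#' @param discount_rate Annual discount rate (fraction), default 0.015.
#' @param wtp_thresholds Willingness-to-pay thresholds, CAD per QALY.
#' @param start_age Cohort entry age in years (cycle 0).
#' @param horizon_age Final age of the simulation in years.
#' @param cohort_scale Number of women the per-population impact is scaled to.
#' @param psa_draws Number of probabilistic sensitivity analysis draws.
#' @param perspective `"payer"` or `"societal"` (reporting default; all runs
#'   compute both).
#' @param seed Master random seed.
#' @return An object of class `brca_settings`.
#' @export
analysis_settings <- function(discount_rate = 0.015,
                              wtp_thresholds = c(50000, 100000),
                              start_age = 30, horizon_age = 83,
                              cohort_scale = 1e6, psa_draws = 5000,
                              perspective = c("payer", "societal"),
                              seed = 1L) {
  perspective <- match.arg(perspective)
  s <- structure(list(
    discount_rate = discount_rate, wtp_thresholds = wtp_thresholds,
    start_age = as.integer(start_age), horizon_age = as.integer(horizon_age),
    cohort_scale = cohort_scale, psa_draws = as.integer(psa_draws),
    perspective = perspective, seed = as.integer(seed)
  ), class = "brca_settings")
  validate_settings(s)
  s
}

validate_settings <- function(s) {
  if (s$discount_rate < 0 || s$discount_rate >= 1)
    stop("discount_rate must be in [0, 1)")
  if (s$start_age >= s$horizon_age)
    stop("start_age must be below horizon_age")
  if (s$psa_draws < 1) stop("psa_draws must be >= 1")
  if (s$cohort_scale <= 0) stop("cohort_scale must be positive")
  invisible(s)
}

new_param_spec <- function(name, fields, kind) {
  base <- fields$base
  if (is.null(base)) stop("parameter '", name, "' has no base value")
  low <- fields$low
  high <- fields$high
  # SD-form uncertainty (utility rows reported as mean (SD)) becomes a
  # normal-approximation range truncated to the valid utility scale.
  if (is.null(low) && !is.null(fields$sd)) {
    low <- max(0, base - 1.96 * fields$sd)
    high <- min(1, base + 1.96 * fields$sd)
  }
  rule <- fields$rule
  if (is.null(rule)) {
    rule <- if (!is.null(low)) "ci" else switch(kind,
      cost = "pct30", utility = "pct10", probability = "pct10")
  }
  if (kind == "cost" && is.null(fields$rule) && is.null(fields$low)) rule <- "pct30"
  family <- fields$family
  if (is.null(family)) {
    family <- if (rule == "fixed") "none" else switch(kind,
      probability = "beta", cost = "gamma", utility = "lognormal")
  }
  spec <- structure(list(
    name = name, base = base, low = low, high = high, rule = rule,
    family = family, kind = kind, units = fields$units %||% switch(kind,
      cost = "CAD", utility = "utility", probability = "proportion"),
    pristine = base
  ), class = "param_spec")
  validate_param_spec(spec)
  spec
}

validate_param_spec <- function(spec) {
  with(spec, {
    if (kind %in% c("probability", "utility")) {
      vals <- c(base, low, high)
      if (any(vals < 0 | vals > 1))
        stop("parameter '", name, "' out of range: ", kind, " values must lie in [0, 1]")
    }
    if (kind == "cost" && base < 0)
      stop("parameter '", name, "' out of range: costs must be nonnegative")
    if (!is.null(low) && !is.null(high) && !(low <= base && base <= high))
      stop("parameter '", name, "' violates low <= base <= high")
    if (!rule %in% c("ci", "pct10", "pct30", "fixed"))
      stop("parameter '", name, "' has unknown variation rule '", rule, "'")
    if (rule == "ci" && (is.null(low) || is.null(high)))
      stop("parameter '", name, "' uses the ci rule but has no low/high bounds")
  })
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate the model parameter set
#'
#' Reads a structured configuration (YAML text, a file path, or an already
#' parsed list) with sections `settings`, `schedules`, `probabilities`,
#' `costs` and `utilities`, validates every parameter (ranges, bound ordering,
#' mandatory names) and checks the prevalence mixture identity
#' P(FH) * prev(FH) + (1 - P(FH)) * prev(no FH) against the overall carrier
#' prevalence (must agree within 5% relative). Optional hook parameters the
#' published table leaves open (test accuracy, VUS rate and reclassification)
#' are filled with packaged defaults and flagged as assumptions in the
#' returned provenance map.
#'
#' @param config `NULL` for the packaged base-case configuration, a path to a
#'   YAML file, a YAML string, or a list with the same structure.
#' @return An object of class `brca_params`: a list with elements `specs`
#'   (named `param_spec` list), `settings` (`brca_settings`), `schedules`
#'   (intervention ages and screening schedules) and `provenance` (named
#'   character vector, `"configured"` or `"assumption"`).
#' @examples
#' ps <- load_parameters()
#' parameter_value(ps, "uptake_rrso")
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "default_params.yaml", package = "brcacea",
                          mustWork = TRUE)
  }
  if (is.character(config)) {
    cfg <- if (length(config) == 1 && file.exists(config)) {
      yaml::read_yaml(config)
    } else {
      yaml::yaml.load(paste(config, collapse = "\n"))
    }
  } else if (is.list(config)) {
    cfg <- config
  } else stop("config must be NULL, a path, YAML text, or a list")

  specs <- list()
  provenance <- character(0)
  for (section in c("probabilities", "costs", "utilities")) {
    kind <- switch(section, probabilities = "probability",
                   costs = "cost", utilities = "utility")
    for (nm in names(cfg[[section]])) {
      fields <- cfg[[section]][[nm]]
      specs[[nm]] <- new_param_spec(nm, fields, kind)
      provenance[nm] <- if (identical(fields$source, "assumption"))
        "assumption" else "configured"
    }
  }
  missing <- setdiff(.mandatory_params, names(specs))
  if (length(missing) > 0)
    stop("missing mandatory parameter(s): ", paste(missing, collapse = ", "))
  for (nm in names(.hook_defaults)) {
    if (!nm %in% names(specs)) {
      kind <- .param_kind(nm)
      specs[[nm]] <- new_param_spec(nm, .hook_defaults[[nm]], kind)
      provenance[nm] <- "assumption"
    }
  }

  set_cfg <- cfg$settings %||% list()
  settings <- do.call(analysis_settings, set_cfg)

  sched <- modifyList(list(
    rrm_age = 37, rrso_age = 40, hrt_stop_age = 51,
    rrm_disutility_years = 1, rrso_disutility_years = 1,
    chemoprevention_start_age = 30, chemoprevention_duration_years = 5,
    retirement_age = 65,
    screening = list(
      general = list(mammography = list(start = 50, stop = 74, every = 2)),
      carrier = list(mammography = list(start = 40, stop = 69, every = 1),
                     mri = list(start = 30, stop = 49, every = 1))
    )
  ), cfg$schedules %||% list())

  ps <- structure(list(specs = specs, settings = settings, schedules = sched,
                       provenance = provenance), class = "brca_params")
  check_prevalence_mixture(ps)
  ps
}

#' @export
print.brca_params <- function(x, ...) {
  kinds <- vapply(x$specs, function(s) s$kind, character(1))
  cat("<brca_params> ", length(x$specs), " parameters (",
      sum(kinds == "probability"), " probabilities, ",
      sum(kinds == "cost"), " costs, ",
      sum(kinds == "utility"), " utilities)\n", sep = "")
  cat("  ages ", x$settings$start_age, "-", x$settings$horizon_age,
      ", discount ", x$settings$discount_rate * 100, "%/yr",
      ", RRM at ", x$schedules$rrm_age, ", RRSO at ", x$schedules$rrso_age,
      "\n", sep = "")
  assum <- names(x$provenance)[x$provenance == "assumption"]
  if (length(assum)) cat("  assumptions: ", paste(assum, collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_prevalence_mixture <- function(ps, tol = 0.05) {
  p_fh <- parameter_value(ps, "p_fh")
  mix <- p_fh * parameter_value(ps, "prevalence_fh") +
    (1 - p_fh) * parameter_value(ps, "prevalence_no_fh")
  overall <- parameter_value(ps, "prevalence_overall")
  rel <- abs(mix - overall) / overall
  if (rel > tol)
    stop(sprintf(paste0("prevalence mixture inconsistent: FH-conditional mixture ",
                        "%.6f differs from overall prevalence %.6f by %.1f%%"),
                 mix, overall, 100 * rel))
  invisible(mix)
}

#' Get a parameter's current value
#' @param ps A `brca_params` object.
#' @param name Parameter name.
#' @return The parameter's current base value.
#' @export
parameter_value <- function(ps, name) {
  if (!name %in% names(ps$specs)) stop("unknown parameter '", name, "'")
  ps$specs[[name]]$base
}

#' Set a parameter's value (leaves uncertainty metadata untouched)
#' @inheritParams parameter_value
#' @param value New value.
#' @return The modified `brca_params`.
#' @export
set_parameter <- function(ps, name, value) {
  if (!name %in% names(ps$specs)) stop("unknown parameter '", name, "'")
  ps$specs[[name]]$base <- value
  ps
}

param_se <- function(spec) {
  switch(spec$rule,
    fixed = 0,
    ci = (spec$high - spec$low) / 3.92,
    pct10 = 0.10 * spec$base / 1.96,
    pct30 = 0.30 * spec$base / 1.96
  )
}

#' Fit the probabilistic sensitivity analysis distribution of one parameter
#'
#' Converts a parameter's uncertainty statement into a sampling distribution:
#' probabilities get a beta distribution, costs a gamma, utilities a
#' log-normal, each moment-matched so that the distribution mean equals the
#' base value. The standard error derives from the variation rule: for a 95%
#' CI, SE = (high - low) / 3.92; for a +/-10% (+/-30%) rule,
#' SE = 0.10 (0.30) * base / 1.96. A zero SE yields a degenerate point mass.
#' Log-normal utility draws are kept mean-preserving (not truncated); validity
#' of utilities is enforced where they are applied, since composed state
#' utilities are capped at 1 during accrual.
#'
#' @param spec A `param_spec` (one element of `ps$specs`).
#' @return An object of class `psa_dist` with the family, its shape
#'   parameters, and the matched mean and SE.
#' @examples
#' ps <- load_parameters()
#' fit_psa_distribution(ps$specs$uptake_rrso)
#' @export
fit_psa_distribution <- function(spec) {
  if (spec$family == "none" && spec$rule != "fixed")
    stop("parameter '", spec$name, "' has no sampling family")
  m <- spec$base
  se <- param_se(spec)
  if (se == 0 || spec$family == "none") {
    return(structure(list(family = "point", value = m, mean = m, se = 0),
                     class = "psa_dist"))
  }
  d <- switch(spec$family,
    beta = {
      v <- se^2
      mv <- m * (1 - m)
      if (v >= mv)
        stop("beta moment matching infeasible for '", spec$name,
             "': SE^2 >= mean*(1-mean)")
      k <- mv / v - 1
      list(family = "beta", alpha = m * k, beta = (1 - m) * k)
    },
    gamma = list(family = "gamma", shape = (m / se)^2, scale = se^2 / m),
    lognormal = {
      sdlog <- sqrt(log(1 + (se / m)^2))
      list(family = "lognormal", meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    },
    stop("unknown family '", spec$family, "'")
  )
  structure(c(d, list(mean = m, se = se)), class = "psa_dist")
}

psa_dist_mean <- function(d) {
  switch(d$family,
    point = d$value,
    beta = d$alpha / (d$alpha + d$beta),
    gamma = d$shape * d$scale,
    lognormal = exp(d$meanlog + d$sdlog^2 / 2)
  )
}

sample_psa_dist <- function(d, n = 1) {
  switch(d$family,
    point = rep(d$value, n),
    beta = rbeta(n, d$alpha, d$beta),
    gamma = rgamma(n, shape = d$shape, scale = d$scale),
    lognormal = rlnorm(n, d$meanlog, d$sdlog)
  )
}

#' Draw one joint parameter sample for probabilistic sensitivity analysis
#'
#' Every parameter with a sampling family is drawn independently from its
#' fitted distribution; fixed-rule parameters keep their base value. The draw
#' is reproducible given the seed.
#'
#' @param ps A `brca_params` object.
#' @param seed Integer seed for this draw.
#' @return A `brca_params` with `base` values replaced by the sampled values.
#' @export
sample_parameters <- function(ps, seed) {
  set.seed(seed)
  for (nm in names(ps$specs)) {
    spec <- ps$specs[[nm]]
    if (spec$rule == "fixed" || spec$family == "none") next
    d <- fit_psa_distribution(spec)
    ps$specs[[nm]]$base <- sample_psa_dist(d, 1)
  }
  attr(ps, "sampled") <- TRUE
  ps
}

#' Move one parameter to a deterministic sensitivity bound
#'
#' Sets the named parameter to its lower or upper bound according to its
#' variation rule (95% CI bound, or -/+10% or -/+30% of base), leaving all
#' other parameters at base. `direction = "base"` restores the value the
#' parameter had when the set was loaded, so that varying and restoring is an
#' exact round trip.
#'
#' @param ps A `brca_params` object.
#' @param name Parameter name.
#' @param direction `"low"`, `"high"`, or `"base"`.
#' @return The modified `brca_params`.
#' @export
vary_parameter <- function(ps, name, direction = c("low", "high", "base")) {
  direction <- match.arg(direction)
  if (!name %in% names(ps$specs)) stop("unknown parameter '", name, "'")
  spec <- ps$specs[[name]]
  if (direction == "base") {
    ps$specs[[name]]$base <- spec$pristine
    return(ps)
  }
  if (spec$rule == "fixed")
    stop("parameter '", name, "' is fixed and has no variation bounds")
  value <- switch(spec$rule,
    ci = if (direction == "low") spec$low else spec$high,
    pct10 = spec$pristine * (1 + if (direction == "low") -0.10 else 0.10),
    pct30 = spec$pristine * (1 + if (direction == "low") -0.30 else 0.30)
  )
  if (spec$kind %in% c("probability", "utility")) value <- min(max(value, 0), 1)
  ps$specs[[name]]$base <- value
  ps
}

#' Names of all parameters with a non-fixed variation rule
#' @param ps A `brca_params` object.
#' @return Character vector of parameter names usable in one-way sensitivity
#'   analysis.
#' @export
varying_parameters <- function(ps) {
  names(ps$specs)[vapply(ps$specs, function(s) s$rule != "fixed", logical(1))]
}
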