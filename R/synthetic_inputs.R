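# Synthetic age-indexed epidemiology: cancer incidence (general population and
# BRCA1/BRCA2 carriers), a female life table, 5-year survival inputs, and
# earnings/employment inputs for the human-capital productivity module. These
# stand in for registry tables (cancer statistics, national life tables) that
# are not distributed with the package; real tables in the same CSV schema can
# be substituted via read_epi_tables().

# Piecewise-constant age bands in registry publication style. The final open
# band repeats the 71-80 value, matching the model assumption that incidence
# after age 80 is frozen at the 71-80 level.
.age_band_lower <- c(30, 35, 40, 45, 50, 55, 60, 65, 71, 81)

.band_values <- function(ages, values) {
  idx <- findInterval(ages, .age_band_lower)
  values[idx]
}

# Annual incidence shapes (probability/year) per band:
# general-population curves rise smoothly with age; carrier curves follow the
# published penetrance pattern - a steep rise through the 30s, a plateau
# through midlife for BC, and an ovarian-cancer curve that takes off after 40.
.shape_bc_general <- c(0.0003, 0.0006, 0.0013, 0.0019, 0.0023, 0.0027,
                       0.0032, 0.0037, 0.0041, 0.0041)
.shape_oc_general <- c(0.00004, 0.00007, 0.00011, 0.00015, 0.00019, 0.00023,
                       0.00027, 0.00030, 0.00033, 0.00033)
.shape_bc_carrier <- c(0.009, 0.016, 0.024, 0.026, 0.024, 0.022,
                       0.020, 0.018, 0.015, 0.015)
.shape_oc_carrier <- c(0.001, 0.002, 0.005, 0.009, 0.011, 0.011,
                       0.009, 0.007, 0.005, 0.005)

# Cumulative-risk calibration targets for combined BRCA1/BRCA2 carriers,
# ages 30-80 (midpoints of the published lifetime-risk bands 61-72% for BC
# and 17-48% for OC).
.carrier_targets <- c(bc = 0.665, oc = 0.325)

#' Cumulative risk implied by a vector of annual probabilities
#'
#' Crude cumulative incidence 1 - prod(1 - p) over the given ages, ignoring
#' competing mortality (the convention used for published penetrance figures).
#'
#' @param p Annual probabilities.
#' @return Cumulative probability.
#' @export
cumulative_risk <- function(p) 1 - prod(1 - p)

.calibrate_curve <- function(shape_ages, target) {
  f <- function(scale) cumulative_risk(pmin(scale * shape_ages, 0.999)) - target
  uniroot(f, c(1e-6, 20), tol = 1e-12)$root
}

#' Generate the age-indexed epidemiological inputs
#'
#' Builds the four input tables the Markov model consumes: an incidence table
#' (annual breast and ovarian cancer probabilities for the general population
#' and for BRCA1/BRCA2 carriers, ages 30 to the horizon), a female life table
#' (annual all-cause mortality), survival inputs (5-year survival by cancer
#' and stage, stage split at diagnosis, annual recurrence probabilities), and
#' productivity inputs (earnings and employment by age, retirement age,
#' temporary-absence and permanent-reduction fractions).
#'
#' The `"canada_like"` preset calibrates the carrier incidence curves so that
#' cumulative carrier risk from age 30 to 80 lands at the midpoint of the
#' published lifetime-risk bands (61-72% breast, 17-48% ovarian). The
#' `"null_risk"` preset zeroes all cancer incidence, which makes the two
#' testing strategies' health outcomes identical downstream and is used for
#' degeneracy checks. Output is deterministic; the seed is accepted for
#' interface stability and reserved for future stochastic perturbation
#' profiles.
#'
#' @param seed Integer seed.
#' @param profile `"canada_like"` (default) or `"null_risk"`.
#' @param max_age Last age (years) the tables must cover.
#' @return An object of class `brca_epi`: list with `incidence` (data.frame
#'   age, bc_general, bc_carrier, oc_general, oc_carrier), `life` (data.frame
#'   age, qx), `survival` (list), `productivity` (list with `table`
#'   data.frame age, earnings, employment plus scalar settings) and `profile`.
#' @examples
#' epi <- generate_inputs(seed = 1)
#' head(epi$incidence)
#' @export
generate_inputs <- function(seed = 1L, profile = c("canada_like", "null_risk"),
                            max_age = 83L) {
  profile <- match.arg(profile)
  ages <- 30:max_age

  if (profile == "canada_like") {
    bc_gen <- .band_values(ages, .shape_bc_general)
    oc_gen <- .band_values(ages, .shape_oc_general)
    ages_cal <- 30:80
    sc_bc <- .calibrate_curve(.band_values(ages_cal, .shape_bc_carrier),
                              .carrier_targets["bc"])
    sc_oc <- .calibrate_curve(.band_values(ages_cal, .shape_oc_carrier),
                              .carrier_targets["oc"])
    bc_car <- pmax(sc_bc * .band_values(ages, .shape_bc_carrier), bc_gen)
    oc_car <- pmax(sc_oc * .band_values(ages, .shape_oc_carrier), oc_gen)
  } else {
    bc_gen <- oc_gen <- bc_car <- oc_car <- rep(0, length(ages))
  }

  incidence <- data.frame(age = ages, bc_general = bc_gen, bc_carrier = bc_car,
                          oc_general = oc_gen, oc_carrier = oc_car)

  # Gompertz-style female all-cause mortality, increasing with age.
  life <- data.frame(age = ages, qx = 0.00035 * exp(0.082 * (ages - 30)))

  survival <- list(
    five_year_survival = list(
      BC = list(overall = 0.88, early = 0.95),
      OC = list(overall = 0.44, early = 0.85)
    ),
    stage_split_early = c(BC = 0.70, OC = 0.30),
    annual_recurrence = c(BC = 0.015, OC = 0.040)
  )
  survival <- .complete_survival(survival)

  retirement_age <- 65
  productivity <- list(
    table = data.frame(
      age = ages,
      earnings = ifelse(ages < retirement_age, 52000, 0),
      employment = ifelse(ages < 55, 0.82,
                   ifelse(ages < 60, 0.70,
                   ifelse(ages < retirement_age, 0.50, 0)))
    ),
    retirement_age = retirement_age,
    temporary_absence_years = 0.5,
    temporary_fraction_affected = 0.9,
    permanent_reduction_fraction = 0.07
  )

  structure(list(incidence = incidence, life = life, survival = survival,
                 productivity = productivity, profile = profile, seed = seed),
            class = "brca_epi")
}

# Fill in the advanced-stage 5-year survival so that the early/advanced
# mixture reproduces the overall figure, and derive the annual
# cancer-specific death probabilities used by the Markov engine.
.complete_survival <- function(sv) {
  for (cc in c("BC", "OC")) {
    s <- sv$five_year_survival[[cc]]
    split <- sv$stage_split_early[[cc]]
    if (is.null(s$advanced)) {
      s$advanced <- (s$overall - split * s$early) / (1 - split)
    }
    if (s$advanced < 0 || s$advanced > 1)
      stop("derived advanced-stage 5-year survival for ", cc, " outside [0, 1]")
    sv$five_year_survival[[cc]] <- s
    sv$annual_death[[cc]] <- c(early = survival_to_annual(s$early),
                               advanced = survival_to_annual(s$advanced))
  }
  sv
}

#' Convert a 5-year survival probability to an annual death probability
#'
#' Assumes a constant annual survival over the five post-diagnosis years, so
#' the annual cancer-specific death probability is 1 - S5^(1/5). The engine
#' applies it during the five post-diagnosis cycles only; afterwards women in
#' remission face background mortality alone.
#'
#' @param prob_5yr Five-year survival probability in [0, 1].
#' @return Annual probability of cancer-specific death.
#' @examples
#' survival_to_annual(0.5) # 1 - 0.5^(1/5)
#' @export
survival_to_annual <- function(prob_5yr) {
  stopifnot(all(prob_5yr >= 0 & prob_5yr <= 1))
  1 - prob_5yr^(1 / 5)
}

#' @export
print.brca_epi <- function(x, ...) {
  ages <- x$incidence$age
  cal <- x$incidence$age <= 80
  cat("<brca_epi> profile '", x$profile, "', ages ", min(ages), "-", max(ages),
      "\n", sep = "")
  cat(sprintf("  cumulative carrier risk 30-80: BC %.3f, OC %.3f\n",
              cumulative_risk(x$incidence$bc_carrier[cal]),
              cumulative_risk(x$incidence$oc_carrier[cal])))
  cat(sprintf("  5-year survival: BC %.2f, OC %.2f\n",
              x$survival$five_year_survival$BC$overall,
              x$survival$five_year_survival$OC$overall))
  invisible(x)
}

#' Write the epidemiological input tables as CSV files
#'
#' Serializes the four tables to `incidence.csv` (age, bc_general,
#' bc_carrier, oc_general, oc_carrier), `life_table.csv` (age, qx),
#' `survival.csv` (key, value pairs) and `productivity.csv` (age, earnings,
#' employment) plus `productivity_settings.csv` (key, value pairs) in `dir`.
#' Users can edit these files (or substitute registry data in the same
#' schema) and reload them with [read_epi_tables()].
#'
#' @param epi A `brca_epi` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_epi_tables <- function(epi, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("incidence.csv", "life_table.csv", "survival.csv",
                            "productivity.csv", "productivity_settings.csv"))
  write.csv(epi$incidence, paths[1], row.names = FALSE)
  write.csv(epi$life, paths[2], row.names = FALSE)
  sv <- epi$survival
  sv_kv <- data.frame(
    key = c("bc_5yr_overall", "bc_5yr_early", "bc_5yr_advanced",
            "oc_5yr_overall", "oc_5yr_early", "oc_5yr_advanced",
            "bc_stage_split_early", "oc_stage_split_early",
            "bc_annual_recurrence", "oc_annual_recurrence"),
    value = c(sv$five_year_survival$BC$overall, sv$five_year_survival$BC$early,
              sv$five_year_survival$BC$advanced,
              sv$five_year_survival$OC$overall, sv$five_year_survival$OC$early,
              sv$five_year_survival$OC$advanced,
              sv$stage_split_early[["BC"]], sv$stage_split_early[["OC"]],
              sv$annual_recurrence[["BC"]], sv$annual_recurrence[["OC"]])
  )
  write.csv(sv_kv, paths[3], row.names = FALSE)
  write.csv(epi$productivity$table, paths[4], row.names = FALSE)
  pr_kv <- data.frame(
    key = c("retirement_age", "temporary_absence_years",
            "temporary_fraction_affected", "permanent_reduction_fraction"),
    value = c(epi$productivity$retirement_age,
              epi$productivity$temporary_absence_years,
              epi$productivity$temporary_fraction_affected,
              epi$productivity$permanent_reduction_fraction)
  )
  write.csv(pr_kv, paths[5], row.names = FALSE)
  invisible(paths)
}

#' Read epidemiological input tables from CSV files
#'
#' Counterpart of [write_epi_tables()]: loads the documented CSV schema from
#' `dir`, validates the structural invariants the model assumes (probabilities
#' in range, carrier incidence at least the general-population incidence at
#' every age) and returns a `brca_epi` usable everywhere a generated one is.
#'
#' @param dir Directory containing the five CSV files.
#' @return A `brca_epi` object with profile `"user_supplied"`.
#' @export
read_epi_tables <- function(dir) {
  inc <- read.csv(file.path(dir, "incidence.csv"))
  need <- c("age", "bc_general", "bc_carrier", "oc_general", "oc_carrier")
  if (!all(need %in% names(inc)))
    stop("incidence.csv must have columns: ", paste(need, collapse = ", "))
  life <- read.csv(file.path(dir, "life_table.csv"))
  if (!all(c("age", "qx") %in% names(life)))
    stop("life_table.csv must have columns: age, qx")
  sv_kv <- read.csv(file.path(dir, "survival.csv"))
  kv <- setNames(sv_kv$value, sv_kv$key)
  survival <- .complete_survival(list(
    five_year_survival = list(
      BC = list(overall = kv[["bc_5yr_overall"]], early = kv[["bc_5yr_early"]],
                advanced = kv[["bc_5yr_advanced"]]),
      OC = list(overall = kv[["oc_5yr_overall"]], early = kv[["oc_5yr_early"]],
                advanced = kv[["oc_5yr_advanced"]])
    ),
    stage_split_early = c(BC = kv[["bc_stage_split_early"]],
                          OC = kv[["oc_stage_split_early"]]),
    annual_recurrence = c(BC = kv[["bc_annual_recurrence"]],
                          OC = kv[["oc_annual_recurrence"]])
  ))
  prod_tab <- read.csv(file.path(dir, "productivity.csv"))
  pr_kv <- read.csv(file.path(dir, "productivity_settings.csv"))
  pv <- setNames(pr_kv$value, pr_kv$key)
  productivity <- list(
    table = prod_tab,
    retirement_age = pv[["retirement_age"]],
    temporary_absence_years = pv[["temporary_absence_years"]],
    temporary_fraction_affected = pv[["temporary_fraction_affected"]],
    permanent_reduction_fraction = pv[["permanent_reduction_fraction"]]
  )
  epi <- structure(list(incidence = inc, life = life, survival = survival,
                        productivity = productivity, profile = "user_supplied",
                        seed = NA_integer_), class = "brca_epi")
  validate_epi(epi)
  epi
}

validate_epi <- function(epi) {
  inc <- epi$incidence
  probs <- as.matrix(inc[, c("bc_general", "bc_carrier", "oc_general", "oc_carrier")])
  if (any(probs < 0 | probs >= 1))
    stop("incidence probabilities must lie in [0, 1)")
  if (any(inc$bc_carrier < inc$bc_general) || any(inc$oc_carrier < inc$oc_general))
    stop("carrier incidence must be >= general-population incidence at every age")
  if (any(epi$life$qx < 0 | epi$life$qx > 1))
    stop("life-table mortality must lie in [0, 1]")
  if (epi$productivity$retirement_age > max(epi$life$age) + 1)
    stop("retirement age beyond the horizon of the tables")
  invisible(epi)
}

# Age-indexed lookups (ages outside the table clamp to its edges; incidence
# beyond the last tabulated age is already frozen at the 71-80 band value).
.lookup <- function(tab, col, ages) {
  idx <- pmin(pmax(ages - tab$age[1] + 1, 1), nrow(tab))
  tab[[col]][idx]
}
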