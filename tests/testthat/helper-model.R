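# Shared fixtures, built once per test run. All inputs are generated in code;
# nothing is read from disk except the packaged default configuration.

.fixtures <- new.env()

base_params <- function() {
  if (is.null(.fixtures$ps)) .fixtures$ps <- load_parameters()
  .fixtures$ps
}

base_epi <- function() {
  if (is.null(.fixtures$epi)) .fixtures$epi <- generate_inputs(seed = 1)
  .fixtures$epi
}

null_epi <- function() {
  if (is.null(.fixtures$null)) .fixtures$null <-
      generate_inputs(seed = 1, profile = "null_risk")
  .fixtures$null
}

base_comparison <- function() {
  if (is.null(.fixtures$cmp)) .fixtures$cmp <-
      compare_strategies(base_params(), base_epi())
  .fixtures$cmp
}

# a detected-carrier row and a rich intervention profile, used across tests
detected_carrier_sub <- function(strategy = "population") {
  subs <- enumerate_subgroups(strategy, base_params())
  subs[subs$carrier & subs$result == "pv" & !subs$fh, , drop = FALSE]
}

profile_row <- function(rrm = FALSE, rrso = FALSE, chemo = FALSE, hrt = FALSE,
                        screening = if (rrm || rrso) "carrier" else "general") {
  data.frame(rrm = rrm, rrso = rrso, chemo = chemo, hrt = hrt,
             screening = screening, prob = 1)
}

# parameter set with every distribution collapsed to a point mass
fixed_params <- function(ps = base_params()) {
  for (nm in names(ps$specs)) {
    ps$specs[[nm]]$rule <- "fixed"
    ps$specs[[nm]]$family <- "none"
  }
  ps
}

# parameter set with every utility (including surgery multipliers) set to 1
unit_utility_params <- function(ps = base_params()) {
  for (nm in names(ps$specs)) {
    if (ps$specs[[nm]]$kind == "utility") {
      ps$specs[[nm]]$base <- 1
      ps$specs[[nm]]$low <- NULL
      ps$specs[[nm]]$high <- NULL
      ps$specs[[nm]]$rule <- "fixed"
      ps$specs[[nm]]$family <- "none"
    }
  }
  ps
}

# strategy-neutral parameter set: no testing/counselling/surveillance costs,
# no intervention uptake (detected carriers still receive intensified
# surveillance, so its unit costs must be zeroed for arms to coincide)
neutralized_params <- function(ps = base_params()) {
  for (nm in c("cost_genetic_testing", "cost_genetic_counselling",
               "cost_mammography", "cost_mri"))
    ps <- set_parameter(ps, nm, 0)
  for (nm in c("uptake_rrm", "uptake_rrso", "uptake_chemoprevention"))
    ps <- set_parameter(ps, nm, 0)
  ps
}

# independent discounted life expectancy from the life table alone
life_table_expectancy <- function(epi, settings) {
  ages <- settings$start_age:(settings$horizon_age - 1)
  idx <- match(ages, epi$life$age)
  q <- epi$life$qx[idx]
  surv <- cumprod(c(1, 1 - q))[seq_along(ages)]  # alive at start of cycle
  disc <- (1 + settings$discount_rate)^-(seq_along(ages) - 1)
  sum(surv * disc)
}
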