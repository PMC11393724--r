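test_that("competing-risk combination matches the closed form", {
  expect_equal(combine_competing_risks(0.02), 0.02)
  two <- combine_competing_risks(c(0.02, 0.02))
  expect_equal(sum(two), 1 - exp(2 * log(1 - 0.02)), tolerance = 1e-12)
  # combined probability is 1 - 0.98^2 = 0.0396 exactly, split equally
  expect_equal(two, c(0.0198, 0.0198), tolerance = 1e-12)
  expect_equal(combine_competing_risks(c(0, 0.5)), c(0, 0.5))
  # a certain cause takes the whole cycle
  expect_equal(combine_competing_risks(c(0.3, 1)), c(0, 1))

  # total allocated probability always equals 1 - prod(1 - p)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(2:5, 1), 0, 0.9)
    expect_equal(sum(combine_competing_risks(p)), 1 - prod(1 - p),
                 tolerance = 1e-12)
  }
})

test_that("transition matrices are row-stochastic with absorbing death states", {
  ps <- base_params()
  epi <- base_epi()
  sub <- detected_carrier_sub()
  for (prof in list(profile_row(), profile_row(rrm = TRUE, rrso = TRUE, hrt = TRUE),
                    profile_row(rrso = TRUE, chemo = TRUE))) {
    A <- build_matrices(TRUE, hazard_modifiers(prof, ps), ps, epi)
    flat <- matrix(A, prod(dim(A)[1:2]), dim(A)[3])
    expect_true(all(abs(rowSums(flat) - 1) < 1e-12))
    expect_true(all(flat >= 0 & flat <= 1))
  }
  M <- build_matrix(45, sub, profile_row(rrso = TRUE), ps, epi)
  for (d in c("DeathBC", "DeathOC", "DeathCHD", "DeathOther"))
    expect_equal(unname(M[d, d]), 1)
  # no BC/OC co-occurrence: no path from a BC state into an OC state
  bc_states <- grep("^BC_", rownames(M), value = TRUE)
  oc_states <- grep("^OC_", rownames(M), value = TRUE)
  expect_true(all(M[bc_states, oc_states] == 0))
  expect_true(all(M[oc_states, bc_states] == 0))
  expect_error(build_matrix(20, sub, profile_row(), ps, epi), "age")
})

test_that("with zero incidence the Well row reduces to the life table", {
  ps <- base_params()
  epi <- null_epi()
  sub <- enumerate_subgroups("population", ps)[3, ]  # a non-carrier leaf
  M <- build_matrix(30, sub, profile_row(), ps, epi)
  q <- epi$life$qx[epi$life$age == 30]
  expect_equal(unname(M["Well", "Well"]), 1 - q, tolerance = 1e-12)
  expect_equal(unname(M["Well", "DeathOther"]), q, tolerance = 1e-12)
  expect_true(all(M["Well", setdiff(colnames(M), c("Well", "DeathOther"))] == 0))
})

test_that("fatal excess CHD risk enters as the product of excess and fatality", {
  ps <- base_params()
  M <- build_matrix(45, detected_carrier_sub(), profile_row(rrso = TRUE),
                    base_params(), base_epi())
  raw <- 0.0072 * 0.0303
  got <- unname(M["Well", "DeathCHD"])
  expect_lte(got, raw)                 # competing risks shave it slightly
  expect_equal(got, raw, tolerance = 0.01)
})

test_that("discounting follows value / (1 + r)^cycle", {
  expect_equal(discount(100, 0, 0.015), 100)
  expect_equal(discount(100, 2, 0.015), 97.066175, tolerance = 1e-6)
  expect_equal(discount(100, 2, 0.015), 100 / (1.015 * 1.015), tolerance = 1e-12)
  expect_equal(discount(100, 7, 0), 100)
  expect_error(discount(100, 1, -0.01))
})

test_that("cohort propagation conserves occupancy and counts events coherently", {
  ps <- base_params()
  trace <- run_cohort(detected_carrier_sub(), profile_row(rrso = TRUE, hrt = TRUE),
                      ps, base_epi())
  expect_true(all(abs(rowSums(trace$occupancy) - 1) < 1e-9))
  expect_true(all(unlist(trace$flows) >= -1e-15))
  # deaths accumulate into absorbing states
  n <- nrow(trace$occupancy)
  expect_equal(sum(trace$flows$death_bc), unname(trace$occupancy[n, "DeathBC"]),
               tolerance = 1e-12)
  # public aggregation preserves mass
  pub <- public_occupancy(trace)
  expect_equal(rowSums(pub), rowSums(trace$occupancy), tolerance = 1e-12)
})

test_that("null-risk cohorts reduce exactly to the discounted life table", {
  ps <- base_params()
  epi <- null_epi()
  sub <- enumerate_subgroups("population", ps)[3, ]
  trace <- run_cohort(sub, profile_row(), ps, epi)
  rules <- accrual_rules(sub, profile_row(), ps, epi)
  out <- accrue(trace, rules, ps, epi)
  expect_equal(out$payer$ly, life_table_expectancy(epi, ps$settings),
               tolerance = 1e-10)
  expect_equal(unname(out$events), rep(0, 5))
})

test_that("unit utilities make QALYs equal life-years exactly", {
  ps <- unit_utility_params()
  epi <- base_epi()
  sub <- detected_carrier_sub()
  prof <- profile_row(rrm = TRUE, rrso = TRUE, hrt = TRUE)
  trace <- run_cohort(sub, prof, ps, epi)
  out <- accrue(trace, accrual_rules(sub, prof, ps, epi), ps, epi)
  expect_identical(out$payer$qaly, out$payer$ly)
  expect_identical(out$payer$qaly_undiscounted, out$payer$ly_undiscounted)
})

test_that("zero discount rate makes discounted and undiscounted totals identical", {
  ps <- base_params()
  ps$settings$discount_rate <- 0
  sub <- detected_carrier_sub()
  prof <- profile_row(rrso = TRUE)
  trace <- run_cohort(sub, prof, ps, base_epi())
  out <- accrue(trace, accrual_rules(sub, prof, ps, base_epi()), ps, base_epi())
  expect_identical(out$payer$cost, out$payer$cost_undiscounted)
  expect_identical(out$payer$qaly, out$payer$qaly_undiscounted)
  expect_identical(out$societal$cost, out$societal$cost_undiscounted)
})

test_that("discounted accumulators never exceed undiscounted ones", {
  out <- accrue(
    run_cohort(detected_carrier_sub(), profile_row(rrso = TRUE),
               base_params(), base_epi()),
    accrual_rules(detected_carrier_sub(), profile_row(rrso = TRUE),
                  base_params(), base_epi()),
    base_params(), base_epi())
  expect_lte(out$payer$cost, out$payer$cost_undiscounted)
  expect_lte(out$payer$qaly, out$payer$qaly_undiscounted)
  expect_lte(out$societal$cost, out$societal$cost_undiscounted)
})

test_that("surgery utility multipliers compose multiplicatively on Well years", {
  ps <- base_params()
  ps$schedules$rrm_age <- 40   # align both surgeries so the windows overlap
  ps$schedules$rrso_age <- 40
  rules <- accrual_rules(detected_carrier_sub(),
                         profile_row(rrm = TRUE, rrso = TRUE), ps, base_epi())
  row40 <- which(rules$ages == 40)
  expect_equal(unname(rules$utilities[row40, "Well"]), 0.88 * 0.95,
               tolerance = 1e-12)
  expect_equal(unname(rules$utilities[row40 - 1, "Well"]), 1)
})

test_that("halving all cancer incidence never decreases discounted QALYs", {
  ps <- base_params()
  epi <- base_epi()
  epi_half <- epi
  epi_half$incidence[, -1] <- epi$incidence[, -1] / 2
  for (strategy in c("population", "fh_based")) {
    full <- run_strategy(strategy, ps, epi)
    half <- run_strategy(strategy, ps, epi_half)
    expect_gte(half$payer$qaly, full$payer$qaly)
  }
})
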