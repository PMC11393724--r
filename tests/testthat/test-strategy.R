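test_that("subgroup enumeration is an exhaustive partition with consistent biology", {
  ps <- base_params()
  pop <- enumerate_subgroups("population", ps)
  fhb <- enumerate_subgroups("fh_based", ps)
  expect_equal(sum(pop$weight), 1, tolerance = 1e-12)
  expect_equal(sum(fhb$weight), 1, tolerance = 1e-12)

  # testing cannot change biology: carrier mass identical across strategies
  carrier_pop <- sum(pop$weight[pop$carrier])
  carrier_fhb <- sum(fhb$weight[fhb$carrier])
  expect_equal(carrier_pop, carrier_fhb, tolerance = 1e-15)
  expect_lt(abs(carrier_pop - 0.0067) / 0.0067, 0.01)

  # structural implications
  expect_true(all(pop$tested[pop$detected]))
  expect_true(all(fhb$fh[fhb$tested]))

  # detected carriers: population tests everyone, FH-based only the FH stratum
  sens <- parameter_value(ps, "test_sensitivity")
  expect_equal(sum(pop$weight[pop$carrier & pop$detected]),
               0.00672316 * sens, tolerance = 1e-12)
  expect_equal(sum(fhb$weight[fhb$carrier & fhb$detected]),
               0.0098 * 0.1 * sens, tolerance = 1e-12)
  expect_equal(sum(fhb$weight[fhb$carrier & !fhb$detected]),
               (1 - 0.0098) * 0.0058 + 0.0098 * 0.1 * (1 - sens),
               tolerance = 1e-12)
})

test_that("intervention uptake splits follow independent published rates", {
  ps <- base_params()
  sub <- detected_carrier_sub()
  prof <- assign_interventions(sub, ps)
  expect_equal(sum(prof$prob), 1, tolerance = 1e-12)
  expect_equal(sum(prof$prob[prof$rrm & prof$rrso]), 0.359 * 0.628,
               tolerance = 1e-12)
  expect_equal(sum(prof$prob[prof$hrt]) / sum(prof$prob[prof$rrso]), 0.8,
               tolerance = 1e-12)
  expect_true(all(prof$rrso[prof$hrt]))  # hrt implies rrso

  # non-detected women get exactly one profile: general screening, no surgery
  undet <- data.frame(strategy = "population", fh = FALSE, carrier = TRUE,
                      tested = TRUE, result = "neg", detected = FALSE,
                      vus = FALSE, weight = 1)
  p0 <- assign_interventions(undet, ps)
  expect_equal(nrow(p0), 1)
  expect_false(any(p0$rrm, p0$rrso, p0$chemo, p0$hrt))
  expect_equal(p0$screening, "general")
})

test_that("hazard modifiers reproduce the published risk reductions", {
  ps <- base_params()
  ages <- 30:60
  mv_none <- modifier_vectors(hazard_modifiers(profile_row(), ps), ages)
  expect_true(all(mv_none$bc == 1) && all(mv_none$oc == 1) &&
                all(mv_none$chd_fatal == 0))

  both <- modifier_vectors(hazard_modifiers(profile_row(rrm = TRUE, rrso = TRUE), ps), ages)
  expect_equal(both$bc[ages == 35], 1)        # before any surgery
  expect_equal(both$bc[ages == 38], 0.09)     # RRM alone (age 37-39)
  expect_equal(both$bc[ages == 45], 0.05)     # RRM + RRSO
  expect_equal(both$oc[ages == 45], 1 - 0.96)

  rrso_only <- modifier_vectors(hazard_modifiers(profile_row(rrso = TRUE), ps), ages)
  expect_equal(rrso_only$bc[ages == 45], 0.49)
  expect_equal(rrso_only$chd_fatal[ages == 45], 0.0072 * 0.0303)
  expect_equal(rrso_only$chd_fatal[ages == 51], 0)   # window closes at 51
  expect_equal(rrso_only$chd_fatal[ages == 39], 0)   # not before RRSO

  hrt <- modifier_vectors(hazard_modifiers(profile_row(rrso = TRUE, hrt = TRUE), ps), ages)
  expect_true(all(hrt$chd_fatal == 0))

  chemo <- modifier_vectors(hazard_modifiers(
    profile_row(rrso = TRUE, chemo = TRUE), ps), ages)
  expect_equal(chemo$bc[ages == 32], 0.71)          # chemoprevention window
  expect_equal(chemo$bc[ages == 45], 0.49)          # window over, RRSO only

  # adding interventions never increases the BC multiplier
  at45 <- function(p) modifier_vectors(hazard_modifiers(p, ps), 45)$bc
  expect_true(at45(profile_row(rrm = TRUE, rrso = TRUE)) <=
                at45(profile_row(rrm = TRUE)))
  expect_true(at45(profile_row(rrm = TRUE)) <= at45(profile_row()))
})

test_that("dated cost events follow the pathway and the half-open age conventions", {
  ps <- base_params()
  pop <- enumerate_subgroups("population", ps)

  neg <- pop[!pop$carrier & pop$result == "neg" & !pop$fh, ][1, ]
  ev <- upfront_costs(neg, profile_row(), ps)
  entry <- ev[ev$age == 30 & ev$weight_by == "cohort", ]
  expect_setequal(entry$item, c("genetic_test", "pretest_counselling"))
  expect_equal(sum(entry$amount), 220 + 167)

  vus <- pop[pop$vus & !pop$fh, ][1, ]
  ev_vus <- upfront_costs(vus, profile_row(), ps)
  expect_true("posttest_counselling" %in% ev_vus$item)

  fhb <- enumerate_subgroups("fh_based", base_params())
  untested <- fhb[!fhb$tested & !fhb$carrier, ][1, ]
  ev_un <- upfront_costs(untested, profile_row(), ps)
  expect_false(any(grepl("test|counselling", ev_un$item)))

  # HRT runs from RRSO age until (not including) age 51: ages 40-50, 11 years
  det <- detected_carrier_sub()
  ev_hrt <- upfront_costs(det, profile_row(rrso = TRUE, hrt = TRUE), ps)
  hrt_rows <- ev_hrt[ev_hrt$item == "hrt", ]
  expect_equal(hrt_rows$age, 40:50)
  expect_true(all(hrt_rows$amount == 680))

  # carriers who undergo RRM screen as carriers only until the RRM age
  ev_rrm <- upfront_costs(det, profile_row(rrm = TRUE), ps)
  mri <- ev_rrm[ev_rrm$item == "mri", ]
  expect_equal(mri$age, 30:36)
  expect_false(any(ev_rrm$item == "mammography"))  # carrier mammography starts at 40

  # without RRM the full carrier schedule applies (MRI 30-49, mammography 40-69)
  ev_scr <- upfront_costs(det, profile_row(rrso = TRUE), ps)
  expect_equal(ev_scr[ev_scr$item == "mri", "age"], 30:49)
  expect_equal(ev_scr[ev_scr$item == "mammography", "age"], 40:69)

  # general screening: biennial mammography 50-74
  expect_equal(ev[ev$item == "mammography", "age"], seq(50, 74, 2))
})
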