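test_that("packaged configuration loads, validates, and satisfies the prevalence mixture", {
  ps <- base_params()
  expect_s3_class(ps, "brca_params")
  expect_true(all(c("prevalence_overall", "uptake_rrso", "cost_rrm",
                    "utility_bc_early") %in% names(ps$specs)))
  p_fh <- parameter_value(ps, "p_fh")
  mix <- p_fh * parameter_value(ps, "prevalence_fh") +
    (1 - p_fh) * parameter_value(ps, "prevalence_no_fh")
  expect_equal(mix, 0.00672316, tolerance = 1e-12)
  expect_lt(abs(mix - parameter_value(ps, "prevalence_overall")) /
              parameter_value(ps, "prevalence_overall"), 0.01)
  # hooks the published table leaves open are flagged as assumptions
  expect_equal(unname(ps$provenance[["vus_probability"]]), "assumption")
})

test_that("invalid configurations are rejected with named errors", {
  cfg <- yaml::read_yaml(system.file("extdata", "default_params.yaml",
                                     package = "brcacea"))
  cfg_missing <- cfg
  cfg_missing$costs$cost_rrm <- NULL
  expect_error(load_parameters(cfg_missing), "cost_rrm")

  cfg_bad <- cfg
  cfg_bad$utilities$utility_bc_early$base <- 1.2
  expect_error(load_parameters(cfg_bad), "utility_bc_early")

  cfg_order <- cfg
  cfg_order$probabilities$uptake_rrso$low <- 0.9
  expect_error(load_parameters(cfg_order), "low <= base <= high")

  cfg_mix <- cfg
  cfg_mix$probabilities$prevalence_no_fh$base <- 0.002
  cfg_mix$probabilities$prevalence_no_fh$low <- 0.001
  expect_error(load_parameters(cfg_mix), "mixture")

  expect_error(analysis_settings(discount_rate = 1.5), "discount_rate")
  expect_error(analysis_settings(start_age = 90, horizon_age = 83), "start_age")
})

test_that("PSA distributions are moment-matched to the base value", {
  ps <- base_params()
  d <- fit_psa_distribution(ps$specs$uptake_rrso)
  expect_equal(d$family, "beta")
  expect_equal(d$alpha, 34.872403, tolerance = 1e-6)
  expect_equal(d$beta, 20.656901, tolerance = 1e-6)

  g <- fit_psa_distribution(ps$specs$cost_genetic_testing)
  expect_equal(g$family, "gamma")
  expect_equal(g$shape, 42.684444, tolerance = 1e-6)
  expect_equal(g$scale, 5.154102, tolerance = 1e-6)

  # every fitted distribution reproduces its base value as its mean
  for (nm in varying_parameters(ps)) {
    di <- fit_psa_distribution(ps$specs[[nm]])
    expect_equal(brcacea:::psa_dist_mean(di), ps$specs[[nm]]$base,
                 tolerance = 1e-9, label = nm)
  }

  # fixed parameters collapse to a point mass
  pm <- fit_psa_distribution(ps$specs$test_sensitivity)
  expect_equal(pm$family, "point")
  expect_identical(sample_psa_dist <- brcacea:::sample_psa_dist(pm, 3),
                   rep(0.9995, 3))

  # infeasible beta moment matching is an error, not a silent fallback
  bad <- ps$specs$prevalence_overall
  bad$low <- 0; bad$high <- 1
  expect_error(fit_psa_distribution(bad), "infeasible")
})

test_that("joint sampling is reproducible, in-range, and mean-consistent", {
  ps <- base_params()
  s1 <- sample_parameters(ps, seed = 42)
  s2 <- sample_parameters(ps, seed = 42)
  expect_identical(s1, s2)
  expect_false(identical(
    parameter_value(sample_parameters(ps, 1), "uptake_rrso"),
    parameter_value(sample_parameters(ps, 2), "uptake_rrso")))
  # fixed parameters never move
  expect_identical(parameter_value(s1, "test_sensitivity"), 0.9995)

  d <- fit_psa_distribution(ps$specs$uptake_rrso)
  set.seed(99)
  draws <- brcacea:::sample_psa_dist(d, 5000)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.628), 3 * d$se / sqrt(5000))
})

test_that("one-way variation hits the documented bounds and round-trips", {
  ps <- base_params()
  expect_equal(parameter_value(
    vary_parameter(ps, "cost_genetic_testing", "high"), "cost_genetic_testing"),
    286)
  expect_equal(parameter_value(
    vary_parameter(ps, "utility_bc_early", "low"), "utility_bc_early"),
    0.639)
  expect_equal(parameter_value(
    vary_parameter(ps, "hr_bc_rrso", "high"), "hr_bc_rrso"), 0.65)

  varied <- vary_parameter(ps, "uptake_rrm", "low")
  expect_identical(vary_parameter(varied, "uptake_rrm", "base"), ps)

  expect_error(vary_parameter(ps, "not_a_parameter", "low"), "unknown parameter")
  expect_error(vary_parameter(ps, "test_sensitivity", "high"), "fixed")
})
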