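test_that("baseline fixture carries the published Singapore inputs", {
  ps <- baseline_parameters()
  expect_silent(validate_parameters(ps))

  band <- ps$asir[ps$asir$age_low == 50, ]
  expect_equal(band$age_high, 54L)
  expect_equal(band$rate, 0.001775)
  expect_equal(asir_lookup(ps, 37), 0.000617)
  expect_equal(asir_lookup(ps, 74), 0.002063)

  expect_equal(ps$stage_dist$screened, c(0.53, 0.43, 0.03, 0.01))
  expect_equal(sum(ps$stage_dist$screened), 1)
  expect_equal(sum(ps$stage_dist$unscreened), 1)
  expect_equal(ps$strat$proportion, c(0.51, 0.41, 0.08))
  expect_equal(sum(ps$strat$proportion), 1)
  expect_equal(ps$strat$multiplier, c(0.5, 1, 2))
  expect_equal(ps$all_cause_mortality, 0.002896)
  expect_equal(ps$stage_costs$cost[1], 63983)
  expect_equal(ps$config$discount_rate, 0.03)
  expect_equal(ps$config$mammography_sensitivity, 0.8)
})

test_that("asir lookup is piecewise-constant within bands and range-checked", {
  ps <- baseline_parameters()
  expect_equal(asir_lookup(ps, 50:54), rep(0.001775, 5))
  for (b in seq_len(nrow(ps$asir))) {
    ages <- seq(ps$asir$age_low[b], min(ps$asir$age_high[b], 110))
    expect_equal(asir_lookup(ps, ages), rep(ps$asir$rate[b], length(ages)))
  }
  expect_error(asir_lookup(ps, 20), class = "screencea_range_error")
  expect_error(asir_lookup(ps, 130), class = "screencea_range_error")
})

test_that("validation names the violated invariant", {
  ps <- baseline_parameters()

  bad <- ps; bad$stage_dist$screened <- c(0.5, 0.5, 0.1, 0.0)
  expect_error(validate_parameters(bad), "proportions must sum to 1",
               class = "screencea_validation_error")

  bad <- ps; bad$utilities$utility <- c(1, 0.3, 0.5, 0.6, 0.7)
  expect_error(validate_parameters(bad), "non-increasing")

  bad <- ps; bad$utilities$utility[1] <- 0.9
  expect_error(validate_parameters(bad), "Healthy utility")

  bad <- ps; bad$stage_costs$cost[2] <- -1
  expect_error(validate_parameters(bad), "non-negative")

  bad <- ps; bad$strat$multiplier[1] <- 0
  expect_error(validate_parameters(bad), "positive")

  bad <- ps; bad$strat$percentile_high[1] <- 50
  expect_error(validate_parameters(bad), "partition")

  bad <- ps; bad$config$discount_rate <- 1.2
  expect_error(validate_parameters(bad), "discount_rate")

  bad <- ps; bad$asir$rate[3] <- 2
  expect_error(validate_parameters(bad), "\\[0,1\\]")

  bad <- ps; bad$osa_bounds$parameter[1] <- "no_such_parameter"
  expect_error(validate_parameters(bad), "does not resolve")
})

test_that("write/load round-trips the baseline exactly", {
  ps <- baseline_parameters()
  dir <- withr::local_tempdir()
  write_parameters(ps, dir)
  loaded <- load_parameters(dir, quiet = TRUE)
  for (f in c("asir", "stage_dist", "mortality", "utilities", "stage_costs",
              "test_costs", "strat", "osa_bounds", "psa_spec"))
    expect_equal(as.data.frame(loaded[[f]]), as.data.frame(ps[[f]]),
                 info = f)
  expect_equal(loaded$all_cause_mortality, ps$all_cause_mortality)
  expect_equal(loaded$config, ps$config)
})

test_that("partial overrides fall back to the baseline with a notice", {
  ps <- baseline_parameters()
  dir <- withr::local_tempdir()

  yaml::write_yaml(list(), file.path(dir, "parameters.yml"))
  expect_message(empty <- load_parameters(dir), "using baseline")
  for (f in c("asir", "stage_dist", "strat"))
    expect_equal(as.data.frame(empty[[f]]), as.data.frame(ps[[f]]))

  yaml::write_yaml(list(config = list(discount_rate = 0)),
                   file.path(dir, "parameters.yml"))
  zero_disc <- load_parameters(dir, quiet = TRUE)
  expect_equal(zero_disc$config$discount_rate, 0)
  expect_equal(zero_disc$config$start_age, 35L)

  bad <- list(stage_dist = list(
    list(stage = "I", screened = 0.5, unscreened = 0.22),
    list(stage = "II", screened = 0.5, unscreened = 0.57),
    list(stage = "III", screened = 0.1, unscreened = 0.12),
    list(stage = "IV", screened = 0.0, unscreened = 0.09)))
  yaml::write_yaml(bad, file.path(dir, "parameters.yml"))
  expect_error(load_parameters(dir, quiet = TRUE),
               class = "screencea_validation_error")

  expect_error(load_parameters(file.path(dir, "nope.yml")),
               class = "screencea_parse_error")
})

test_that("parameter registry gets, sets and renormalises", {
  ps <- baseline_parameters()
  expect_equal(param_get(ps, "cost_stage_II"), 78226)
  expect_equal(param_get(ps, "multiplier_high"), 2)

  ps2 <- param_set(ps, "stage_dist_screened_I", 0.636)
  expect_equal(param_get(ps2, "stage_dist_screened_I"), 0.636)
  expect_equal(sum(ps2$stage_dist$screened), 1)
  # other stages keep their relative shares
  rest <- ps$stage_dist$screened[-1] / sum(ps$stage_dist$screened[-1])
  expect_equal(ps2$stage_dist$screened[-1] / sum(ps2$stage_dist$screened[-1]),
               rest)

  ps3 <- param_set(ps, "utility_I", 1.5)
  expect_equal(param_get(ps3, "utility_I"), 1)
  ps4 <- param_set(ps, "mammography_sensitivity", 1.2)
  expect_equal(ps4$config$mammography_sensitivity, 1)

  expect_error(param_get(ps, "nope"),
               class = "screencea_unknown_parameter")
})
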