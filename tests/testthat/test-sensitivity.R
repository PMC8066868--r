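test_that("gamma fits are moment-matched to the published ranges", {
  f <- fit_gamma(110, 87.50, 162.50)
  expect_equal(f$shape / f$rate, 110, tolerance = 1e-6)
  expect_equal(sqrt(f$shape) / f$rate, (162.50 - 87.50) / (2 * 1.96))
  set.seed(1)
  draws <- rgamma(1e5, shape = f$shape, rate = f$rate)
  expect_lt(abs(mean(draws) - 110), 3 * sd(draws) / sqrt(1e5))
  expect_error(fit_gamma(110, 110, 110),
               class = "screencea_validation_error")
  expect_error(fit_gamma(-1, -2, 3), class = "screencea_validation_error")
})

test_that("beta fits stay on [0,1] with the requested mean", {
  f <- fit_beta(0.731, 0.63, 0.83)
  expect_equal(f$shape / (f$shape + f$shape2), 0.731, tolerance = 1e-6)
  f4 <- fit_beta(0.352, 0.252, 0.452)
  set.seed(1)
  draws <- rbeta(1e4, f4$shape, f4$shape2)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.352), 3 * sd(draws) / sqrt(1e4))
  # infeasible dispersion is shrunk, not fatal
  expect_message(wide <- fit_beta(0.01, -1, 1), "shrunk")
  expect_true(wide$sd^2 < 0.01 * 0.99)
  expect_error(fit_beta(1.2, 1.1, 1.3), class = "screencea_validation_error")
})

test_that("one-way runs with degenerate bounds have zero span", {
  ps <- baseline_parameters()
  base <- param_get(ps, "cost_stage_II")
  ps$osa_bounds[ps$osa_bounds$parameter == "cost_stage_II",
                c("low", "high")] <- base
  entry <- osa_run("cost_stage_II", ps)
  expect_equal(entry$span, 0)
  expect_equal(entry$icer_at_low, entry$icer_at_high)
})

test_that("a parameter no strategy uses has zero span", {
  ps <- baseline_parameters()
  # both comparators mammogram-only: ultrasound price cannot matter
  ref <- build_current_strategy()
  cmp <- truncate_strategy(build_current_strategy(), 60)
  entry <- osa_run("cost_ultrasound", ps, reference = ref, comparator = cmp)
  expect_equal(entry$span, 0)
  expect_error(osa_run("no_such", ps),
               class = "screencea_unknown_parameter")
})

test_that("tornado ordering is deterministic and sorted by span", {
  ps <- baseline_parameters()
  subset <- c("cost_stage_II", "utility_II", "discount_rate",
              "multiplier_low")
  a <- run_osa(ps, parameters = subset)
  b <- run_osa(ps, parameters = rev(subset))
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(all(diff(a$span) <= 0))
})

test_that("PSA draws are reproducible and common across arms", {
  ps <- baseline_parameters()
  a <- run_psa(ps, n = 50, seed = 9)
  b <- run_psa(ps, n = 50, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, run_psa(ps, n = 50, seed = 10)$draws))
  expect_error(run_psa(ps, n = 0), class = "screencea_validation_error")
})

test_that("zero-variance distributions reproduce the deterministic result", {
  ps <- baseline_parameters()
  ps$psa_spec$low <- ps$psa_spec$mean
  ps$psa_spec$high <- ps$psa_spec$mean
  psa <- run_psa(ps, n = 10, seed = 1)
  base <- psa$baseline
  expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 10))
  expect_equal(psa$draws$delta_qaly, rep(base$delta_qaly, 10))
})

test_that("PSA agrees with brute-force re-evaluation per draw", {
  ps <- baseline_parameters()
  psa <- run_psa(ps, n = 4, seed = 21)
  ref <- build_current_strategy()
  cmp <- build_tailored_strategy()
  for (i in 1:4) {
    psd <- ps
    for (p in ps$psa_spec$parameter)
      psd <- param_set(psd, p, psa$draws[[p]][i])
    ce <- icer(run_strategy(ref, psd), run_strategy(cmp, psd))
    expect_equal(psa$draws$delta_cost[i], ce$delta_cost, tolerance = 1e-9)
    expect_equal(psa$draws$delta_qaly[i], ce$delta_qaly, tolerance = 1e-9)
  }
})

test_that("acceptability curves follow the net-benefit rule", {
  draws <- tibble::tibble(draw = 1:4,
                          delta_cost = c(-100, -50, 50, 100),
                          delta_qaly = c(0.1, 0.1, 0.1, 0.1))
  cc <- ceac(draws, wtp_grid = c(0, 499, 500, 1000, 2000))
  expect_equal(cc$probability, c(0.5, 0.5, 0.75, 1, 1))
  expect_true(all(diff(cc$probability) >= 0))   # monotone when dQALY > 0
  expect_equal(wtp_full_acceptance(structure(list(draws = draws),
                                             class = "psa_result"),
                                   wtp_grid = 0:2000), 1000)
  all_se <- tibble::tibble(draw = 1:3, delta_cost = c(-1, -2, -3),
                           delta_qaly = c(0.1, 0.2, 0.3))
  expect_equal(ceac(all_se, c(0, 10))$probability, c(1, 1))
  never <- tibble::tibble(draw = 1, delta_cost = 10, delta_qaly = -1)
  expect_equal(wtp_full_acceptance(structure(list(draws = never),
                                             class = "psa_result"),
                                   wtp_grid = 0:10), Inf)
})
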