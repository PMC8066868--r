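test_that("diagnosis probability is the published product of factors", {
  ps <- baseline_parameters()
  # ASIR(52) x p_screened(I) x sensitivity x multiplier
  expect_equal(diagnosis_probability(52, "I", 2, TRUE, ps),
               0.001775 * 0.53 * 0.8 * 2)
  expect_equal(diagnosis_probability(37, "IV", 0.5, TRUE, ps),
               0.000617 * 0.01 * 0.8 * 0.5)
  # off-screen: nothing in screen_only, unscreened mix with interval detection
  ps_so <- with_mode(ps, "screen_only")
  expect_equal(diagnosis_probability(52, "I", 1, FALSE, ps_so), 0)
  expect_equal(diagnosis_probability(52, "I", 1, FALSE, ps),
               0.001775 * 0.22)
  expect_equal(unname(diagnosis_probability(52, "all", 1, TRUE, ps)),
               0.001775 * c(0.53, 0.43, 0.03, 0.01) * 0.8)
  # clamped to [0,1] for extreme multipliers
  expect_true(all(diagnosis_probability(52, "all", 1e6, TRUE, ps) <= 1))
  expect_error(diagnosis_probability(52, "I", -1, TRUE, ps),
               class = "screencea_validation_error")
})

test_that("transition matrix rows are stochastic with the stated structure", {
  ps <- baseline_parameters()
  m <- transition_matrix(60, 2, TRUE, ps)
  expect_equal(unname(m["Dead", ]), c(0, 0, 0, 0, 0, 1))
  expect_equal(m["IV", "Dead"], 0.268 + 0.002896)
  expect_equal(m["IV", "IV"], 1 - 0.268 - 0.002896)
  expect_equal(m["I", "II"], 0)   # no stage progression after diagnosis
  # healthy row with all diagnosis probabilities zero
  m0 <- transition_matrix(60, 1, FALSE, with_mode(ps, "screen_only"))
  expect_equal(m0["Healthy", "Healthy"], 1 - 0.002896)
  expect_equal(m0["Healthy", "Dead"], 0.002896)

  for (seed in 1:5) {
    psr <- generate_parameter_set(synthetic_spec(seed = seed))
    for (scr in c(TRUE, FALSE)) {
      m <- transition_matrix(55, 1.7, scr, psr)
      expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-12)
      expect_true(all(m >= 0))
    }
  }
})

test_that("infeasible transition mass is rejected", {
  ps <- baseline_parameters()
  ps$asir$rate <- rep(0.9, nrow(ps$asir))   # valid alone, infeasible x2 risk
  expect_error(transition_matrix(60, 2, TRUE, ps),
               class = "screencea_infeasible_error")
})

test_that("cohort recursion: degenerate and closed-form cases", {
  ps <- zero_rate_params()
  sched <- build_current_strategy()$arms$schedule[[1]]
  tr <- run_cohort(sched, 1, ps)
  expect_equal(nrow(tr), 40)
  expect_equal(tr$healthy, rep(1, 40))
  expect_equal(sum(tr$dx_I + tr$dx_II + tr$dx_III + tr$dx_IV), 0)

  # no incidence, flat background hazard: closed-form lifetime mortality
  ps2 <- baseline_parameters()
  ps2$asir$rate <- 0
  tr2 <- run_cohort(sched, 1, ps2)
  expect_equal(attr(tr2, "final_state")[6], 1 - (1 - 0.002896)^40,
               tolerance = 1e-12)
})

test_that("occupancy is conserved, death and diagnoses are monotone", {
  sched_t <- build_tailored_strategy()$arms$schedule[[3]]
  for (seed in 1:5) {
    ps <- generate_parameter_set(synthetic_spec(seed = seed))
    for (mode in c("screen_only", "screen_plus_interval")) {
      tr <- run_cohort(sched_t, 2, with_mode(ps, mode))
      occ <- as.matrix(tr[, c("healthy", "stage_I", "stage_II", "stage_III",
                              "stage_IV", "dead")])
      expect_equal(unname(rowSums(occ)), rep(1, nrow(tr)), tolerance = 1e-9)
      expect_true(all(occ >= 0))
      expect_true(all(diff(tr$dead) >= 0))
      cum_dx <- cumsum(tr$dx_I + tr$dx_II + tr$dx_III + tr$dx_IV)
      expect_true(all(diff(cum_dx) >= -1e-15))
      expect_true(all(tr$new_deaths >= 0))
    }
  }
})

test_that("accumulation: undiscounted no-event cohort banks one LY per cycle", {
  ps <- zero_rate_params()
  ps$config$discount_rate <- 0
  sched <- screening_schedule(integer(0))
  out <- accumulate(run_cohort(sched, 1, ps), sched, 0, ps)
  expect_equal(out$life_years, 40)
  expect_equal(out$qalys, 40)
  expect_equal(out$cost, 0)

  ps$config$discount_rate <- 0.03
  out2 <- accumulate(run_cohort(sched, 1, ps), sched, 0, ps)
  expect_equal(out2$life_years, sum(1.03^-(0:39)))
})

test_that("costs decompose into screening, entry and stage components", {
  ps <- baseline_parameters()
  sched <- build_current_strategy()$arms$schedule[[1]]
  tr <- run_cohort(sched, 1, ps)
  disc <- 1.03^-(tr$cycle)

  for (model in c("annual", "once")) {
    psm <- ps
    psm$config$stage_cost_model <- model
    out <- accumulate(tr, sched, 212, psm)
    screen_cost <- sum(110 * disc[tr$age %in% sched$age] *
                         tr$healthy[tr$age %in% sched$age])
    stage_exposure <- if (model == "annual")
      colSums(disc * as.matrix(tr[, c("stage_I", "stage_II", "stage_III",
                                      "stage_IV")]))
    else colSums(disc * as.matrix(tr[, c("dx_I", "dx_II", "dx_III",
                                         "dx_IV")]))
    expect_equal(out$cost,
                 212 + screen_cost + sum(stage_exposure * ps$stage_costs$cost),
                 info = model)
  }
})

test_that("QALYs never exceed life years; discounting never increases outcomes", {
  for (seed in 1:3) {
    ps <- generate_parameter_set(synthetic_spec(seed = seed))
    for (strat in list(build_current_strategy(ps$config),
                       build_tailored_strategy(ps$strat, ps$config))) {
      disc <- run_strategy(strat, ps)
      ps0 <- ps; ps0$config$discount_rate <- 0
      undisc <- run_strategy(strat, ps0)
      expect_lte(disc$qalys, disc$life_years)
      expect_lte(disc$cost, undisc$cost)
      expect_lte(disc$life_years, undisc$life_years)
      expect_lte(disc$qalys, undisc$qalys)
    }
  }
})

test_that("half-cycle correction shaves at most half a cycle of alive time", {
  ps <- baseline_parameters()
  ps_h <- ps; ps_h$config$half_cycle_correction <- TRUE
  sched <- build_current_strategy()$arms$schedule[[1]]
  tr <- run_cohort(sched, 1, ps)
  a <- accumulate(tr, sched, 0, ps)
  b <- accumulate(tr, sched, 0, ps_h)
  expect_lt(b$life_years, a$life_years)
  expect_gt(b$life_years, a$life_years - 0.5)
})

test_that("arm mixing is the population-weighted expectation", {
  ps <- baseline_parameters()
  sched <- build_current_strategy()$arms$schedule[[1]]
  one <- accumulate(run_cohort(sched, 1, ps), sched, 0, ps)
  expect_equal(as.data.frame(mix_arms(list(one), 1)), as.data.frame(one))
  expect_equal(as.data.frame(mix_arms(list(one, one), c(0.5, 0.5))),
               as.data.frame(one))
  two <- accumulate(run_cohort(sched, 2, ps), sched, 0, ps)
  mixed <- mix_arms(list(one, two), c(0.25, 0.75))
  expect_equal(mixed$cost, 0.25 * one$cost + 0.75 * two$cost)
  expect_error(mix_arms(list(one, two), c(0.7, 0.7)),
               class = "screencea_validation_error")
})

test_that("doubling incidence strictly increases detected cases", {
  ps <- baseline_parameters()
  ps2 <- ps
  ps2$asir$rate <- 2 * ps$asir$rate
  for (strat in list(build_current_strategy(), build_tailored_strategy())) {
    base <- run_strategy(strat, ps)
    doubled <- run_strategy(strat, ps2)
    expect_gt(doubled$cases_per_1000, base$cases_per_1000)
  }
})
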