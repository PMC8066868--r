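# Shared fixtures, built in code.

# baseline with every hazard zeroed: nobody is ever diagnosed or dies
zero_rate_params <- function() {
  ps <- baseline_parameters()
  ps$asir$rate <- 0
  ps$mortality$rate <- rep(0, 4)
  ps$all_cause_mortality <- 0
  ps
}

# degenerate synthetic spec: all perturbations off
degenerate_spec <- function(seed = 1) {
  synthetic_spec(seed = seed,
                 incidence_scale_sd = 0, incidence_jitter = 0,
                 stage_concentration = Inf, proportion_concentration = Inf,
                 cost_dispersion = 0, utility_jitter = 0,
                 mortality_jitter = 0)
}

# hand-made one-row outcomes for CEA unit tests
make_outcomes <- function(cost, ly, qalys) {
  tibble::tibble(cost = cost, life_years = ly, qalys = qalys,
                 cases_per_1000 = 0, death_probability = 0)
}

with_mode <- function(ps, mode) {
  ps$config$detection_mode <- mode
  ps
}

# total strategy cost decomposed into its screening/entry component
screening_cost_component <- function(strategy, ps) {
  out <- run_strategy(strategy, ps)
  l <- attr(out, "loadings")
  sum(l$screens_by_test *
        ps$test_costs$cost[match(names(l$screens_by_test),
                                 ps$test_costs$test)]) +
    entry_cost(strategy, ps)
}
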