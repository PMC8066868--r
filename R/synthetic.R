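# Synthetic parameter sets with the statistical structure the analysis
# assumes, and an individual-level microsimulation oracle for validating the
# cohort recursion.

#' Specification for a synthetic parameter set
#'
#' Controls the perturbation distributions applied around the bundled
#' baseline: a multiplicative scale (log-normal) and band-level jitter for
#' the incidence curve (kept non-decreasing up to a plateau), Dirichlet
#' draws for the stage simplexes and risk-group proportions (concentration
#' `kappa * baseline`), log-normal dispersion for costs (re-ordered so costs
#' increase with stage), and bounded jitter for utilities (re-ordered so
#' utilities are non-increasing with stage). All-zero perturbations
#' reproduce the baseline fixture exactly.
#'
#' @param seed Integer seed.
#' @param incidence_scale_sd Log-sd of the common incidence scale.
#' @param incidence_jitter Log-sd of per-band jitter.
#' @param stage_concentration Dirichlet concentration for stage simplexes.
#' @param proportion_concentration Dirichlet concentration for risk-group
#'   proportions.
#' @param cost_dispersion Log-sd for stage and test costs.
#' @param utility_jitter Half-width of uniform utility jitter.
#' @param mortality_jitter Log-sd for stage mortality rates.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1,
                           incidence_scale_sd = 0.25,
                           incidence_jitter = 0.10,
                           stage_concentration = 80,
                           proportion_concentration = 80,
                           cost_dispersion = 0.15,
                           utility_jitter = 0.05,
                           mortality_jitter = 0.15) {
  structure(list(seed = seed,
                 incidence_scale_sd = incidence_scale_sd,
                 incidence_jitter = incidence_jitter,
                 stage_concentration = stage_concentration,
                 proportion_concentration = proportion_concentration,
                 cost_dispersion = cost_dispersion,
                 utility_jitter = utility_jitter,
                 mortality_jitter = mortality_jitter),
            class = "synthetic_spec")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a random, fully validated parameter set
#'
#' Draws a parameter set around the bundled baseline according to a
#' [synthetic_spec()]. By construction every generated set passes
#' [validate_parameters()]: stage simplexes sum to 1, utilities are
#' stage-monotone with Healthy fixed at 1, costs increase with stage, and
#' the incidence curve is non-decreasing to a plateau. Sensitivity bounds
#' and the PSA specification are rebuilt around the perturbed values
#' (costs +/-30% Gamma, utilities +/-0.1 Beta, 80/120% elsewhere).
#'
#' @param spec A `synthetic_spec`.
#' @return A validated `parameter_set`.
#' @examples
#' ps <- generate_parameter_set(synthetic_spec(seed = 7))
#' validate_parameters(ps)
#' @export
generate_parameter_set <- function(spec = synthetic_spec()) {
  ps <- baseline_parameters()
  degenerate <- spec$incidence_scale_sd == 0 && spec$incidence_jitter == 0 &&
    is.infinite(spec$stage_concentration) &&
    is.infinite(spec$proportion_concentration) &&
    spec$cost_dispersion == 0 && spec$utility_jitter == 0 &&
    spec$mortality_jitter == 0
  if (degenerate) return(ps)
  set.seed(spec$seed)

  ## incidence: common scale + band jitter, non-decreasing to a plateau
  scale <- exp(stats::rnorm(1, 0, spec$incidence_scale_sd))
  jit <- exp(stats::rnorm(nrow(ps$asir), 0, spec$incidence_jitter))
  rates <- pmin(cummax(ps$asir$rate * scale * jit), 0.05)
  ps$asir$rate <- rates

  ## stage simplexes
  for (ctx in c("screened", "unscreened"))
    ps$stage_dist[[ctx]] <-
      .rdirichlet1(spec$stage_concentration * ps$stage_dist[[ctx]])

  ## mortality: jittered, kept increasing with stage
  ps$mortality$rate <- pmin(sort(
    ps$mortality$rate * exp(stats::rnorm(4, 0, spec$mortality_jitter))), 1)

  ## utilities: jittered, non-increasing with stage, interior of (0,1)
  su <- ps$utilities$utility[-1] +
    stats::runif(4, -spec$utility_jitter, spec$utility_jitter)
  ps$utilities$utility[-1] <- sort(pmin(pmax(su, 0.05), 0.95),
                                   decreasing = TRUE)

  ## costs: dispersed, increasing with stage
  ps$stage_costs$cost <- sort(
    ps$stage_costs$cost * exp(stats::rnorm(4, 0, spec$cost_dispersion)))
  vary <- ps$test_costs$test != "self_exam"
  ps$test_costs$cost[vary] <-
    ps$test_costs$cost[vary] *
    exp(stats::rnorm(sum(vary), 0, spec$cost_dispersion))

  ## risk-group proportions
  ps$strat$proportion <-
    .rdirichlet1(spec$proportion_concentration * ps$strat$proportion)

  ## rebuild sensitivity tables around the perturbed values
  ps$osa_bounds <- .synthetic_osa_bounds(ps)
  ps$psa_spec <- .baseline_psa_spec(ps)
  validate_parameters(ps)
  ps
}

# 80/120% everywhere, +/-30% for costs, +/-0.1 for utilities (all capped to
# valid support) — the same rules the baseline applies, from the new values
.synthetic_osa_bounds <- function(ps) {
  cost_ids <- c(paste0("cost_stage_", .stages),
                paste0("cost_", setdiff(.test_types, "self_exam")))
  util_ids <- paste0("utility_", .stages)
  other_ids <- c(paste0("multiplier_", .risk_groups),
                 "mammography_sensitivity", "discount_rate",
                 paste0("mortality_stage_", .stages),
                 paste0("stage_dist_screened_", .stages),
                 paste0("stage_dist_unscreened_", .stages))
  rows <- purrr::map(c(cost_ids, util_ids, other_ids), function(id) {
    v <- param_get(ps, id)
    if (id %in% cost_ids) {
      lo <- 0.7 * v; hi <- 1.3 * v
    } else if (id %in% util_ids) {
      lo <- max(v - 0.1, 0.01); hi <- min(v + 0.1, 0.99)
    } else {
      lo <- 0.8 * v
      hi <- if (id %in% c("multiplier_low", "multiplier_intermediate",
                          "multiplier_high", "discount_rate"))
        1.2 * v else min(1.2 * v, 1)
    }
    tibble::tibble(parameter = id, low = lo, high = hi)
  })
  dplyr::bind_rows(rows)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` women year by year using the identical
#' per-cycle probabilities as the cohort engine (risk group sampled by
#' population proportion; diagnosis, death, costs and utilities realised
#' stochastically; the same discounted accounting as [accumulate()]).
#' Serves as a brute-force validation of the cohort recursion: its mean
#' outcomes converge to the cohort values with the returned Monte Carlo
#' standard errors.
#'
#' @param strategy A `strategy`.
#' @param ps A `parameter_set` (half-cycle correction must be off; the
#'   oracle accounts cycle-start occupancy).
#' @param n_individuals Number of simulated women.
#' @param seed Integer seed.
#' @return A tibble with one row per outcome (`cost`, `life_years`,
#'   `qalys`, `cases_per_1000`, `death_probability`), columns `estimate`
#'   and `se`.
#' @examples
#' microsim_oracle(build_current_strategy(), baseline_parameters(),
#'                 n_individuals = 1000, seed = 1)
#' @export
microsim_oracle <- function(strategy, ps, n_individuals = 200000, seed = 1) {
  if (n_individuals < 1)
    rlang::abort("need at least one individual",
                 class = "screencea_validation_error")
  if (isTRUE(ps$config$half_cycle_correction))
    rlang::abort("the microsimulation oracle assumes cycle-start accounting",
                 class = "screencea_validation_error")
  set.seed(seed)
  n_arm <- as.integer(stats::rmultinom(1, n_individuals,
                                       strategy$arms$weight))
  ec <- entry_cost(strategy, ps)
  ages <- seq(ps$config$start_age, ps$config$end_age)
  ac <- ps$all_cause_mortality
  stage_death <- pmin(ps$mortality$rate + ac, 1)
  util <- ps$utilities$utility[match(c("Healthy", .stages),
                                     ps$utilities$state)]
  stage_cost <- ps$stage_costs$cost[match(.stages, ps$stage_costs$stage)]
  annual <- ps$config$stage_cost_model == "annual"
  test_cost_of <- stats::setNames(
    ps$test_costs$cost[match(.test_types, ps$test_costs$test)], .test_types)

  sim_arm <- function(n, schedule, multiplier) {
    state <- rep.int(1L, n)            # 1 Healthy, 2-5 stages, 6 Dead
    cost <- rep.int(ec, n)
    ly <- qaly <- numeric(n)
    case <- logical(n)
    sched_cost <- stats::setNames(rep(0, length(ages)), ages)
    sched_cost[as.character(schedule$age)] <- test_cost_of[schedule$modality]
    imaging_ages <- schedule$age[schedule$modality != "self_exam"]
    for (t in seq_along(ages)) {
      age <- ages[t]
      disc <- (1 + ps$config$discount_rate)^-(t - 1)
      alive <- state != 6L
      ly[alive] <- ly[alive] + disc
      qaly[alive] <- qaly[alive] + disc * util[state[alive]]
      healthy <- state == 1L
      in_stage <- state >= 2L & state <= 5L
      if (annual && any(in_stage))
        cost[in_stage] <- cost[in_stage] + disc * stage_cost[state[in_stage] - 1L]
      is_screen <- age %in% schedule$age
      if (is_screen && any(healthy))
        cost[healthy] <- cost[healthy] + disc * sched_cost[[as.character(age)]]
      pdx <- .diagnosis_vector(age, multiplier, age %in% imaging_ages, ps)
      ## healthy: competing diagnosis (4 stages) / other-cause death
      idx <- which(healthy)
      if (length(idx)) {
        u <- stats::runif(length(idx))
        thr <- cumsum(c(pdx, ac))
        dest <- findInterval(u, thr) + 1L   # 1..4 stage, 5 death, >5 stay
        dx <- dest <= 4L
        if (any(dx)) {
          state[idx[dx]] <- dest[dx] + 1L
          case[idx[dx]] <- TRUE
          if (!annual)
            cost[idx[dx]] <- cost[idx[dx]] + disc * stage_cost[dest[dx]]
        }
        state[idx[dest == 5L]] <- 6L
      }
      ## staged women: stage-specific + all-cause death
      idx <- which(in_stage)
      if (length(idx)) {
        dies <- stats::runif(length(idx)) < stage_death[state[idx] - 1L]
        state[idx[dies]] <- 6L
      }
    }
    tibble::tibble(cost = cost, ly = ly, qaly = qaly,
                   case = as.numeric(case), dead = as.numeric(state == 6L))
  }

  per <- dplyr::bind_rows(purrr::pmap(
    list(n_arm, strategy$arms$schedule, strategy$arms$multiplier),
    function(n, sched, mult) {
      if (n == 0) return(NULL)
      sim_arm(n, sched, mult)
    }))
  per$case1000 <- per$case * 1000
  fields <- c(cost = "cost", life_years = "ly", qalys = "qaly",
              cases_per_1000 = "case1000", death_probability = "dead")
  tibble::tibble(
    outcome = names(fields),
    estimate = unname(vapply(fields, function(f) mean(per[[f]]), numeric(1))),
    se = unname(vapply(fields, function(f)
      stats::sd(per[[f]]) / sqrt(nrow(per)), numeric(1)))
  )
}
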