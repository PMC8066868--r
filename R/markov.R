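# Markov cohort engine: annual-cycle state-transition recursion over
# Healthy, Stage I-IV and Dead, with screen-triggered and interval detection,
# and discounted accumulation of costs, life years and QALYs.

#' Annual probability of diagnosis into a stage
#'
#' In a cycle with an imaging screen (mammogram or ultrasound) the
#' probability of a Healthy woman being diagnosed at stage `s` is
#' `ASIR(age) * p_screened(s) * sensitivity * multiplier`. Outside imaging
#' screens, detection depends on the configured mode:
#' `"screen_only"` yields 0 (no detection between screens), while
#' `"screen_plus_interval"` yields `ASIR(age) * p_unscreened(s) * multiplier`
#' (symptomatic interval presentation, no imaging sensitivity). Results are
#' clamped to \[0,1\]. A self-examination visit is not an imaging screen.
#'
#' @param age Age in years (within the covered incidence bands).
#' @param stage Stage label(s) among `"I".."IV"`, or `"all"` for the full
#'   vector.
#' @param multiplier Risk-group incidence multiplier (> 0).
#' @param is_screen_cycle Is this an imaging screen cycle for the arm?
#' @param ps A `parameter_set`.
#' @return Annual probability (vector along `stage`).
#' @examples
#' ps <- baseline_parameters()
#' diagnosis_probability(52, "I", 2, TRUE, ps)   # 0.0015052
#' @export
diagnosis_probability <- function(age, stage, multiplier, is_screen_cycle,
                                  ps) {
  if (multiplier < 0)
    rlang::abort("risk multiplier must be non-negative",
                 class = "screencea_validation_error")
  p <- .diagnosis_vector(age, multiplier, is_screen_cycle, ps)
  if (identical(stage, "all")) return(p)
  unname(p[match(match.arg(stage, .stages, several.ok = TRUE), .stages)])
}

# stage-indexed diagnosis probabilities for one cycle (internal fast path)
.diagnosis_vector <- function(age, multiplier, is_screen_cycle, ps) {
  if (is_screen_cycle) {
    p <- asir_lookup(ps$asir, age) * ps$stage_dist$screened *
      ps$config$mammography_sensitivity * multiplier
  } else if (ps$config$detection_mode == "screen_only") {
    p <- numeric(4)
  } else {
    p <- asir_lookup(ps$asir, age) * ps$stage_dist$unscreened * multiplier
  }
  stats::setNames(pmin(pmax(p, 0), 1), .stages)
}

#' Transition matrix for one cycle
#'
#' Row-stochastic matrix over (Healthy, I, II, III, IV, Dead). Healthy women
#' are diagnosed per [diagnosis_probability()] or die of other causes; women
#' in a stage state die at the stage-specific breast-cancer rate plus the
#' all-cause rate (cause-specific rates added, capped at 1) or remain in
#' their stage — the model has no remission and no stage progression after
#' diagnosis. Dead is absorbing.
#'
#' @inheritParams diagnosis_probability
#' @return A 6x6 matrix with rows summing to 1.
#' @export
transition_matrix <- function(age, multiplier, is_screen_cycle, ps) {
  pdx <- .diagnosis_vector(age, multiplier, is_screen_cycle, ps)
  ac <- ps$all_cause_mortality
  if (sum(pdx) + ac > 1)
    rlang::abort(sprintf(
      "infeasible parameters: Healthy off-diagonal mass %.4f exceeds 1 at age %d",
      sum(pdx) + ac, age), class = "screencea_infeasible_error")
  stage_death <- pmin(ps$mortality$rate + ac, 1)
  m <- matrix(0, 6, 6, dimnames = list(.states, .states))
  m["Healthy", .stages] <- pdx
  m["Healthy", "Dead"] <- ac
  m["Healthy", "Healthy"] <- 1 - sum(pdx) - ac
  for (i in seq_along(.stages)) {
    m[.stages[i], "Dead"] <- stage_death[i]
    m[.stages[i], .stages[i]] <- 1 - stage_death[i]
  }
  m["Dead", "Dead"] <- 1
  m
}

#' Run the cohort recursion for one risk-group arm
#'
#' Starts 100% Healthy at `start_age` and iterates one annual cycle per age
#' through `end_age`. New diagnoses are recorded from the Healthy occupancy
#' at cycle start, before the state update.
#'
#' @param schedule A `screening_schedule` (tibble with `age`, `modality`).
#' @param multiplier Risk-group incidence multiplier.
#' @param ps A `parameter_set`.
#' @return A `cohort_trace` tibble, one row per cycle: `cycle` (0-based),
#'   `age`, occupancies `healthy`, `stage_I`..`stage_IV`, `dead` at cycle
#'   start, per-stage new diagnoses `dx_I`..`dx_IV` occurring during the
#'   cycle, and `new_deaths`.
#' @examples
#' tr <- run_cohort(build_current_strategy()$arms$schedule[[1]], 1,
#'                  baseline_parameters())
#' sum(tr$dx_I + tr$dx_II + tr$dx_III + tr$dx_IV) * 1000
#' @export
run_cohort <- function(schedule, multiplier, ps) {
  ages <- seq(ps$config$start_age, ps$config$end_age)
  n <- length(ages)
  occ <- c(1, 0, 0, 0, 0, 0)
  ac <- ps$all_cause_mortality
  stage_death <- pmin(ps$mortality$rate + ac, 1)
  occ_mat <- matrix(0, n + 1, 6)
  dx_mat <- matrix(0, n, 4)
  occ_mat[1, ] <- occ
  imaging_ages <- schedule$age[schedule$modality != "self_exam"]
  for (t in seq_len(n)) {
    age <- ages[t]
    pdx <- .diagnosis_vector(age, multiplier, age %in% imaging_ages, ps)
    if (sum(pdx) + ac > 1)
      rlang::abort(sprintf(
        "infeasible parameters: Healthy off-diagonal mass exceeds 1 at age %d",
        age), class = "screencea_infeasible_error")
    new_dx <- occ[1] * pdx
    dx_mat[t, ] <- new_dx
    nxt <- numeric(6)
    nxt[6] <- occ[6] + occ[1] * ac + sum(occ[2:5] * stage_death)
    nxt[2:5] <- occ[2:5] * (1 - stage_death) + new_dx
    nxt[1] <- occ[1] * (1 - sum(pdx) - ac)
    occ <- nxt
    occ_mat[t + 1, ] <- occ
  }
  out <- tibble::tibble(
    cycle = seq_len(n) - 1L,
    age = ages,
    healthy = occ_mat[seq_len(n), 1],
    stage_I = occ_mat[seq_len(n), 2],
    stage_II = occ_mat[seq_len(n), 3],
    stage_III = occ_mat[seq_len(n), 4],
    stage_IV = occ_mat[seq_len(n), 5],
    dead = occ_mat[seq_len(n), 6],
    dx_I = dx_mat[, 1], dx_II = dx_mat[, 2],
    dx_III = dx_mat[, 3], dx_IV = dx_mat[, 4],
    new_deaths = occ_mat[seq_len(n) + 1, 6] - occ_mat[seq_len(n), 6]
  )
  attr(out, "final_state") <- occ
  attr(out, "multiplier") <- multiplier
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Accumulate discounted outcomes over a cohort trace
#'
#' Per cycle `t` (0 at `start_age`) the discount factor is `(1+r)^-t`.
#' Life years count the alive occupancy at cycle start; QALYs weight each
#' state's occupancy by its utility. Costs comprise screening test costs for
#' the Healthy occupancy in screen cycles, direct medical costs for the
#' diseased states — charged annually per year of stage occupancy under
#' `stage_cost_model = "annual"` (the default) or once at diagnosis under
#' `"once"` — and any one-time entry cost at cycle 0. Cases and the lifetime
#' death probability are undiscounted. With `half_cycle_correction = TRUE`,
#' life-year and QALY contributions average the cycle-start and cycle-end
#' occupancies.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param schedule The `screening_schedule` that produced it.
#' @param entry_cost One-time cost at entry (SGD).
#' @param ps A `parameter_set`.
#' @return An `arm_outcomes` tibble (one row): `cost`, `life_years`, `qalys`
#'   (all discounted, per woman), `cases_per_1000` and `death_probability`
#'   (undiscounted). Carries a `"loadings"` attribute with the discounted
#'   exposures (state person-years, screens by modality, diagnoses by stage)
#'   that outcomes are linear in.
#' @export
accumulate <- function(trace, schedule, entry_cost = 0, ps) {
  cfg <- ps$config
  ages <- trace$age
  if (length(ages) != cfg$end_age - cfg$start_age + 1)
    rlang::abort("trace and configuration cover different horizons",
                 class = "screencea_validation_error")
  disc <- (1 + cfg$discount_rate)^-(trace$cycle)
  occ <- as.matrix(trace[, c("healthy", "stage_I", "stage_II", "stage_III",
                             "stage_IV", "dead")])
  if (isTRUE(cfg$half_cycle_correction)) {
    final <- attr(trace, "final_state")
    occ_end <- rbind(occ[-1, , drop = FALSE], final)
    occ_eff <- (occ + occ_end) / 2
  } else occ_eff <- occ
  dx <- as.matrix(trace[, c("dx_I", "dx_II", "dx_III", "dx_IV")])

  ## discounted exposures (outcomes are linear functionals of these)
  py_state <- colSums(disc * occ_eff)[1:5]              # healthy + stages
  names(py_state) <- c("Healthy", .stages)
  dx_disc <- colSums(disc * dx)
  names(dx_disc) <- .stages
  screen_rows <- match(schedule$age, ages)
  screens_by_test <- vapply(.test_types, function(tt) {
    rows <- screen_rows[schedule$modality == tt]
    if (!length(rows)) 0 else sum(disc[rows] * trace$healthy[rows])
  }, numeric(1))

  util <- ps$utilities$utility[match(c("Healthy", .stages),
                                     ps$utilities$state)]
  stage_cost <- ps$stage_costs$cost[match(.stages, ps$stage_costs$stage)]
  test_cost <- ps$test_costs$cost[match(.test_types, ps$test_costs$test)]

  life_years <- sum(py_state)
  qalys <- sum(py_state * util)
  stage_exposure <- if (cfg$stage_cost_model == "annual")
    colSums(disc * occ[, 2:5, drop = FALSE]) else dx_disc
  names(stage_exposure) <- .stages
  cost <- sum(stage_exposure * stage_cost) +
    sum(screens_by_test * test_cost) + entry_cost
  cases <- sum(dx)
  final <- attr(trace, "final_state")

  out <- tibble::tibble(
    cost = cost,
    life_years = life_years,
    qalys = qalys,
    cases_per_1000 = cases * 1000,
    death_probability = final[6]
  )
  attr(out, "loadings") <- list(
    py_state = py_state, stage_exposure = stage_exposure,
    screens_by_test = screens_by_test,
    cases = cases, death_probability = final[6]
  )
  class(out) <- c("arm_outcomes", class(out))
  out
}

#' Population-weighted mixture of arm outcomes
#'
#' Every outcome field of the mixture is the weight-weighted sum of the
#' inputs' fields (the expectation over risk groups).
#'
#' @param outcomes List of `arm_outcomes` (one-row tibbles).
#' @param weights Numeric weights summing to 1.
#' @return An `arm_outcomes` tibble (one row).
#' @export
mix_arms <- function(outcomes, weights) {
  if (abs(sum(weights) - 1) > 1e-9)
    rlang::abort("mixture weights must sum to 1",
                 class = "screencea_validation_error")
  stacked <- dplyr::bind_rows(outcomes)
  out <- tibble::as_tibble(as.list(colSums(as.matrix(stacked) * weights)))
  lds <- purrr::map(outcomes, attr, "loadings")
  if (!any(purrr::map_lgl(lds, is.null))) {
    mixed <- purrr::reduce(purrr::map2(lds, weights, function(l, w)
      purrr::map(l, `*`, w)), function(a, b) purrr::map2(a, b, `+`))
    attr(out, "loadings") <- mixed
  }
  class(out) <- c("arm_outcomes", class(out))
  out
}

#' Run a full strategy (all risk-group arms)
#'
#' Runs [run_cohort()] and [accumulate()] for every arm of the strategy and
#' mixes the results by population weight. Entry costs are charged once per
#' woman in every arm.
#'
#' @param strategy A `strategy`.
#' @param ps A `parameter_set`.
#' @return An `arm_outcomes` tibble (one row) with a `"by_arm"` attribute
#'   holding the per-group outcomes.
#' @examples
#' run_strategy(build_current_strategy(), baseline_parameters())
#' @export
run_strategy <- function(strategy, ps) {
  ec <- entry_cost(strategy, ps)
  per_arm <- purrr::pmap(
    list(strategy$arms$schedule, strategy$arms$multiplier),
    function(sched, mult) {
      accumulate(run_cohort(sched, mult, ps), sched, ec, ps)
    })
  out <- mix_arms(per_arm, strategy$arms$weight)
  detail <- dplyr::bind_cols(
    tibble::tibble(group = strategy$arms$group,
                   weight = strategy$arms$weight),
    dplyr::bind_rows(per_arm))
  attr(out, "by_arm") <- detail
  attr(out, "strategy") <- strategy$name
  out
}
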