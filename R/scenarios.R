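# Percentile-cutoff scenario analysis and the ending-age variant.

#' Built-in percentile-cutoff scenarios
#'
#' The baseline stratification (60th/95th percentile cutoffs) uses the
#' empirical Asian-population proportions 0.51/0.41/0.08. No empirical
#' mapping is published for the alternative cutoffs, so those scenarios use
#' the nominal percentile widths as population proportions (e.g.
#' 0.60/0.30/0.10); supply your own proportions to [cutoff_scenario()] to
#' override. Multipliers are fixed at 0.5/1/2 throughout.
#'
#' @return Tibble of four `cutoff_scenario` specifications with list-column
#'   `proportions`.
#' @export
cutoff_scenarios <- function() {
  tibble::tibble(
    name = c("60L-35I-5H", "60L-30I-10H", "40L-55I-5H", "40L-50I-10H"),
    width_low = c(60, 60, 40, 40),
    width_intermediate = c(35, 30, 55, 50),
    width_high = c(5, 10, 5, 10),
    proportions = list(
      c(low = 0.51, intermediate = 0.41, high = 0.08),
      c(low = 0.60, intermediate = 0.30, high = 0.10),
      c(low = 0.40, intermediate = 0.55, high = 0.05),
      c(low = 0.40, intermediate = 0.50, high = 0.10)
    )
  )
}

#' Construct a cutoff scenario
#'
#' @param name Scenario label, e.g. `"55L-35I-10H"`.
#' @param widths Percentile widths (low, intermediate, high); must sum
#'   to 100.
#' @param proportions Population proportions per group; defaults to
#'   `widths / 100`.
#' @return One-row tibble in the shape of [cutoff_scenarios()].
#' @export
cutoff_scenario <- function(name, widths, proportions = widths / 100) {
  if (abs(sum(widths) - 100) > 1e-9)
    rlang::abort("percentile widths must sum to 100",
                 class = "screencea_validation_error")
  if (abs(sum(proportions) - 1) > 1e-9)
    rlang::abort("scenario proportions must sum to 1",
                 class = "screencea_validation_error")
  tibble::tibble(
    name = name,
    width_low = widths[1], width_intermediate = widths[2],
    width_high = widths[3],
    proportions = list(stats::setNames(as.numeric(proportions),
                                       c("low", "intermediate", "high")))
  )
}

#' Risk stratification implied by a cutoff scenario
#'
#' Expands a scenario row into the stratification tibble consumed by
#' [build_tailored_strategy()], keeping the parameter set's multipliers.
#'
#' @param scenario One row of [cutoff_scenarios()].
#' @param ps A `parameter_set` (supplies the multipliers).
#' @return A stratification tibble (`group`, percentile bounds,
#'   `proportion`, `multiplier`).
#' @export
scenario_stratification <- function(scenario, ps) {
  pr <- scenario$proportions[[1]]
  cuts <- cumsum(c(0, scenario$width_low, scenario$width_intermediate,
                   scenario$width_high))
  tibble::tibble(
    group = c("low", "intermediate", "high"),
    percentile_low = cuts[1:3],
    percentile_high = cuts[2:4],
    proportion = as.numeric(pr[c("low", "intermediate", "high")]),
    multiplier = ps$strat$multiplier[match(c("low", "intermediate", "high"),
                                           ps$strat$group)]
  )
}

#' Run one percentile-cutoff scenario
#'
#' Rebuilds the tailored strategy with the scenario's risk-group
#' proportions (the current programme is unchanged), runs the deterministic
#' model for both arms, and attaches the incremental result.
#'
#' @param scenario One row of [cutoff_scenarios()] (or [cutoff_scenario()]).
#' @param ps A `parameter_set`.
#' @return A `scenario_result` tibble: one row per arm with lifetime cost,
#'   LY, QALY, cases and death probability, plus the incremental columns on
#'   the comparator row.
#' @examples
#' run_scenario(cutoff_scenarios()[1, ], baseline_parameters())
#' @export
run_scenario <- function(scenario, ps) {
  strat <- scenario_stratification(scenario, ps)
  current <- build_current_strategy(ps$config)
  tailored <- build_tailored_strategy(strat, ps$config)
  out_cur <- run_strategy(current, ps)
  out_tlr <- run_strategy(tailored, ps)
  ce <- icer(out_cur, out_tlr)
  res <- dplyr::bind_cols(
    tibble::tibble(scenario = scenario$name,
                   strategy = c(current$name, tailored$name)),
    dplyr::bind_rows(out_cur, out_tlr))
  res$delta_cost <- c(NA, ce$delta_cost)
  res$delta_ly <- c(NA, ce$delta_ly)
  res$delta_qaly <- c(NA, ce$delta_qaly)
  res$icer <- c(NA, ce$icer)
  res$quadrant <- c(NA, ce$quadrant)
  attr(res, "ce_result") <- ce
  attr(res, "tailored_strategy") <- tailored
  class(res) <- c("scenario_result", class(res))
  res
}

#' Full scenario table (all four built-in cutoff scenarios)
#'
#' @param ps A `parameter_set`.
#' @param scenarios Scenario tibble (default [cutoff_scenarios()]).
#' @return Stacked [run_scenario()] rows — the published-style summary table
#'   of costs and health outcomes per strategy and scenario.
#' @export
run_cea_table <- function(ps, scenarios = cutoff_scenarios()) {
  dplyr::bind_rows(purrr::map(seq_len(nrow(scenarios)), function(i)
    run_scenario(scenarios[i, ], ps)))
}

#' Ending-age variant of the baseline comparison
#'
#' Truncates the tailored programme's screening schedules so no screen
#' occurs after `end_age` (the cohort horizon itself is unchanged) and
#' recomputes the incremental result against the unchanged current
#' programme. `end_age = 74` is the baseline comparison; `end_age = 69`
#' mirrors the incumbent programme's ending age.
#'
#' @param end_age Last permitted screening age; 69 or 74.
#' @param ps A `parameter_set`.
#' @return A `ce_result` tibble.
#' @export
run_ending_age_variant <- function(end_age, ps) {
  if (!end_age %in% c(69L, 74L))
    rlang::abort("supported ending ages are 69 and 74",
                 class = "screencea_validation_error")
  current <- build_current_strategy(ps$config)
  tailored <- truncate_strategy(
    build_tailored_strategy(ps$strat, ps$config), end_age)
  icer(run_strategy(current, ps), run_strategy(tailored, ps))
}
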