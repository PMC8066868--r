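# Comparator screening programmes as explicit per-risk-group schedules.

#' Screening modality indicated at a given age
#'
#' The tailored programme uses breast self-examination below age 40,
#' ultrasound from 40 to 49 (denser breast tissue limits mammography), and
#' mammography from 50 onwards. Self-examination carries no cost and no
#' imaging sensitivity: a self-exam visit detects with the unscreened stage
#' distribution, exactly like an interval presentation.
#'
#' @param age Integer age(s) in years.
#' @return Character vector: `"self_exam"`, `"ultrasound"` or `"mammogram"`.
#' @examples
#' modality_for_age(c(36, 45, 60))
#' @export
modality_for_age <- function(age) {
  dplyr::case_when(
    age < 40 ~ "self_exam",
    age < 50 ~ "ultrasound",
    TRUE     ~ "mammogram"
  )
}

#' Build a screening schedule
#'
#' @param screen_ages Integer ages at which screens occur.
#' @param modality Either a single modality for all ages, or a function of
#'   age (default [modality_for_age()]).
#' @return A `screening_schedule` tibble with columns `age`, `modality`.
#' @export
screening_schedule <- function(screen_ages,
                               modality = modality_for_age) {
  screen_ages <- sort(unique(as.integer(screen_ages)))
  mod <- if (is.function(modality)) modality(screen_ages)
         else rep(modality, length(screen_ages))
  out <- tibble::tibble(age = screen_ages, modality = mod)
  class(out) <- c("screening_schedule", class(out))
  out
}

#' Current biennial mammogram-only strategy
#'
#' The incumbent programme: one population-wide arm (weight 1, incidence
#' multiplier 1) with mammograms every 2 years from age 50, the last screen
#' at 68 and none after 69. No entry costs.
#'
#' @param config Model configuration (list as in
#'   `baseline_parameters()$config`); only used for bounds checking.
#' @return A `strategy` object.
#' @examples
#' build_current_strategy()$arms$schedule[[1]]
#' @export
build_current_strategy <- function(config = baseline_parameters()$config) {
  sched <- screening_schedule(seq(50L, 68L, by = 2L), "mammogram")
  new_strategy(
    name = "current mammogram only",
    arms = tibble::tibble(
      group = "all", weight = 1, multiplier = 1,
      schedule = list(sched)
    ),
    entry_items = character(0)
  )
}

#' Polygenic risk-tailored strategy
#'
#' Three arms weighted by the risk stratification's population proportions,
#' with the group multipliers applied to incidence. Default screening
#' intensities: high risk annually from 35 to 74; intermediate risk every
#' 2 years from 36 (last screen 74); low risk every 3 years from 37 (last
#' screen 73). Modalities follow [modality_for_age()]. Entry costs (buccal
#' swab genotyping plus risk-factor questionnaire) are charged once per woman
#' at entry.
#'
#' @param strat Risk stratification tibble (`group`, `proportion`,
#'   `multiplier`, percentile columns), default the baseline's.
#' @param config Model configuration; supplies the age horizon.
#' @param intervals Named integer screening intervals in years per group.
#' @param start_offsets Named first-screen offsets (years after `start_age`)
#'   per group; the defaults place the last screens at ages 74/74/73.
#' @return A `strategy` object with three arms.
#' @examples
#' s <- build_tailored_strategy()
#' vapply(s$arms$schedule, nrow, integer(1))
#' @export
build_tailored_strategy <- function(strat = baseline_parameters()$strat,
                                    config = baseline_parameters()$config,
                                    intervals = c(high = 1L, intermediate = 2L,
                                                  low = 3L),
                                    start_offsets = c(high = 0L,
                                                      intermediate = 1L,
                                                      low = 2L)) {
  if (abs(sum(strat$proportion) - 1) > 1e-9)
    rlang::abort("risk-group proportions must sum to 1",
                 class = "screencea_validation_error")
  arms <- dplyr::mutate(
    strat[, c("group", "proportion", "multiplier")],
    schedule = purrr::map(.data$group, function(g) {
      ages <- seq(config$start_age + start_offsets[[g]], config$end_age,
                  by = intervals[[g]])
      screening_schedule(ages)
    })
  )
  names(arms)[names(arms) == "proportion"] <- "weight"
  new_strategy(
    name = "polygenic risk tailored",
    arms = arms,
    entry_items = c("buccal_swab", "questionnaire")
  )
}

#' @keywords internal
#' @noRd
new_strategy <- function(name, arms, entry_items,
                         uses_screened_distribution_at_screens = TRUE) {
  if (abs(sum(arms$weight) - 1) > 1e-9)
    rlang::abort("strategy arm weights must sum to 1",
                 class = "screencea_validation_error")
  structure(list(name = name, arms = arms, entry_items = entry_items,
                 uses_screened_distribution_at_screens =
                   uses_screened_distribution_at_screens),
            class = "strategy")
}

#' One-time entry cost of a strategy
#'
#' Sums the strategy's entry cost items (e.g. buccal swab, questionnaire)
#' at the prices in the parameter set, so sensitivity draws on test costs
#' propagate to entry costs.
#'
#' @param strategy A `strategy`.
#' @param ps A `parameter_set`.
#' @return Cost in SGD (scalar).
#' @export
entry_cost <- function(strategy, ps) {
  if (!length(strategy$entry_items)) return(0)
  sum(ps$test_costs$cost[match(strategy$entry_items, ps$test_costs$test)])
}

#' Truncate a strategy's screening schedules
#'
#' Drops all screens after `last_age`, e.g. to mirror the incumbent
#' programme's ending age of 69 in the tailored arm.
#'
#' @param strategy A `strategy`.
#' @param last_age Last permitted screening age.
#' @return The truncated `strategy`.
#' @export
truncate_strategy <- function(strategy, last_age) {
  strategy$arms$schedule <- purrr::map(
    strategy$arms$schedule,
    function(s) {
      out <- s[s$age <= last_age, ]
      class(out) <- class(s)
      out
    })
  strategy
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy> %s\n", x$name))
  for (i in seq_len(nrow(x$arms))) {
    sch <- x$arms$schedule[[i]]
    cat(sprintf("  %-13s weight %.2f, multiplier x%g, %d screens (ages %d-%d)\n",
                x$arms$group[i], x$arms$weight[i], x$arms$multiplier[i],
                nrow(sch), min(sch$age), max(sch$age)))
  }
  if (length(x$entry_items))
    cat(sprintf("  entry costs: %s\n", paste(x$entry_items, collapse = " + ")))
  invisible(x)
}
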