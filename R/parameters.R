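# Model parameters: typed representation, validation, I/O, and the bundled
# Singapore baseline (age-specific incidence, stage distributions, mortality,
# utilities, direct medical and test costs, polygenic risk stratification,
# run configuration, and the sensitivity-analysis bounds derived from them).

#' Breast cancer stages tracked by the model
#' @keywords internal
#' @noRd
.stages <- c("I", "II", "III", "IV")

#' Markov states in transition order
#' @keywords internal
#' @noRd
.states <- c("Healthy", "I", "II", "III", "IV", "Dead")

.risk_groups <- c("low", "intermediate", "high")

.test_types <- c("mammogram", "ultrasound", "self_exam", "buccal_swab",
                 "questionnaire")

#' Baseline model parameters (Singapore)
#'
#' Returns the bundled baseline parameter set for the Singaporean screening
#' population: age-specific breast cancer incidence rates by 5-year band,
#' screened/unscreened stage-at-diagnosis distributions, stage-specific annual
#' breast-cancer mortality plus a flat all-cause mortality rate, stage-specific
#' utility weights and annual direct medical costs, screening test costs,
#' the polygenic risk stratification (population proportions 0.51/0.41/0.08
#' with incidence multipliers 0.5/1/2), and the run configuration (ages 35-74,
#' annual cycles, 3% discounting, 80% imaging sensitivity).
#'
#' One-way sensitivity bounds (`osa_bounds`) use a row's published minimum and
#' maximum where available (costs vary by +/-30%, utilities by +/-0.1) and
#' 80%/120% of the baseline value otherwise; probabilities are capped at 1.
#' The probabilistic sensitivity specification (`psa_spec`) covers cost
#' parameters (Gamma) and stage utilities (Beta), moment-matched so the
#' distribution mean equals the baseline value.
#'
#' Note: the published Stage II utility range is internally inconsistent
#' (minimum equal to maximum at 0.63); the bundled bounds mirror Stage I
#' (0.63, 0.83).
#'
#' @return A `parameter_set` object: a named list with tibble components
#'   `asir`, `stage_dist`, `mortality`, `utilities`, `stage_costs`,
#'   `test_costs`, `strat`, `osa_bounds`, `psa_spec`, scalar
#'   `all_cause_mortality`, and list `config`.
#' @examples
#' ps <- baseline_parameters()
#' asir_lookup(ps, 52)
#' @export
baseline_parameters <- function() {
  ps <- list(
    asir = tibble::tibble(
      age_low  = c(35L, 40L, 45L, 50L, 55L, 60L, 65L, 70L, 75L, 80L, 85L),
      age_high = c(39L, 44L, 49L, 54L, 59L, 64L, 69L, 74L, 79L, 84L, 120L),
      rate = c(0.000617, 0.001114, 0.001733, 0.001775, 0.002073, 0.002119,
               0.002056, 0.002063, 0.001974, 0.001710, 0.001530)
    ),
    stage_dist = tibble::tibble(
      stage      = .stages,
      screened   = c(0.53, 0.43, 0.03, 0.01),
      unscreened = c(0.22, 0.57, 0.12, 0.09)
    ),
    mortality = tibble::tibble(
      stage = .stages,
      rate  = c(0.020, 0.044, 0.083, 0.268)
    ),
    all_cause_mortality = 0.002896,
    utilities = tibble::tibble(
      state   = c("Healthy", .stages),
      utility = c(1.000, 0.731, 0.731, 0.599, 0.352)
    ),
    stage_costs = tibble::tibble(
      stage = .stages,
      cost  = c(63983.00, 78226.00, 91129.00, 110136.00)
    ),
    test_costs = tibble::tibble(
      test = .test_types,
      cost = c(110.00, 230.00, 0.00, 210.00, 2.00)
    ),
    strat = tibble::tibble(
      group          = .risk_groups,
      percentile_low  = c(0, 60, 95),
      percentile_high = c(60, 95, 100),
      proportion     = c(0.51, 0.41, 0.08),
      multiplier     = c(0.5, 1, 2)
    ),
    config = list(
      start_age = 35L,
      end_age = 74L,
      cycle_length = 1,
      discount_rate = 0.03,
      mammography_sensitivity = 0.8,
      detection_mode = "screen_plus_interval",
      stage_cost_model = "annual",
      half_cycle_correction = FALSE
    )
  )
  ps$osa_bounds <- .baseline_osa_bounds(ps)
  ps$psa_spec <- .baseline_psa_spec(ps)
  structure(ps, class = "parameter_set")
}

# Published min/max where the source prints them; 80/120% of baseline elsewhere.
.baseline_osa_bounds <- function(ps) {
  costs <- ps$stage_costs$cost
  dplyr::bind_rows(
    tibble::tibble(
      parameter = paste0("multiplier_", .risk_groups),
      low  = 0.8 * ps$strat$multiplier,
      high = 1.2 * ps$strat$multiplier
    ),
    tibble::tibble(parameter = "mammography_sensitivity",
                   low = 0.64, high = 0.96),
    tibble::tibble(parameter = "discount_rate", low = 0.024, high = 0.036),
    tibble::tibble(
      parameter = paste0("cost_stage_", .stages),
      low  = c(44788.10, 54758.20, 63790.30, 77095.20),
      high = c(83177.90, 101693.80, 118467.70, 143175.80)
    ),
    tibble::tibble(
      parameter = paste0("cost_", c("mammogram", "ultrasound", "buccal_swab",
                                    "questionnaire")),
      low  = c(87.50, 161.00, 122.50, 1.40),
      high = c(162.50, 299.00, 227.50, 2.60)
    ),
    tibble::tibble(
      parameter = paste0("utility_", .stages),
      low  = c(0.63, 0.63, 0.499, 0.252),
      high = c(0.83, 0.83, 0.599, 0.452)
    ),
    tibble::tibble(
      parameter = paste0("mortality_stage_", .stages),
      low  = 0.8 * ps$mortality$rate,
      high = pmin(1.2 * ps$mortality$rate, 1)
    ),
    tibble::tibble(
      parameter = paste0("stage_dist_screened_", .stages),
      low  = 0.8 * ps$stage_dist$screened,
      high = pmin(1.2 * ps$stage_dist$screened, 1)
    ),
    tibble::tibble(
      parameter = paste0("stage_dist_unscreened_", .stages),
      low  = 0.8 * ps$stage_dist$unscreened,
      high = pmin(1.2 * ps$stage_dist$unscreened, 1)
    )
  )
}

# Only cost and utility parameters vary probabilistically.
.baseline_psa_spec <- function(ps) {
  ob <- .baseline_osa_bounds(ps)
  cost_ids <- c(paste0("cost_stage_", .stages),
                paste0("cost_", c("mammogram", "ultrasound", "buccal_swab",
                                  "questionnaire")))
  util_ids <- paste0("utility_", .stages)
  spec <- ob[ob$parameter %in% c(cost_ids, util_ids), ]
  spec$family <- ifelse(spec$parameter %in% util_ids, "beta", "gamma")
  spec$mean <- vapply(spec$parameter, function(id) param_get(ps, id),
                      numeric(1))
  spec[, c("parameter", "family", "mean", "low", "high")]
}

#' Validate a parameter set
#'
#' Checks every structural invariant: contiguous incidence bands covering the
#' model horizon with rates in \[0,1\]; stage distributions on the unit simplex
#' (within 1e-9); probabilities in \[0,1\]; Healthy utility fixed at 1 with
#' utilities non-increasing by stage; non-negative costs; risk-group
#' proportions summing to 1 with positive multipliers and percentile ranges
#' partitioning \[0,100\]; a sane run configuration; and that every parameter
#' named in `osa_bounds`/`psa_spec` resolves in the set.
#'
#' @param ps A `parameter_set`.
#' @return `ps`, invisibly. Aborts with a message naming the violated
#'   invariant otherwise.
#' @export
validate_parameters <- function(ps) {
  fail <- function(msg) rlang::abort(paste0("invalid parameter_set: ", msg),
                                     class = "screencea_validation_error")
  a <- ps$asir
  if (any(a$rate < 0 | a$rate > 1)) fail("asir rates must lie in [0,1]")
  if (is.unsorted(a$age_low)) fail("asir bands must be ordered by age")
  if (any(a$age_low[-1] != a$age_high[-nrow(a)] + 1L))
    fail("asir bands must be contiguous and non-overlapping")
  if (a$age_low[1] > ps$config$start_age || max(a$age_high) < ps$config$end_age)
    fail("asir bands must cover the model horizon")

  for (ctx in c("screened", "unscreened")) {
    p <- ps$stage_dist[[ctx]]
    if (any(p < 0 | p > 1))
      fail(sprintf("%s stage proportions must lie in [0,1]", ctx))
    if (abs(sum(p) - 1) > 1e-9)
      fail(sprintf("%s stage proportions must sum to 1 (got %.12g)", ctx,
                   sum(p)))
  }

  if (any(ps$mortality$rate < 0 | ps$mortality$rate > 1))
    fail("stage mortality rates must lie in [0,1]")
  if (ps$all_cause_mortality < 0 || ps$all_cause_mortality > 1)
    fail("all-cause mortality must lie in [0,1]")

  u <- ps$utilities
  if (u$utility[u$state == "Healthy"] != 1)
    fail("Healthy utility must equal 1")
  su <- u$utility[match(.stages, u$state)]
  if (any(su < 0 | su > 1)) fail("utilities must lie in [0,1]")
  if (is.unsorted(rev(su))) fail("utilities must be non-increasing with stage")

  if (any(ps$stage_costs$cost < 0) || any(ps$test_costs$cost < 0))
    fail("costs must be non-negative")

  s <- ps$strat
  if (abs(sum(s$proportion) - 1) > 1e-9)
    fail("risk-group proportions must sum to 1")
  if (any(s$multiplier <= 0)) fail("risk multipliers must be positive")
  if (s$percentile_low[1] != 0 || s$percentile_high[nrow(s)] != 100 ||
      any(s$percentile_low[-1] != s$percentile_high[-nrow(s)]))
    fail("percentile ranges must partition [0,100]")

  cfg <- ps$config
  if (cfg$discount_rate < 0 || cfg$discount_rate >= 1)
    fail("discount_rate must lie in [0,1)")
  if (cfg$start_age >= cfg$end_age) fail("start_age must precede end_age")
  if (cfg$mammography_sensitivity <= 0 || cfg$mammography_sensitivity > 1)
    fail("mammography_sensitivity must lie in (0,1]")
  if (!cfg$detection_mode %in% c("screen_only", "screen_plus_interval"))
    fail("detection_mode must be screen_only or screen_plus_interval")
  if (!cfg$stage_cost_model %in% c("annual", "once"))
    fail("stage_cost_model must be annual or once")

  for (id in unique(c(ps$osa_bounds$parameter, ps$psa_spec$parameter))) {
    ok <- tryCatch({param_get(ps, id); TRUE}, error = function(e) FALSE)
    if (!ok) fail(sprintf("sensitivity parameter '%s' does not resolve", id))
  }
  invisible(ps)
}

#' Look up the age-specific incidence rate
#'
#' Piecewise-constant lookup of the annual breast-cancer incidence probability
#' for the band containing each age.
#'
#' @param asir An age-rate tibble (`age_low`, `age_high`, `rate`) or a
#'   `parameter_set` (its `asir` component is used).
#' @param age Integer age(s) in years.
#' @return Numeric vector of annual probabilities, one per age.
#' @examples
#' asir_lookup(baseline_parameters(), c(37, 74))
#' @export
asir_lookup <- function(asir, age) {
  if (inherits(asir, "parameter_set")) asir <- asir$asir
  idx <- findInterval(age, asir$age_low)
  bad <- idx == 0L | age > asir$age_high[pmax(idx, 1L)]
  if (any(bad))
    rlang::abort(sprintf("age(s) %s outside the covered incidence bands",
                         paste(age[bad], collapse = ", ")),
                 class = "screencea_range_error")
  asir$rate[idx]
}

#' @export
print.parameter_set <- function(x, ...) {
  cfg <- x$config
  cat("<parameter_set>\n")
  cat(sprintf("  horizon: ages %d-%d, %g-year cycles, discount %.1f%%\n",
              cfg$start_age, cfg$end_age, cfg$cycle_length,
              100 * cfg$discount_rate))
  cat(sprintf("  detection: %s; stage costs charged: %s; sensitivity %.2f\n",
              cfg$detection_mode, cfg$stage_cost_model,
              cfg$mammography_sensitivity))
  cat(sprintf("  risk groups: %s\n",
              paste(sprintf("%s %.2f (x%g)", x$strat$group,
                            x$strat$proportion, x$strat$multiplier),
                    collapse = ", ")))
  cat(sprintf("  %d incidence bands; %d OSA parameters; %d PSA parameters\n",
              nrow(x$asir), nrow(x$osa_bounds), nrow(x$psa_spec)))
  invisible(x)
}

## ---- parameter registry -------------------------------------------------
## Flat ids addressing every scalar the sensitivity analyses perturb.

.param_registry <- function() {
  reg <- list(
    mammography_sensitivity = list(
      get = function(ps) ps$config$mammography_sensitivity,
      set = function(ps, v) {
        ps$config$mammography_sensitivity <- min(v, 1); ps
      }),
    discount_rate = list(
      get = function(ps) ps$config$discount_rate,
      set = function(ps, v) { ps$config$discount_rate <- v; ps }),
    all_cause_mortality = list(
      get = function(ps) ps$all_cause_mortality,
      set = function(ps, v) { ps$all_cause_mortality <- min(v, 1); ps })
  )
  for (g in .risk_groups) {
    reg[[paste0("multiplier_", g)]] <- local({
      gg <- g
      list(get = function(ps) ps$strat$multiplier[ps$strat$group == gg],
           set = function(ps, v) {
             ps$strat$multiplier[ps$strat$group == gg] <- v; ps
           })
    })
  }
  for (s in .stages) {
    reg[[paste0("cost_stage_", s)]] <- local({
      ss <- s
      list(get = function(ps) ps$stage_costs$cost[ps$stage_costs$stage == ss],
           set = function(ps, v) {
             ps$stage_costs$cost[ps$stage_costs$stage == ss] <- v; ps
           })
    })
    reg[[paste0("utility_", s)]] <- local({
      ss <- s
      list(get = function(ps) ps$utilities$utility[ps$utilities$state == ss],
           set = function(ps, v) {
             ps$utilities$utility[ps$utilities$state == ss] <- min(v, 1); ps
           })
    })
    reg[[paste0("mortality_stage_", s)]] <- local({
      ss <- s
      list(get = function(ps) ps$mortality$rate[ps$mortality$stage == ss],
           set = function(ps, v) {
             ps$mortality$rate[ps$mortality$stage == ss] <- min(v, 1); ps
           })
    })
    for (ctx in c("screened", "unscreened")) {
      reg[[paste0("stage_dist_", ctx, "_", s)]] <- local({
        ss <- s; cc <- ctx
        list(
          get = function(ps) ps$stage_dist[[cc]][ps$stage_dist$stage == ss],
          ## perturb one stage's proportion, renormalise the others so the
          ## simplex constraint survives
          set = function(ps, v) {
            v <- min(max(v, 0), 1)
            p <- ps$stage_dist[[cc]]
            i <- ps$stage_dist$stage == ss
            rest <- sum(p[!i])
            p[!i] <- if (rest > 0) p[!i] * (1 - v) / rest else (1 - v) / sum(!i)
            p[i] <- v
            ps$stage_dist[[cc]] <- p
            ps
          })
      })
    }
  }
  for (tt in setdiff(.test_types, "self_exam")) {
    reg[[paste0("cost_", tt)]] <- local({
      t0 <- tt
      list(get = function(ps) ps$test_costs$cost[ps$test_costs$test == t0],
           set = function(ps, v) {
             ps$test_costs$cost[ps$test_costs$test == t0] <- v; ps
           })
    })
  }
  reg
}

.registry_cache <- new.env(parent = emptyenv())

.reg <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- .param_registry()
  .registry_cache$reg
}

#' Get or set a named model parameter
#'
#' Flat accessors for the scalar parameters addressed by the sensitivity
#' analyses, e.g. `"cost_stage_II"`, `"utility_III"`, `"multiplier_low"`,
#' `"mammography_sensitivity"`, `"stage_dist_screened_I"`. Setters enforce
#' support: probabilities and utilities are capped at 1, and perturbing one
#' stage's proportion renormalises the remaining stages so the distribution
#' still sums to 1.
#'
#' @param ps A `parameter_set`.
#' @param parameter Parameter id (character scalar).
#' @param value Replacement value.
#' @return `param_get`: the scalar value. `param_set`: the modified
#'   `parameter_set`.
#' @export
param_get <- function(ps, parameter) {
  entry <- .reg()[[parameter]]
  if (is.null(entry))
    rlang::abort(sprintf("unknown parameter '%s'", parameter),
                 class = "screencea_unknown_parameter")
  entry$get(ps)
}

#' @rdname param_get
#' @export
param_set <- function(ps, parameter, value) {
  entry <- .reg()[[parameter]]
  if (is.null(entry))
    rlang::abort(sprintf("unknown parameter '%s'", parameter),
                 class = "screencea_unknown_parameter")
  entry$set(ps, value)
}

## ---- I/O -----------------------------------------------------------------

#' Write a parameter set to disk
#'
#' Serialises a parameter set as one structured YAML file
#' (`parameters.yml`) plus a delimited age-rate table (`asir.csv`,
#' columns `age_low`, `age_high`, `rate`).
#'
#' @param ps A `parameter_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(ps$asir), file.path(dir, "asir.csv"),
                   row.names = FALSE)
  payload <- list(
    stage_dist = lapply(split(ps$stage_dist, seq_len(nrow(ps$stage_dist))),
                        as.list),
    mortality = lapply(split(ps$mortality, seq_len(nrow(ps$mortality))),
                       as.list),
    all_cause_mortality = ps$all_cause_mortality,
    utilities = lapply(split(ps$utilities, seq_len(nrow(ps$utilities))),
                       as.list),
    stage_costs = lapply(split(ps$stage_costs, seq_len(nrow(ps$stage_costs))),
                         as.list),
    test_costs = lapply(split(ps$test_costs, seq_len(nrow(ps$test_costs))),
                        as.list),
    strat = lapply(split(ps$strat, seq_len(nrow(ps$strat))), as.list),
    config = ps$config,
    osa_bounds = lapply(split(ps$osa_bounds, seq_len(nrow(ps$osa_bounds))),
                        as.list),
    psa_spec = lapply(split(ps$psa_spec, seq_len(nrow(ps$psa_spec))), as.list)
  )
  names(payload$stage_dist) <- NULL
  for (nm in c("mortality", "utilities", "stage_costs", "test_costs", "strat",
               "osa_bounds", "psa_spec"))
    names(payload[[nm]]) <- NULL
  yaml::write_yaml(payload, file.path(dir, "parameters.yml"), precision = 15)
  invisible(dir)
}

#' Load a parameter set, falling back to the baseline for absent fields
#'
#' Reads a directory written by [write_parameters()] (or a bare
#' `parameters.yml`); any component absent from the file falls back to the
#' bundled baseline with a notice. The result is validated before return.
#'
#' @param source Directory containing `parameters.yml` (and optionally
#'   `asir.csv`), or a path to a YAML file.
#' @param quiet Suppress fallback notices.
#' @return A validated `parameter_set`.
#' @export
load_parameters <- function(source, quiet = FALSE) {
  note <- function(...) if (!quiet) message(sprintf(...))
  if (dir.exists(source)) {
    yml <- file.path(source, "parameters.yml")
    csv <- file.path(source, "asir.csv")
  } else {
    yml <- source
    csv <- file.path(dirname(source), "asir.csv")
  }
  if (!file.exists(yml))
    rlang::abort(sprintf("parameter file '%s' not found", yml),
                 class = "screencea_parse_error")
  raw <- tryCatch(yaml::read_yaml(yml), error = function(e)
    rlang::abort(sprintf("cannot parse '%s': %s", yml, conditionMessage(e)),
                 class = "screencea_parse_error"))
  ps <- baseline_parameters()

  rows_to_tibble <- function(rows, file, field) {
    out <- tryCatch(dplyr::bind_rows(lapply(rows, tibble::as_tibble)),
                    error = function(e)
      rlang::abort(sprintf("malformed table '%s' in %s: %s", field, file,
                           conditionMessage(e)),
                   class = "screencea_parse_error"))
    out
  }
  tab_fields <- c("stage_dist", "mortality", "utilities", "stage_costs",
                  "test_costs", "strat", "osa_bounds", "psa_spec")
  for (f in tab_fields) {
    if (!is.null(raw[[f]])) ps[[f]] <- rows_to_tibble(raw[[f]], yml, f)
    else note("field '%s' not in %s; using baseline", f, yml)
  }
  if (!is.null(raw$all_cause_mortality))
    ps$all_cause_mortality <- raw$all_cause_mortality
  else note("field 'all_cause_mortality' not in %s; using baseline", yml)
  if (!is.null(raw$config)) {
    for (k in names(raw$config)) ps$config[[k]] <- raw$config[[k]]
    missing_cfg <- setdiff(names(ps$config), names(raw$config))
    if (length(missing_cfg))
      note("config fields %s not in %s; using baseline",
           paste(missing_cfg, collapse = ", "), yml)
  } else note("field 'config' not in %s; using baseline", yml)
  if (file.exists(csv)) {
    asir <- tryCatch(
      utils::read.csv(csv, colClasses = c("integer", "integer", "numeric")),
      error = function(e)
        rlang::abort(sprintf("malformed table '%s': %s", csv,
                             conditionMessage(e)),
                     class = "screencea_parse_error"))
    if (!identical(names(asir), c("age_low", "age_high", "rate")))
      rlang::abort(sprintf(
        "malformed table '%s': expected columns age_low, age_high, rate", csv),
        class = "screencea_parse_error")
    ps$asir <- tibble::as_tibble(asir)
  } else note("no asir.csv alongside %s; using baseline incidence", yml)
  validate_parameters(ps)
  ps
}
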