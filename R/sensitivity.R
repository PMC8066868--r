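# One-way (tornado) and probabilistic sensitivity analysis with Gamma/Beta
# parameter distributions, cost-effectiveness plane draws and acceptability
# curves.

#' Moment-matched Gamma distribution for a cost parameter
#'
#' Fits a Gamma distribution whose mean equals the supplied mean and whose
#' standard deviation is `(high - low) / (2 * 1.96)` — the published range is
#' read as a 95% interval.
#'
#' @param mean Baseline (mean) value, > 0.
#' @param low,high Range limits, `0 < low < mean < high`.
#' @return A one-row `psa_distribution` tibble with the fitted `shape` and
#'   `rate`.
#' @examples
#' fit_gamma(110, 87.5, 162.5)
#' @export
fit_gamma <- function(mean, low, high) {
  if (!(low < high))
    rlang::abort("degenerate range: low must be strictly below high",
                 class = "screencea_validation_error")
  if (!(low > 0 && mean > 0))
    rlang::abort("gamma support must be positive",
                 class = "screencea_validation_error")
  sd <- (high - low) / (2 * 1.96)
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  tibble::tibble(family = "gamma", mean = mean, low = low, high = high,
                 sd = sd, shape = shape, rate = rate,
                 shape2 = NA_real_)
}

#' Moment-matched Beta distribution for a utility parameter
#'
#' Fits a Beta distribution on \[0,1\] with the supplied mean and standard
#' deviation `(high - low) / (2 * 1.96)`. If that standard deviation is
#' infeasible for the Beta family (variance must be below `mean * (1-mean)`),
#' it is shrunk to the largest feasible value and a notice is emitted.
#'
#' @param mean Baseline (mean) utility in (0,1).
#' @param low,high Range limits, `low < high`.
#' @return A one-row `psa_distribution` tibble with `shape` (alpha) and
#'   `shape2` (beta).
#' @examples
#' fit_beta(0.731, 0.63, 0.83)
#' @export
fit_beta <- function(mean, low, high) {
  if (!(mean > 0 && mean < 1))
    rlang::abort("beta mean must lie strictly inside (0,1)",
                 class = "screencea_validation_error")
  if (!(low < high))
    rlang::abort("degenerate range: low must be strictly below high",
                 class = "screencea_validation_error")
  sd <- (high - low) / (2 * 1.96)
  max_var <- mean * (1 - mean)
  if (sd^2 >= max_var) {
    sd <- sqrt(max_var) * 0.95
    message(sprintf(
      "beta sd infeasible for mean %.3f; shrunk to %.4f", mean, sd))
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  tibble::tibble(family = "beta", mean = mean, low = low, high = high,
                 sd = sd, shape = mean * nu, rate = NA_real_,
                 shape2 = (1 - mean) * nu)
}

.draw_parameter <- function(spec_row, n) {
  if (spec_row$high == spec_row$low) return(rep(spec_row$mean, n))
  if (spec_row$family == "gamma") {
    f <- fit_gamma(spec_row$mean, spec_row$low, spec_row$high)
    stats::rgamma(n, shape = f$shape, rate = f$rate)
  } else {
    f <- fit_beta(spec_row$mean, spec_row$low, spec_row$high)
    stats::rbeta(n, shape1 = f$shape, shape2 = f$shape2)
  }
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs the deterministic comparison twice with the parameter at its low
#' and high bound (all other parameters at baseline) and records the ICER at
#' each.
#'
#' @param parameter Parameter id present in `ps$osa_bounds`.
#' @param ps A `parameter_set`.
#' @param reference,comparator `strategy` objects (defaults: current
#'   programme vs risk-tailored programme).
#' @return A one-row `tornado_entry` tibble: `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`, and the quadrants at each bound.
#' @export
osa_run <- function(parameter, ps,
                    reference = build_current_strategy(ps$config),
                    comparator = build_tailored_strategy(ps$strat, ps$config)) {
  row <- ps$osa_bounds[ps$osa_bounds$parameter == parameter, ]
  if (nrow(row) != 1)
    rlang::abort(sprintf("parameter '%s' not present in osa_bounds",
                         parameter),
                 class = "screencea_unknown_parameter")
  eval_at <- function(v) {
    psv <- param_set(ps, parameter, v)
    icer(run_strategy(reference, psv), run_strategy(comparator, psv))
  }
  lo <- eval_at(row$low)
  hi <- eval_at(row$high)
  tibble::tibble(
    parameter = parameter, low = row$low, high = row$high,
    icer_at_low = lo$icer, icer_at_high = hi$icer,
    span = abs(hi$icer - lo$icer),
    quadrant_low = lo$quadrant, quadrant_high = hi$quadrant
  )
}

#' Full one-way sensitivity analysis (tornado table)
#'
#' Runs [osa_run()] for every parameter in `ps$osa_bounds` and returns the
#' entries sorted by decreasing ICER span (ties broken alphabetically, so
#' the ordering is deterministic).
#'
#' @inheritParams osa_run
#' @param parameters Parameter ids to vary (default: all of `osa_bounds`).
#' @return A `tornado` tibble, one row per parameter.
#' @export
run_osa <- function(ps,
                    reference = build_current_strategy(ps$config),
                    comparator = build_tailored_strategy(ps$strat, ps$config),
                    parameters = ps$osa_bounds$parameter) {
  out <- dplyr::bind_rows(purrr::map(parameters, osa_run, ps = ps,
                                     reference = reference,
                                     comparator = comparator))
  out <- dplyr::arrange(out, dplyr::desc(.data$span), .data$parameter)
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the PSA specification (`ps$psa_spec`:
#' Gamma-distributed costs, Beta-distributed utilities, moment-matched to
#' the baseline means) and re-evaluates both strategies under each draw —
#' the same draw is applied to both arms, so parameters are common. Because
#' only cost and utility parameters vary, cohort dynamics are unchanged
#' across draws and outcomes are exact linear functionals of the baseline
#' discounted exposures; `run_psa` exploits this and falls back to full
#' model re-runs if the specification ever names a dynamics parameter.
#'
#' All draws are generated up front in the fixed order of `psa_spec` from
#' the single seed, so results do not depend on evaluation order.
#'
#' @param ps A `parameter_set`.
#' @param reference,comparator `strategy` objects.
#' @param n Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed.
#' @return A `psa_result`: list with `draws` (tibble: `draw`, `delta_cost`,
#'   `delta_qaly`, plus one column per varied parameter), `n`, `seed`, and
#'   the deterministic `ce_result` at baseline.
#' @examples
#' ps <- baseline_parameters()
#' psa <- run_psa(ps, n = 100, seed = 1)
#' ceac(psa, wtp_grid = c(0, 1000))
#' @export
run_psa <- function(ps,
                    reference = build_current_strategy(ps$config),
                    comparator = build_tailored_strategy(ps$strat, ps$config),
                    n = 10000, seed = 1) {
  if (n <= 0)
    rlang::abort("number of PSA draws must be positive",
                 class = "screencea_validation_error")
  spec <- ps$psa_spec
  set.seed(seed)
  draw_mat <- vapply(seq_len(nrow(spec)),
                     function(i) .draw_parameter(spec[i, ], n), numeric(n))
  if (n == 1) draw_mat <- matrix(draw_mat, nrow = 1)
  colnames(draw_mat) <- spec$parameter

  linear_ids <- c(paste0("cost_stage_", .stages),
                  paste0("cost_", setdiff(.test_types, "self_exam")),
                  paste0("utility_", .stages))
  base_ref <- run_strategy(reference, ps)
  base_cmp <- run_strategy(comparator, ps)
  base_ce <- icer(base_ref, base_cmp)

  if (all(spec$parameter %in% linear_ids)) {
    coefs <- function(strategy, base) {
      l <- attr(base, "loadings")
      entry <- as.numeric(.test_types %in% strategy$entry_items)
      names(entry) <- .test_types
      cost_coef <- c(
        stats::setNames(l$stage_exposure, paste0("cost_stage_", .stages)),
        stats::setNames((l$screens_by_test + entry)[setdiff(.test_types,
                                                            "self_exam")],
                        paste0("cost_",
                               setdiff(.test_types, "self_exam"))))
      qaly_coef <- stats::setNames(l$py_state[.stages],
                                   paste0("utility_", .stages))
      list(cost = cost_coef, qaly = qaly_coef)
    }
    cr <- coefs(reference, base_ref)
    cc <- coefs(comparator, base_cmp)
    all_cost_ids <- names(cr$cost)
    all_util_ids <- names(cr$qaly)
    base_vals <- vapply(c(all_cost_ids, all_util_ids), param_get, numeric(1),
                        ps = ps)
    dcost_coef <- cc$cost - cr$cost
    dqaly_coef <- cc$qaly - cr$qaly
    centred <- function(ids, coef) {
      present <- intersect(ids, colnames(draw_mat))
      dev <- sweep(draw_mat[, present, drop = FALSE], 2,
                   base_vals[present], `-`)
      as.numeric(dev %*% coef[present])
    }
    delta_cost <- base_ce$delta_cost + centred(all_cost_ids, dcost_coef)
    delta_qaly <- base_ce$delta_qaly + centred(all_util_ids, dqaly_coef)
  } else {
    res <- purrr::map(seq_len(n), function(i) {
      psd <- ps
      for (p in spec$parameter) psd <- param_set(psd, p, draw_mat[i, p])
      ce <- icer(run_strategy(reference, psd), run_strategy(comparator, psd))
      c(ce$delta_cost, ce$delta_qaly)
    })
    delta_cost <- purrr::map_dbl(res, 1)
    delta_qaly <- purrr::map_dbl(res, 2)
  }

  draws <- dplyr::bind_cols(
    tibble::tibble(draw = seq_len(n), delta_cost = delta_cost,
                   delta_qaly = delta_qaly),
    tibble::as_tibble(draw_mat))
  structure(list(draws = draws, n = n, seed = seed, baseline = base_ce),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  pse <- mean(x$draws$delta_qaly > 0 & x$draws$delta_cost < 0)
  cat(sprintf("<psa_result> %d draws (seed %d)\n", x$n, x$seed))
  cat(sprintf("  mean dC = %.2f SGD, mean dQALY = %.4f; %.1f%% of draws in SE quadrant\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly), 100 * pse))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' non-negative incremental net monetary benefit
#' (`wtp * delta_qaly - delta_cost >= 0`).
#'
#' @param psa A `psa_result` (or its `draws` tibble).
#' @param wtp_grid Willingness-to-pay grid (SGD/QALY).
#' @return A `ceac` tibble: `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 5000, by = 50)) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  if (nrow(draws) < 1)
    rlang::abort("need at least one PSA draw",
                 class = "screencea_validation_error")
  probs <- vapply(wtp_grid, function(w)
    mean(w * draws$delta_qaly - draws$delta_cost >= 0), numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, probability = probs)
  class(out) <- c("ceac", class(out))
  out
}

#' Smallest willingness-to-pay with full acceptance
#'
#' The smallest grid value at which the acceptability curve reaches
#' probability 1 (i.e. every PSA draw is cost-effective).
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Grid to scan (default 0 to 20000 SGD/QALY in steps of 1).
#' @return Scalar WTP, or `Inf` if acceptance never reaches 1 on the grid.
#' @export
wtp_full_acceptance <- function(psa, wtp_grid = seq(0, 20000, by = 1)) {
  cc <- ceac(psa, wtp_grid)
  hit <- which(cc$probability >= 1)
  if (!length(hit)) return(Inf)
  cc$wtp[hit[1]]
}
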