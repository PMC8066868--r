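# Run configuration, delimited report outputs and the run manifest.

#' Run the full pipeline and write delimited report tables
#'
#' Executes the deterministic model for the baseline and every requested
#' cutoff scenario, the one-way sensitivity analysis, and a probabilistic
#' sensitivity analysis per scenario, writing plain delimited outputs plus a
#' JSON run manifest listing every file. Deterministic outputs reproduce
#' bit-for-bit on rerun; stochastic outputs reproduce given the seed.
#'
#' Files written: `cea_table.csv` (per-scenario, per-arm costs and health
#' outcomes with incremental columns), `trace_<strategy>.csv` (state
#' occupancy and per-age diagnoses, columns in the order produced by
#' [run_cohort()]), `tornado.csv`, `psa_draws_<scenario>.csv` (draw id and
#' CE-plane coordinates), `ceac_<scenario>.csv`, and `manifest.json`.
#'
#' @param out_dir Output directory (created if missing).
#' @param ps A `parameter_set`.
#' @param scenarios Scenario tibble (default [cutoff_scenarios()]).
#' @param n_draws PSA draws per scenario.
#' @param seed Integer seed for the PSA.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves.
#' @param osa Run the one-way sensitivity analysis (default TRUE).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest as a list.
#' @export
run_report <- function(out_dir, ps = baseline_parameters(),
                       scenarios = cutoff_scenarios(),
                       n_draws = 1000, seed = 1,
                       wtp_grid = seq(0, 5000, by = 25),
                       osa = TRUE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  validate_parameters(ps)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, name)
  }

  say("deterministic model: %d scenarios", nrow(scenarios))
  cea_tab <- run_cea_table(ps, scenarios)
  emit(cea_tab, "cea_table.csv")

  current <- build_current_strategy(ps$config)
  tailored <- build_tailored_strategy(ps$strat, ps$config)
  emit(run_cohort(current$arms$schedule[[1]], 1, ps), "trace_current.csv")
  for (i in seq_len(nrow(tailored$arms)))
    emit(run_cohort(tailored$arms$schedule[[i]],
                    tailored$arms$multiplier[i], ps),
         sprintf("trace_tailored_%s.csv", tailored$arms$group[i]))

  if (osa) {
    say("one-way sensitivity analysis: %d parameters", nrow(ps$osa_bounds))
    emit(run_osa(ps), "tornado.csv")
  }

  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    say("PSA %s: %d draws", sc$name, n_draws)
    strat <- scenario_stratification(sc, ps)
    psa <- run_psa(ps, comparator = build_tailored_strategy(strat, ps$config),
                   n = n_draws, seed = seed)
    emit(psa$draws[, c("draw", "delta_cost", "delta_qaly")],
         sprintf("psa_draws_%s.csv", sc$name))
    emit(ceac(psa, wtp_grid), sprintf("ceac_%s.csv", sc$name))
  }

  manifest <- list(
    package = "screencea",
    version = as.character(utils::packageVersion("screencea")),
    seed = seed, n_draws = n_draws,
    scenarios = scenarios$name,
    config = ps$config,
    outputs = files,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
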