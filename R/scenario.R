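#' Scenario configuration
#'
#' Bundles every knob of an end-to-end run. `scenario` selects the phase
#' parameter transform: `"main"` (base case), `"sensitivity_100"` (+100%
#' phase III costs and all phase durations), `"adaptive_50"` /
#' `"adaptive_100"` (50% / 100% of trials adaptive).
#'
#' @param option_id Design option, 1, 2 or 3.
#' @param scenario One of `"main"`, `"sensitivity_100"`, `"adaptive_50"`,
#'   `"adaptive_100"`.
#' @param n_runs Monte Carlo runs (the analysis uses 100).
#' @param seed Master seed. Portfolio generation uses `seed`, the epi
#'   generator `seed + 1`, and Monte Carlo run `r` uses `seed + 100 + r - 1`.
#' @param perspectives Perspectives to summarise.
#' @param discount_rate Annual discount rate.
#' @param end_year Last benefit year.
#' @param discount_outcomes Discount health outcomes alongside costs?
#' @param archetype_split See [default_archetype_split()].
#' @param epi_ranges See [default_epi_ranges()].
#' @param des Simulation window/replenishment, a [des_config()].
#' @param vaccine Procurement assumptions, a [vaccine_params()].
#' @return List of class `run_config`.
#' @export
scenario_config <- function(option_id = 1, scenario = "main", n_runs = 100,
                            seed = 1,
                            perspectives = c("societal", "altruistic"),
                            discount_rate = 0.03, end_year = 2035,
                            discount_outcomes = TRUE,
                            archetype_split = default_archetype_split(),
                            epi_ranges = default_epi_ranges(),
                            des = des_config(),
                            vaccine = vaccine_params()) {
  scenarios <- c("main", "sensitivity_100", "adaptive_50", "adaptive_100")
  if (!scenario %in% scenarios) {
    stop("unknown scenario '", scenario, "'; expected one of: ",
         paste(scenarios, collapse = ", "))
  }
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (!option_id %in% 1:3) stop("unknown design option: ", option_id)
  structure(list(option_id = option_id, scenario = scenario, n_runs = n_runs,
                 seed = seed, perspectives = perspectives,
                 discount_rate = discount_rate, end_year = end_year,
                 discount_outcomes = discount_outcomes,
                 archetype_split = archetype_split, epi_ranges = epi_ranges,
                 des = des, vaccine = vaccine),
            class = "run_config")
}

#' Phase parameters implied by a scenario name
#'
#' @param scenario Scenario name, see [scenario_config()].
#' @param phase_params Base table to transform.
#' @return Transformed `phase_params`.
#' @export
scenario_phase_params <- function(scenario, phase_params = base_phase_params()) {
  switch(scenario,
         main = phase_params,
         sensitivity_100 = apply_sensitivity(phase_params, 1, 1),
         adaptive_50 = apply_efficiency(phase_params, 0.5),
         adaptive_100 = apply_efficiency(phase_params, 1),
         stop("unknown scenario: ", scenario))
}

# Mean yearly series of a column across runs (internal): sums the column
# over diseases within each run-year, then averages over runs (runs without
# launches contribute zeros).
mean_yearly <- function(per_run_benefits, column, n_runs) {
  years <- sort(unique(unlist(lapply(per_run_benefits, function(b) b$year))))
  if (!length(years)) return(setNames(numeric(0), character(0)))
  acc <- setNames(numeric(length(years)), years)
  for (b in per_run_benefits) {
    if (!nrow(b)) next
    s <- tapply(b[[column]], b$year, sum)
    acc[names(s)] <- acc[names(s)] + s
  }
  acc / n_runs
}

#' Run one scenario end to end
#'
#' Generates (or accepts) a portfolio and disease-parameter table, applies
#' the scenario's phase-parameter transform, runs the Monte Carlo pipeline
#' simulation, computes averted outcomes per run (first-launch attribution
#' per disease and product class) and averages them, assembles the cost
#' schedules and produces an [economic_summary()] per perspective.
#'
#' @param config A [scenario_config()].
#' @param portfolio Optional pre-built `portfolio_spec` (otherwise
#'   generated).
#' @param epi Optional pre-built `epi_params` table (otherwise generated).
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there (CSV/JSON).
#' @return List of class `scenario_result`: `config`, `portfolio`, `epi`,
#'   `phase_params`, `mc` (an `mc_summary`), `benefits` (mean yearly
#'   series), `cost_schedules`, `economics` (one `economic_summary` per
#'   perspective).
#' @export
run_scenario <- function(config = scenario_config(), portfolio = NULL,
                         epi = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  pp <- scenario_phase_params(config$scenario)
  if (is.null(portfolio)) {
    portfolio <- generate_portfolio(config$option_id, config$archetype_split,
                                    seed = config$seed, phase_params = pp)
  }
  if (is.null(epi)) {
    epi <- generate_disease_params(option_diseases(config$option_id),
                                   config$epi_ranges, seed = config$seed + 1)
  }
  message(sprintf("[%s] portfolio: %d candidates, %d diseases",
                  format(Sys.time(), "%H:%M:%S"), sum(portfolio$count),
                  length(unique(portfolio$disease))))

  mc <- run_monte_carlo(portfolio, pp, config$des, n_runs = config$n_runs,
                        base_seed = config$seed + 100, keep_runs = TRUE)
  message(sprintf("[%s] DES: %.1f mean launches over %d runs",
                  format(Sys.time(), "%H:%M:%S"), mc$mean_total_launches,
                  mc$n_runs))

  per_run <- lapply(mc$runs, function(r)
    benefits_for_launches(r$launches, epi, end_year = config$end_year))
  benefits <- list(
    cases_averted = mean_yearly(per_run, "cases_averted", config$n_runs),
    deaths_averted = mean_yearly(per_run, "deaths_averted", config$n_runs),
    dalys_averted = mean_yearly(per_run, "dalys_averted", config$n_runs),
    yll_averted = mean_yearly(per_run, "yll_averted", config$n_runs),
    yld_averted = mean_yearly(per_run, "yld_averted", config$n_runs),
    treatment_costs_averted = mean_yearly(per_run, "treatment_costs_averted",
                                          config$n_runs))

  mech <- mechanism_cost_schedule(mechanism_cost_params(
    config$option_id,
    ops_years = config$des$horizon_start:config$des$horizon_end))
  procurement <- procurement_costs(benefits$cases_averted, config$vaccine)
  cost_schedules <- lapply(setNames(nm = config$perspectives), function(p)
    total_cost_schedule(p, mech, mc$mean_spend_by_year, procurement))

  economics <- lapply(setNames(nm = config$perspectives), function(p)
    economic_summary(config$option_id, p, cost_schedules[[p]],
                     benefits$treatment_costs_averted,
                     benefits$dalys_averted, benefits$deaths_averted,
                     rate = config$discount_rate,
                     base_year = config$des$horizon_start,
                     discount_outcomes = config$discount_outcomes))
  message(sprintf("[%s] done in %.1fs", format(Sys.time(), "%H:%M:%S"),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  res <- structure(list(config = config, portfolio = portfolio, epi = epi,
                        phase_params = pp, mc = mc, benefits = benefits,
                        cost_schedules = cost_schedules,
                        economics = economics),
                   class = "scenario_result")
  if (!is.null(out_dir)) write_scenario_outputs(res, out_dir)
  res
}

# Write all artifacts of a scenario run (internal; used by run_scenario and
# the CLI).
write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_portfolio_csv(res$portfolio, file.path(out_dir, "portfolio.csv"))
  write_epi_csv(res$epi, file.path(out_dir, "epi.csv"))
  launches <- do.call(rbind, lapply(seq_along(res$mc$runs), function(r) {
    l <- res$mc$runs[[r]]$launches
    if (nrow(l)) l$run <- r
    l
  }))
  utils::write.csv(launches, file.path(out_dir, "launches.csv"),
                   row.names = FALSE)
  spend <- data.frame(year = as.integer(names(res$mc$mean_spend_by_year)),
                      spend_musd = as.numeric(res$mc$mean_spend_by_year))
  utils::write.csv(spend, file.path(out_dir, "spend_by_year.csv"),
                   row.names = FALSE)
  yrs <- names(res$benefits$dalys_averted)
  averted <- data.frame(year = as.integer(yrs))
  for (nm in names(res$benefits)) averted[[nm]] <- as.numeric(res$benefits[[nm]])
  utils::write.csv(averted, file.path(out_dir, "averted_by_year.csv"),
                   row.names = FALSE)
  summaries <- lapply(res$economics, unclass)
  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Comparison table across design options
#'
#' Assembles a table with one column per scenario result: portfolio size,
#' expected phase III entrants and launches, discounted phase III costs, net
#' costs and benefits, BCR, DALYs and deaths averted, cost per DALY and per
#' death, and the ICER of each option against the previous column.
#'
#' @param results List of `scenario_result` objects (>= 1), ordered for the
#'   incremental comparison.
#' @param perspective Which perspective's summaries to tabulate.
#' @return `data.frame` with a `metric` column and one column per option.
#' @export
make_report <- function(results, perspective = "societal") {
  if (!length(results)) stop("no scenario results to report")
  cols <- lapply(results, function(res) {
    ec <- res$economics[[perspective]]
    if (is.null(ec)) stop("no summary for perspective '", perspective, "'")
    p3 <- discount(res$mc$mean_spend_by_year * 1e6,
                   rate = ec$discount_rate, base_year = ec$base_year)
    c(candidates = sum(res$portfolio$count),
      phase3_entrants = res$mc$mean_phase3_entrants,
      launches = res$mc$mean_total_launches,
      phase3_costs_busd = p3 / 1e9,
      net_cost_busd = ec$net_cost / 1e9,
      net_benefit_busd = ec$net_benefit / 1e9,
      bcr = ec$bcr,
      dalys_averted_m = ec$dalys_averted / 1e6,
      deaths_averted_m = ec$deaths_averted / 1e6,
      cost_per_daly = ec$cost_per_daly,
      cost_per_death = ec$cost_per_death,
      icer_vs_previous = NA_real_)
  })
  for (i in seq_along(results)[-1]) {
    cols[[i]]["icer_vs_previous"] <- icer(
      results[[i]]$economics[[perspective]],
      results[[i - 1]]$economics[[perspective]])
  }
  out <- data.frame(metric = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    out[[paste0("option_", results[[i]]$config$option_id)]] <- unname(cols[[i]])
  }
  out
}
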