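#' Simulation configuration
#'
#' @param horizon_start,horizon_end First and last calendar year of the
#'   simulation window (inclusive). Launches are counted if they occur in a
#'   calendar year within the window.
#' @param replenish Logical; inject new early-stage candidates?
#' @param replenish_rate New candidates per archetype per replenishment year.
#' @param replenish_years Calendar years in which replenishment occurs.
#' @return List of class `des_config`.
#' @export
des_config <- function(horizon_start = 2019, horizon_end = 2030,
                       replenish = TRUE, replenish_rate = 10,
                       replenish_years = 2019:2023) {
  if (horizon_end < horizon_start) stop("horizon end before start")
  structure(list(horizon_start = horizon_start, horizon_end = horizon_end,
                 replenish = replenish, replenish_rate = replenish_rate,
                 replenish_years = replenish_years),
            class = "des_config")
}

#' Replenishment cohort for one calendar year
#'
#' For each replenishment year, `replenish_rate` new candidates per
#' archetype present in the portfolio enter the pipeline at that archetype's
#' earliest active phase (preclinical wherever the archetype has one).
#' Target diseases are assigned uniformly over `diseases` using the current
#' RNG stream.
#'
#' @param portfolio A `portfolio_spec` (defines the archetypes present).
#' @param config A [des_config()].
#' @param year Calendar year.
#' @param diseases Disease pool for the new candidates; defaults to those in
#'   the portfolio.
#' @param phase_params Phase parameter table.
#' @return `data.frame` with columns `disease`, `archetype`, `phase`,
#'   `entry_time` (possibly zero rows).
#' @export
replenish <- function(portfolio, config, year,
                      diseases = unique(portfolio$disease),
                      phase_params = base_phase_params()) {
  if (!config$replenish || !(year %in% config$replenish_years)) {
    return(data.frame(disease = character(0), archetype = character(0),
                      phase = character(0), entry_time = numeric(0)))
  }
  archs <- sort(unique(portfolio$archetype[portfolio$count > 0]))
  n <- config$replenish_rate
  if (!length(archs)) {
    return(data.frame(disease = character(0), archetype = character(0),
                      phase = character(0), entry_time = numeric(0)))
  }
  out <- data.frame(
    disease = sample(diseases, length(archs) * n, replace = TRUE),
    archetype = rep(archs, each = n),
    phase = rep(vapply(archs, function(a)
      archetype_phases(a, phase_params)[1], character(1)), each = n),
    entry_time = year - config$horizon_start,
    stringsAsFactors = FALSE)
  out
}

# Expand a portfolio into one row per candidate (internal).
expand_candidates <- function(portfolio) {
  idx <- rep(seq_len(nrow(portfolio)), portfolio$count)
  data.frame(disease = portfolio$disease[idx],
             archetype = portfolio$archetype[idx],
             phase = portfolio$phase_at_start[idx],
             entry_time = rep(0, length(idx)),
             stringsAsFactors = FALSE)
}

# Spread an amount uniformly over the calendar years spanned by
# [t0, t0 + len) (times in years since horizon start); returns a named
# vector keyed by calendar year.
spread_over_years <- function(amount, t0, len, start_year) {
  if (len <= 0) {
    return(setNames(amount, as.character(start_year + floor(t0))))
  }
  ks <- floor(t0):floor(t0 + len - 1e-12)
  overlap <- pmin(t0 + len, ks + 1) - pmax(t0, ks)
  setNames(amount * overlap / len, as.character(start_year + ks))
}

#' Run the pipeline simulation once
#'
#' Every candidate is an independent entity: it sits in each successive
#' active phase of its archetype for that phase's duration, then draws a
#' Bernoulli success with the phase's probability. Failure removes the
#' candidate; success moves it on. A launch is recorded when a candidate
#' successfully exits its final active phase (phase III for archetypes that
#' have one) in a calendar year inside the horizon; the product enters the
#' global market one year after launch. Phase servers have infinite
#' capacity, so candidates never interact.
#'
#' Phase III costs are booked for every candidate that *enters* phase III
#' within the horizon — trial costs are sunk whether or not the trial
#' succeeds — and are spread uniformly over the calendar years the phase
#' spans.
#'
#' Success draws are consumed in a fixed per-candidate order and the walk is
#' never cut short by the horizon, so under a shared seed lengthening phase
#' durations can only delay or drop launches, never create them.
#'
#' @param portfolio A `portfolio_spec`.
#' @param phase_params Phase parameter table (possibly transformed by
#'   [apply_sensitivity()] / [apply_efficiency()]).
#' @param config A [des_config()].
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return List of class `simulation_result`: `launches` (data.frame with
#'   `disease`, `archetype`, `class`, `launch_time`, `launch_year`,
#'   `market_entry_year`), `phase3_spend_by_year` (named numeric, 2020 USD
#'   millions), `phase3_entrants`, `n_candidates`.
#' @export
simulate_once <- function(portfolio, phase_params = base_phase_params(),
                          config = des_config(), seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  start_year <- config$horizon_start
  horizon_len <- config$horizon_end - config$horizon_start + 1

  cands <- expand_candidates(portfolio)
  if (config$replenish) {
    for (yr in sort(config$replenish_years)) {
      cands <- rbind(cands, replenish(portfolio, config, yr,
                                      phase_params = phase_params))
    }
  }

  tabs <- lapply(setNames(nm = unique(cands$archetype)),
                 archetype_walk_table, phase_params = phase_params)

  launches <- vector("list", nrow(cands))
  spend <- numeric(0)
  entrants <- 0L
  for (i in seq_len(nrow(cands))) {
    tab <- tabs[[cands$archetype[i]]]
    j0 <- match(cands$phase[i], tab$phase)
    if (is.na(j0)) {
      stop("candidate in phase '", cands$phase[i],
           "' which archetype '", cands$archetype[i], "' lacks")
    }
    t <- cands$entry_time[i]
    ok <- TRUE
    for (j in j0:nrow(tab)) {
      if (tab$phase[j] == "phase3" && t < horizon_len) {
        entrants <- entrants + 1L
        s <- spread_over_years(tab$cost[j], t, tab$length[j], start_year)
        for (k in names(s)) spend[k] <- sum(spend[k], s[[k]], na.rm = TRUE)
      }
      t <- t + tab$length[j]
      if (stats::runif(1) > tab$p_success[j]) { ok <- FALSE; break }
    }
    if (ok && t < horizon_len) {
      launches[[i]] <- data.frame(
        disease = cands$disease[i], archetype = cands$archetype[i],
        launch_time = t, stringsAsFactors = FALSE)
    }
  }
  launches <- do.call(rbind, launches)
  if (is.null(launches)) {
    launches <- data.frame(disease = character(0), archetype = character(0),
                           launch_time = numeric(0))
  }
  launches$class <- if (nrow(launches)) archetype_class(launches$archetype) else character(0)
  launches$launch_year <- start_year + floor(launches$launch_time)
  launches$market_entry_year <- launches$launch_year + 1
  spend <- spend[order(as.integer(names(spend)))]
  structure(list(launches = launches, phase3_spend_by_year = spend,
                 phase3_entrants = entrants, n_candidates = nrow(cands)),
            class = "simulation_result")
}

#' Monte Carlo aggregation of pipeline runs
#'
#' Repeats [simulate_once()] with per-run seeds `base_seed + run - 1` and
#' aggregates launches to mean and SD per archetype per launch year, plus
#' the mean phase III spend per calendar year.
#'
#' @inheritParams simulate_once
#' @param n_runs Number of Monte Carlo runs (the analysis uses 100).
#' @param base_seed Integer; run `r` uses seed `base_seed + r - 1`.
#' @param keep_runs Keep the individual `simulation_result`s (needed by the
#'   benefits layer)?
#' @return List of class `mc_summary`: `launches_by_archetype_year`
#'   (data.frame `archetype`, `year`, `mean`, `sd`), `mean_total_launches`,
#'   `sd_total_launches`, `mean_phase3_entrants`, `mean_spend_by_year`,
#'   `n_runs`, and `runs` when `keep_runs = TRUE`.
#' @export
run_monte_carlo <- function(portfolio, phase_params = base_phase_params(),
                            config = des_config(), n_runs = 100, base_seed,
                            keep_runs = FALSE) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  stopifnot(!missing(base_seed))
  runs <- lapply(seq_len(n_runs), function(r) {
    simulate_once(portfolio, phase_params, config, seed = base_seed + r - 1)
  })

  years <- config$horizon_start:config$horizon_end
  archs <- sort(unique(portfolio$archetype))
  grid <- expand.grid(archetype = archs, year = years,
                      stringsAsFactors = FALSE)
  counts <- sapply(runs, function(res) {
    l <- res$launches
    key <- paste(l$archetype, l$launch_year)
    tab <- table(key)
    as.numeric(tab[paste(grid$archetype, grid$year)])
  })
  counts[is.na(counts)] <- 0
  counts <- matrix(counts, nrow = nrow(grid))
  grid$mean <- rowMeans(counts)
  grid$sd <- apply(counts, 1, stats::sd)
  if (n_runs == 1L) grid$sd <- 0

  spend_years <- sort(unique(unlist(lapply(runs, function(r)
    names(r$phase3_spend_by_year)))))
  spend_mat <- sapply(runs, function(r)
    r$phase3_spend_by_year[spend_years])
  spend_mat[is.na(spend_mat)] <- 0
  spend_mat <- matrix(spend_mat, nrow = length(spend_years))
  mean_spend <- setNames(rowMeans(spend_mat), spend_years)

  totals <- vapply(runs, function(r) nrow(r$launches), numeric(1))
  out <- list(
    launches_by_archetype_year = grid,
    mean_total_launches = mean(totals),
    sd_total_launches = if (n_runs > 1) stats::sd(totals) else 0,
    mean_phase3_entrants = mean(vapply(runs, `[[`, numeric(1), "phase3_entrants")),
    mean_spend_by_year = mean_spend,
    n_runs = n_runs)
  if (keep_runs) out$runs <- runs
  structure(out, class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Monte Carlo pipeline summary (", x$n_runs, " runs)\n", sep = "")
  cat("  mean launches: ", round(x$mean_total_launches, 2),
      " (sd ", round(x$sd_total_launches, 2), ")\n", sep = "")
  cat("  mean phase III entrants: ", round(x$mean_phase3_entrants, 2), "\n",
      sep = "")
  cat("  mean phase III spend: US$",
      round(sum(x$mean_spend_by_year) / 1000, 2), " billion\n", sep = "")
  invisible(x)
}
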