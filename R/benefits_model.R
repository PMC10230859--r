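#' Years of life lost per death
#'
#' Death-weighted mean residual life expectancy across age groups:
#' `sum_a(D_a * L_a) / sum_a D_a`.
#'
#' @param params `epi_params` rows for one disease.
#' @return YLL per death, years.
#' @export
yll_per_death <- function(params) {
  D <- sum(params$deaths)
  if (D <= 0) stop("total deaths must be positive to define YLL per death")
  sum(params$deaths * params$life_expectancy) / D
}

#' Years lived with disability per case
#'
#' Incidence-weighted disability time per case,
#' `sum_a(I_a * T_a * DW) / sum_a I_a`, with the untreated
#' (`yld_per_untreated_case`) or treated (`yld_per_treated_case`) duration
#' and disability weight.
#'
#' @param params `epi_params` rows for one disease.
#' @return YLD per case, years.
#' @export
yld_per_untreated_case <- function(params) {
  I <- sum(params$incidence)
  if (I <= 0) stop("total incidence must be positive to define YLD per case")
  sum(params$incidence * params$dur_untreated * params$dw_untreated) / I
}

#' @rdname yld_per_untreated_case
#' @export
yld_per_treated_case <- function(params) {
  I <- sum(params$incidence)
  if (I <= 0) stop("total incidence must be positive to define YLD per case")
  sum(params$incidence * params$dur_treated * params$dw_treated) / I
}

#' Disease-level rate summary
#'
#' Aggregates an `epi_params` table for one disease over age groups into the
#' scalar rates the benefit equations consume. Shared proportions (coverage,
#' case fatality, treatment cost) are incidence-weighted means, which equal
#' the common value when they are age-invariant.
#'
#' @param params `epi_params` rows for one disease.
#' @return List: `I` (annual incidence), `CB` (baseline coverage), `CFR`,
#'   `CFRT`, `K` (treatment cost/case), `yll` (per death), `yld_untreated`,
#'   `yld_treated` (per case).
#' @export
disease_rates <- function(params) {
  stopifnot(length(unique(params$disease)) == 1L)
  I <- sum(params$incidence)
  w <- params$incidence / I
  list(I = I,
       CB = sum(w * params$coverage_baseline),
       CFR = sum(w * params$cfr_untreated),
       CFRT = sum(w * params$cfr_treated),
       K = sum(w * params$treatment_cost),
       yll = yll_per_death(params),
       yld_untreated = yld_per_untreated_case(params),
       yld_treated = yld_per_treated_case(params))
}

#' Incidence trajectory under a new vaccine
#'
#' A vaccine reduces annual incidence by 10 percentage points of the
#' base-case level in its first market year and by a further 10 points each
#' subsequent year, capped at a 90% reduction (reached in year 9 of the
#' ramp). Before market entry incidence equals the base case.
#'
#' @param IB_series Named numeric vector of base-case incidence keyed by
#'   calendar year.
#' @param market_entry_year First calendar year the vaccine is on the
#'   market; `NA` means no vaccine (returns `IB_series` unchanged).
#' @return Numeric vector of with-vaccine incidence, same names.
#' @export
incidence_with_vaccine <- function(IB_series, market_entry_year) {
  years <- as.numeric(names(IB_series))
  stopifnot(!any(is.na(years)))
  if (is.na(market_entry_year)) return(IB_series)
  t <- years - market_entry_year + 1
  red <- ifelse(t >= 1, pmin(0.1 * t, 0.9), 0)
  IB_series * (1 - red)
}

#' Treatment coverage under a new therapeutic/diagnostic
#'
#' Coverage rises by 10 percentage points in the first market year and by a
#' further 10 points each subsequent year, to a maximum attainment of 90%.
#' Baseline coverage above 90% is never reduced by the cap.
#'
#' @param CB Baseline coverage in \[0, 1\] (scalar or per-year vector).
#' @param market_entry_year First market year; `NA` means no product.
#' @param year Calendar year(s) to evaluate.
#' @return Coverage in \[0, 1\] for each `year`.
#' @export
coverage_with_product <- function(CB, market_entry_year, year) {
  stopifnot(all(CB >= 0 & CB <= 1))
  if (is.na(market_entry_year)) return(rep(CB, length.out = length(year)))
  t <- year - market_entry_year + 1
  ramped <- pmin(CB + 0.1 * pmax(t, 0), pmax(0.9, CB))
  ifelse(t >= 1, ramped, CB)
}

#' Build a disease scenario trajectory
#'
#' Year-by-year base-case vs with-product incidence and coverage from the
#' first market entry through `end_year`. Base-case incidence and coverage
#' are held constant at the input values (no secular trend).
#'
#' @param rates Output of [disease_rates()].
#' @param vaccine_entry_year,treatment_entry_year Calendar year of market
#'   entry of the first vaccine / first therapeutic-or-diagnostic for this
#'   disease (`NA` if none).
#' @param start_year First year of the table (defaults to earliest entry).
#' @param end_year Last benefit year (2035 in the base analysis).
#' @return `data.frame` with columns `year`, `IB`, `IV`, `CB`, `CD`.
#' @export
build_trajectory <- function(rates, vaccine_entry_year = NA,
                             treatment_entry_year = NA,
                             start_year = NULL, end_year = 2035) {
  if (is.null(start_year)) {
    start_year <- suppressWarnings(
      min(vaccine_entry_year, treatment_entry_year, na.rm = TRUE))
    if (!is.finite(start_year)) {
      return(data.frame(year = numeric(0), IB = numeric(0), IV = numeric(0),
                        CB = numeric(0), CD = numeric(0)))
    }
  }
  if (start_year > end_year) {
    return(data.frame(year = numeric(0), IB = numeric(0), IV = numeric(0),
                      CB = numeric(0), CD = numeric(0)))
  }
  years <- start_year:end_year
  IB <- setNames(rep(rates$I, length(years)), years)
  data.frame(
    year = years,
    IB = as.numeric(IB),
    IV = as.numeric(incidence_with_vaccine(IB, vaccine_entry_year)),
    CB = rates$CB,
    CD = coverage_with_product(rates$CB, treatment_entry_year, years))
}

# Bracketed deaths terms shared by the deaths/YLL equations (internal).
deaths_base <- function(traj, rates) {
  traj$IB * (1 - traj$CB) * rates$CFR + traj$IB * traj$CB * rates$CFRT
}
deaths_with_product <- function(traj, rates) {
  traj$IV * (1 - traj$CD) * rates$CFR + traj$IV * traj$CD * rates$CFRT
}

#' Yearly averted outcomes for one disease
#'
#' Literal evaluation of the averted-burden equations on a trajectory:
#' cases averted (base minus with-vaccine incidence), deaths averted (case
#' fatality applied to treated and untreated shares), YLL averted (deaths
#' averted times YLL per death), YLD averted (disability time of treated and
#' untreated cases), DALYs averted (YLL + YLD, exactly additive), and
#' treatment costs averted (cases averted plus the change in treated-case
#' volume, priced at the per-case cost).
#'
#' @param traj Trajectory from [build_trajectory()].
#' @param rates Output of [disease_rates()].
#' @return `data.frame` per year: `year`, `cases_averted`, `deaths_averted`,
#'   `yll_averted`, `yld_averted`, `dalys_averted`,
#'   `treatment_costs_averted` (2020 USD).
#' @export
averted_outcomes <- function(traj, rates) {
  N <- traj$IB - traj$IV
  stopifnot(all(N >= -1e-9))
  deaths <- deaths_base(traj, rates) - deaths_with_product(traj, rates)
  yll <- (deaths_base(traj, rates) - deaths_with_product(traj, rates)) * rates$yll
  yld <- (traj$IB * (1 - traj$CB) * rates$yld_untreated +
            traj$IB * traj$CB * rates$yld_treated) -
         (traj$IV * (1 - traj$CD) * rates$yld_untreated +
            traj$IV * traj$CD * rates$yld_treated)
  costs <- N * rates$K - (traj$IV * traj$CD - traj$IB * traj$CB) * rates$K
  data.frame(year = traj$year,
             cases_averted = N,
             deaths_averted = deaths,
             yll_averted = yll,
             yld_averted = yld,
             dalys_averted = yll + yld,
             treatment_costs_averted = costs)
}

#' Summed averted quantities over the benefit window
#'
#' Convenience totals of [averted_outcomes()] columns: each evaluates its
#' equation summed over the trajectory years.
#'
#' @inheritParams averted_outcomes
#' @return A single number.
#' @export
cases_averted <- function(traj) sum(traj$IB - traj$IV)

#' @rdname cases_averted
#' @export
deaths_averted <- function(traj, rates) {
  sum(deaths_base(traj, rates) - deaths_with_product(traj, rates))
}

#' @rdname cases_averted
#' @export
yll_averted <- function(traj, rates) deaths_averted(traj, rates) * rates$yll

#' @rdname cases_averted
#' @export
yld_averted <- function(traj, rates) sum(averted_outcomes(traj, rates)$yld_averted)

#' DALYs averted
#'
#' @param yll,yld YLL and YLD averted (scalars or aligned vectors).
#' @return `yll + yld`.
#' @export
dalys_averted <- function(yll, yld) yll + yld

#' @rdname cases_averted
#' @param N Cases averted per year (defaults to `traj$IB - traj$IV`).
#' @export
treatment_costs_averted <- function(traj, rates, N = traj$IB - traj$IV) {
  sum(N * rates$K - (traj$IV * traj$CD - traj$IB * traj$CB) * rates$K)
}

#' Averted outcomes implied by a set of launches
#'
#' Applies the benefit-attribution rule: per disease, only the *first*
#' vaccine launch starts the incidence ramp and only the earliest
#' therapeutic-or-diagnostic launch starts the (single, shared) coverage
#' ramp; later launches of the same class add nothing. Diseases without any
#' launch contribute zeros.
#'
#' @param launches `launches` data.frame from a [simulate_once()] result.
#' @param epi `epi_params` table covering the portfolio's diseases.
#' @param end_year Last benefit year.
#' @return `data.frame`: one row per disease-year with the
#'   [averted_outcomes()] columns plus `disease`.
#' @export
benefits_for_launches <- function(launches, epi, end_year = 2035) {
  out <- list()
  for (dz in unique(launches$disease)) {
    l <- launches[launches$disease == dz, ]
    v_entry <- suppressWarnings(
      min(l$market_entry_year[l$class == "vaccine"]))
    t_entry <- suppressWarnings(
      min(l$market_entry_year[l$class %in% c("therapeutic", "diagnostic")]))
    v_entry <- if (is.finite(v_entry)) v_entry else NA
    t_entry <- if (is.finite(t_entry)) t_entry else NA
    ep <- epi[epi$disease == dz, ]
    if (!nrow(ep)) stop("no epi parameters for disease '", dz, "'")
    rates <- disease_rates(ep)
    traj <- build_trajectory(rates, v_entry, t_entry, end_year = end_year)
    if (!nrow(traj)) next
    ao <- averted_outcomes(traj, rates)
    ao$disease <- dz
    out[[dz]] <- ao
  }
  if (!length(out)) {
    ao <- averted_outcomes(
      build_trajectory(list(I = 0, CB = 0), NA, NA, start_year = NULL),
      list(CFR = 0, CFRT = 0, K = 0, yll = 0, yld_untreated = 0, yld_treated = 0))
    ao$disease <- character(0)
    return(ao)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
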