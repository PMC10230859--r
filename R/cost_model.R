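#' Mechanism cost parameters for a design option
#'
#' Annual operating costs are US$25/40/60 million for options 1/2/3, with a
#' one-time start-up cost of 45% of the annual operating cost booked in the
#' first operating year. Options 2 and 3 additionally invest US$100 million
#' and US$250 million per year in health system strengthening (HSS) for the
#' first five years.
#'
#' @param option_id Design option, 1, 2 or 3.
#' @param ops_years Calendar years the mechanism operates (defaults to the
#'   simulation window; the source does not state an end year).
#' @return List of class `mechanism_cost_params`: `annual_ops`, `startup`,
#'   `hss_annual` (all USD millions), `ops_years`, `hss_years`.
#' @export
mechanism_cost_params <- function(option_id, ops_years = 2019:2030) {
  ops <- switch(as.character(option_id), "1" = 25, "2" = 40, "3" = 60,
                stop("unknown design option: ", option_id))
  hss <- switch(as.character(option_id), "1" = 0, "2" = 100, "3" = 250)
  structure(list(annual_ops = ops, startup = 0.45 * ops, hss_annual = hss,
                 ops_years = ops_years,
                 hss_years = ops_years[1]:(ops_years[1] + 4)),
            class = "mechanism_cost_params")
}

#' Yearly mechanism cost schedule
#'
#' @param params A [mechanism_cost_params()].
#' @return Named numeric vector, USD millions per calendar year: start-up in
#'   the first year, operations every operating year, HSS in its years.
#' @export
mechanism_cost_schedule <- function(params) {
  years <- params$ops_years
  s <- setNames(rep(params$annual_ops, length(years)), years)
  s[1] <- s[1] + params$startup
  hss <- intersect(as.character(params$hss_years), names(s))
  s[hss] <- s[hss] + params$hss_annual
  s
}

#' Vaccine procurement parameters
#'
#' @param efficacy Vaccine efficacy (base case 75%).
#' @param price_per_dose Procurement cost per dose, 2020 USD (base case 10).
#' @return List of class `vaccine_params`.
#' @export
vaccine_params <- function(efficacy = 0.75, price_per_dose = 10) {
  stopifnot(efficacy > 0, efficacy <= 1, price_per_dose >= 0)
  structure(list(efficacy = efficacy, price_per_dose = price_per_dose),
            class = "vaccine_params")
}

#' Yearly vaccine procurement costs
#'
#' Doses required to avert `N` cases at efficacy `E` cost `(N / E) * K`:
#' cases averted by the vaccine are grossed up by efficacy and priced per
#' dose.
#'
#' @param cases_averted_series Named numeric vector of vaccine-averted cases
#'   per calendar year.
#' @param params A [vaccine_params()].
#' @return Named numeric vector, USD per year.
#' @export
procurement_costs <- function(cases_averted_series, params = vaccine_params()) {
  stopifnot(all(cases_averted_series >= 0))
  cases_averted_series / params$efficacy * params$price_per_dose
}

#' Total yearly cost schedule under a perspective
#'
#' The societal perspective sums mechanism costs (operations, start-up,
#' HSS), phase III trial spend and vaccine procurement; the altruistic
#' investor perspective excludes procurement (assumed borne by countries or
#' pooled-procurement entities).
#'
#' @param perspective `"societal"` or `"altruistic"`.
#' @param mech_costs Named vector from [mechanism_cost_schedule()], USD
#'   millions.
#' @param phase3_spend Named vector of phase III spend per year, USD
#'   millions.
#' @param procurement Named vector from [procurement_costs()], USD.
#' @return Named numeric vector, USD per calendar year.
#' @export
total_cost_schedule <- function(perspective, mech_costs, phase3_spend,
                                procurement = numeric(0)) {
  if (!perspective %in% c("societal", "altruistic")) {
    stop("unknown perspective: ", perspective)
  }
  comps <- list(mech_costs * 1e6, phase3_spend * 1e6)
  if (perspective == "societal") comps <- c(comps, list(procurement))
  years <- sort(unique(unlist(lapply(comps, names))))
  out <- setNames(numeric(length(years)), years)
  for (cmp in comps) for (k in names(cmp)) out[k] <- out[k] + cmp[[k]]
  out
}
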