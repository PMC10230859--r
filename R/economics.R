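#' Present value of a yearly series
#'
#' `sum_x value_x / (1 + rate)^(x - base_year)`. Costs, economic benefits
#' and health outcomes are all discounted at the same 3% rate to the
#' simulation start year.
#'
#' @param yearly_series Named numeric vector keyed by calendar year, or a
#'   plain vector with `years` supplied.
#' @param rate Annual discount rate (> -1); default 0.03.
#' @param base_year Year values are discounted to.
#' @param years Calendar years (defaults to `names(yearly_series)`).
#' @return Present value (scalar).
#' @export
discount <- function(yearly_series, rate = 0.03, base_year = 2019,
                     years = as.numeric(names(yearly_series))) {
  stopifnot(rate > -1, length(years) == length(yearly_series),
            !any(is.na(years)))
  sum(yearly_series / (1 + rate)^(years - base_year))
}

#' Benefit-cost ratio
#'
#' Total monetary benefits (treatment costs averted) divided by total
#' monetary costs, both discounted.
#'
#' @param net_benefit,net_cost Discounted totals, same units.
#' @return `net_benefit / net_cost`.
#' @export
bcr <- function(net_benefit, net_cost) {
  if (net_cost <= 0) stop("BCR requires a positive net cost")
  net_benefit / net_cost
}

#' Cost per unit outcome
#'
#' @param net_cost Discounted net cost, USD.
#' @param outcomes Discounted outcome count (DALYs or deaths averted).
#' @return USD per outcome unit.
#' @export
cost_per_outcome <- function(net_cost, outcomes) {
  if (outcomes <= 0) stop("cost per outcome requires positive outcomes")
  net_cost / outcomes
}

#' Incremental cost-effectiveness ratio between design options
#'
#' Difference in net costs divided by difference in effectiveness (DALYs
#' averted) between two options. A dominated comparison (the more effective
#' option is cheaper) is flagged with a warning and returned as its
#' (negative) ratio.
#'
#' @param option_hi,option_lo Either `economic_summary` objects or lists
#'   with `net_cost` and `dalys_averted`.
#' @return USD per DALY averted.
#' @export
icer <- function(option_hi, option_lo) {
  d_cost <- option_hi$net_cost - option_lo$net_cost
  d_eff <- option_hi$dalys_averted - option_lo$dalys_averted
  if (d_eff == 0) stop("ICER undefined: equal effectiveness")
  if (d_cost < 0 && d_eff > 0) {
    warning("option_hi dominates option_lo (cheaper and more effective)")
  }
  d_cost / d_eff
}

#' Headline economic summary for one option and perspective
#'
#' Discounts every stream to the base year and derives the headline ratios.
#' Health outcomes are discounted alongside costs by default (set
#' `discount_outcomes = FALSE` for undiscounted DALYs/deaths).
#'
#' @param option_id Design option.
#' @param perspective `"societal"` or `"altruistic"`.
#' @param cost_schedule Named yearly total costs, USD (see
#'   [total_cost_schedule()]).
#' @param benefit_schedule Named yearly treatment costs averted, USD.
#' @param dalys_by_year,deaths_by_year Named yearly health outcomes.
#' @param rate Discount rate; `base_year` the discounting anchor.
#' @param discount_outcomes Discount DALYs/deaths too?
#' @return List of class `economic_summary` with `net_cost`, `net_benefit`,
#'   `dalys_averted`, `deaths_averted`, `bcr`, `cost_per_daly`,
#'   `cost_per_death`, plus the inputs' metadata.
#' @export
economic_summary <- function(option_id, perspective, cost_schedule,
                             benefit_schedule, dalys_by_year, deaths_by_year,
                             rate = 0.03, base_year = 2019,
                             discount_outcomes = TRUE) {
  net_cost <- discount(cost_schedule, rate, base_year)
  net_benefit <- discount(benefit_schedule, rate, base_year)
  out_rate <- if (discount_outcomes) rate else 0
  dalys <- discount(dalys_by_year, out_rate, base_year)
  deaths <- discount(deaths_by_year, out_rate, base_year)
  structure(list(
    option_id = option_id, perspective = perspective,
    net_cost = net_cost, net_benefit = net_benefit,
    dalys_averted = dalys, deaths_averted = deaths,
    bcr = bcr(net_benefit, net_cost),
    cost_per_daly = cost_per_outcome(net_cost, dalys),
    cost_per_death = cost_per_outcome(net_cost, deaths),
    discount_rate = rate, base_year = base_year,
    discount_outcomes = discount_outcomes),
    class = "economic_summary")
}

#' @export
print.economic_summary <- function(x, ...) {
  cat(sprintf("Design option %s (%s perspective)\n", x$option_id, x$perspective))
  cat(sprintf("  net cost:        US$%.2f billion\n", x$net_cost / 1e9))
  cat(sprintf("  net benefit:     US$%.2f billion\n", x$net_benefit / 1e9))
  cat(sprintf("  DALYs averted:   %.1f million\n", x$dalys_averted / 1e6))
  cat(sprintf("  deaths averted:  %.2f million\n", x$deaths_averted / 1e6))
  cat(sprintf("  BCR:             %.2f\n", x$bcr))
  cat(sprintf("  cost/DALY:       US$%.2f\n", x$cost_per_daly))
  cat(sprintf("  cost/death:      US$%.0f\n", x$cost_per_death))
  invisible(x)
}
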