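#' Product archetypes
#'
#' The ten product archetypes modelled: vaccines, new chemical entities,
#' repurposed drugs and biologics, each in a "simple" and "complex" variant,
#' plus two diagnostic development archetypes (assay development and simple
#' platform development). Each archetype carries its own per-phase trial
#' cost, duration and probability of success.
#'
#' @return Character vector of the ten archetype names.
#' @export
archetypes <- function() {
  c("vaccine-simple", "vaccine-complex",
    "nce-simple", "nce-complex",
    "repurposed-simple", "repurposed-complex",
    "biologic-simple", "biologic-complex",
    "dx-assay", "dx-platform")
}

#' Trial phases
#'
#' @return Character vector of the four pipeline phases, in pipeline order.
#' @export
trial_phases <- function() {
  c("preclinical", "phase1", "phase2", "phase3")
}

#' Product class of an archetype
#'
#' Maps archetypes onto the three product classes used for benefit
#' attribution: a vaccine launch starts an incidence-reduction ramp, while
#' therapeutic and diagnostic launches start (and share) a treatment-coverage
#' ramp.
#'
#' @param archetype Character vector of archetype names.
#' @return Character vector: "vaccine", "therapeutic" or "diagnostic".
#' @export
archetype_class <- function(archetype) {
  stopifnot(all(archetype %in% archetypes()))
  ifelse(startsWith(archetype, "vaccine"), "vaccine",
         ifelse(startsWith(archetype, "dx"), "diagnostic", "therapeutic"))
}

#' Base-case trial phase parameters
#'
#' Per-archetype, per-phase cost (2020 USD millions), duration (years) and
#' probability of success for the preclinical, phase I, phase II and phase
#' III stages of the pipeline. `NA` cells mark phases the archetype either
#' does not possess at all (all three values `NA`) or possesses in a
#' degenerate form (e.g. diagnostic platform development has a phase III of
#' stated length but no cost and no attrition).
#'
#' @return A `data.frame` of class `phase_params` with columns `archetype`,
#'   `phase`, `cost`, `length`, `p_success` (one row per archetype x phase).
#' @seealso [apply_sensitivity()], [apply_efficiency()],
#'   [expected_launch_probability()]
#' @export
base_phase_params <- function() {
  a <- archetypes()
  cost <- rbind(
    preclinical = c(6.66, 16.63, 5.00, 10.00,   NA, 5.00, 10.79, 21.59, 3.00,     NA),
    phase1      = c(2.25,  2.47, 2.21,  7.44,   NA, 2.21,  2.41,  7.65, 2.00, 100.00),
    phase2      = c(13.22, 13.88, 5.81,  6.39, 5.81, 5.81,  7.53,  8.28, 3.50,   3.50),
    phase3      = c(111.10, 133.32, 32.82, 36.10, 17.61, 17.61, 54.12, 59.53, NA,  NA))
  len <- rbind(
    preclinical = c(3.36, 3.33, 2.49, 2.87,   NA,   NA, 3.29, 3.24, 1.00,   NA),
    phase1      = c(1.57, 1.97, 1.80, 1.93,   NA,   NA, 1.62, 1.49, 1.25,   NA),
    phase2      = c(2.23, 3.71, 3.38, 3.51, 2.14, 2.14, 2.47, 4.16, 1.33, 2.50),
    phase3      = c(2.33, 3.50, 3.18, 2.80, 2.14, 2.14, 2.10, 3.38,   NA, 2.00))
  p <- rbind(
    preclinical = c(0.410, 0.410, 0.650, 0.550,    NA, 0.750, 0.750, 0.770, 0.500,    NA),
    phase1      = c(0.684, 0.500, 0.597, 0.572,    NA, 0.585, 0.662, 0.696, 1.000, 0.750),
    phase2      = c(0.459, 0.216, 0.388, 0.197, 0.457, 0.457, 0.443, 0.322, 1.000, 1.000),
    phase3      = c(0.708, 0.636, 0.691, 0.403, 0.681, 0.681, 0.709, 0.625,    NA,    NA))
  ph <- trial_phases()
  # matrices are phases x archetypes; as.vector() is column-major
  out <- data.frame(
    archetype = rep(a, each = length(ph)),
    phase = rep(ph, times = length(a)),
    cost = as.vector(cost),
    length = as.vector(len),
    p_success = as.vector(p),
    stringsAsFactors = FALSE)
  class(out) <- c("phase_params", "data.frame")
  validate_phase_params(out)
  out
}

validate_phase_params <- function(pp) {
  stopifnot(is.data.frame(pp),
            all(c("archetype", "phase", "cost", "length", "p_success") %in% names(pp)))
  with(pp, {
    stopifnot(all(archetype %in% archetypes()), all(phase %in% trial_phases()))
    stopifnot(all(cost >= 0, na.rm = TRUE), all(length >= 0, na.rm = TRUE))
    stopifnot(all(p_success >= 0 & p_success <= 1, na.rm = TRUE))
  })
  invisible(pp)
}

# A phase is "active" for an archetype iff any of its three parameters is
# present; fully-NA phases are skipped in the walk (a repurposed drug starts
# at phase II; an assay launches on exiting phase II). Within an active
# phase, NA length counts as 0 years, NA cost as 0, NA p_success as certain
# success (diagnostic platform phase III: stated length, no cost, no
# attrition).
phase_active <- function(pp) {
  !(is.na(pp$cost) & is.na(pp$length) & is.na(pp$p_success))
}

#' Active phases of an archetype
#'
#' @param archetype Single archetype name.
#' @param phase_params Phase parameter table, see [base_phase_params()].
#' @return Character vector of the phases the archetype actually passes
#'   through, in pipeline order.
#' @export
archetype_phases <- function(archetype, phase_params = base_phase_params()) {
  stopifnot(length(archetype) == 1L, archetype %in% archetypes())
  rows <- phase_params[phase_params$archetype == archetype, ]
  rows <- rows[match(trial_phases(), rows$phase), ]
  rows$phase[phase_active(rows)]
}

# Per-archetype walk table with NA imputation applied (internal).
archetype_walk_table <- function(archetype, phase_params) {
  rows <- phase_params[phase_params$archetype == archetype, ]
  rows <- rows[match(trial_phases(), rows$phase), ]
  rows <- rows[phase_active(rows), , drop = FALSE]
  rows$cost[is.na(rows$cost)] <- 0
  rows$length[is.na(rows$length)] <- 0
  rows$p_success[is.na(rows$p_success)] <- 1
  rows
}

#' Analytic probability that a candidate eventually launches
#'
#' Product of the per-phase success probabilities from the starting phase
#' through the archetype's final active phase, ignoring the time horizon.
#' Serves as the closed-form oracle for the Monte Carlo launch counts.
#'
#' @param archetype Archetype name.
#' @param starting_phase Phase the candidate enters the pipeline in; must be
#'   an active phase of the archetype.
#' @param phase_params Phase parameter table.
#' @return Probability in \[0, 1\].
#' @examples
#' expected_launch_probability("vaccine-simple", "phase1") # ~0.222
#' @export
expected_launch_probability <- function(archetype, starting_phase,
                                        phase_params = base_phase_params()) {
  tab <- archetype_walk_table(archetype, phase_params)
  i <- match(starting_phase, tab$phase)
  if (is.na(i)) {
    stop("phase '", starting_phase, "' is not an active phase of archetype '",
         archetype, "'")
  }
  prod(tab$p_success[i:nrow(tab)])
}

#' Sensitivity transform: inflate phase III costs and all phase durations
#'
#' The multiway sensitivity scenario raises phase III trial costs by
#' `cost_factor` x 100% and every phase duration by `length_factor` x 100%
#' for all archetypes. Success probabilities and `NA` cells are untouched;
#' costs of phases other than phase III are untouched.
#'
#' @param phase_params Phase parameter table.
#' @param cost_factor,length_factor Non-negative fractional increases
#'   (1 = +100%).
#' @return Transformed `phase_params` table.
#' @export
apply_sensitivity <- function(phase_params, cost_factor = 1, length_factor = 1) {
  stopifnot(cost_factor >= 0, length_factor >= 0)
  pp <- phase_params
  is_p3 <- pp$phase == "phase3" & !is.na(pp$cost)
  pp$cost[is_p3] <- pp$cost[is_p3] * (1 + cost_factor)
  has_len <- !is.na(pp$length)
  pp$length[has_len] <- pp$length[has_len] * (1 + length_factor)
  validate_phase_params(pp)
  pp
}

#' Efficiency transform: adaptive-trial scenario
#'
#' Adaptive trial designs are taken to shorten every phase by 6 months and
#' cut phase III costs by 15%. With a share `adaptive_share` of trials run
#' adaptively, the pipeline-average effect is a duration reduction of
#' `0.5 * adaptive_share` years per phase (floored at a small positive
#' minimum) and a phase III cost multiplier of `1 - 0.15 * adaptive_share`.
#' The two stated scenarios are shares 0.5 (3 months, -7.5% cost) and 1.0
#' (6 months, -15% cost); other shares interpolate linearly.
#'
#' @param phase_params Phase parameter table.
#' @param adaptive_share Share of trials using adaptive designs, in \[0, 1\].
#' @param min_length Floor for shortened phase durations, years.
#' @return Transformed `phase_params` table.
#' @export
apply_efficiency <- function(phase_params, adaptive_share, min_length = 0.01) {
  stopifnot(adaptive_share >= 0, adaptive_share <= 1)
  if (!adaptive_share %in% c(0, 0.5, 1)) {
    message("adaptive_share ", adaptive_share,
            " interpolates linearly between the stated 50%/100% scenarios")
  }
  pp <- phase_params
  has_len <- !is.na(pp$length)
  pp$length[has_len] <- pmax(pp$length[has_len] - 0.5 * adaptive_share, min_length)
  if (adaptive_share == 0) pp$length <- phase_params$length # exact identity
  is_p3 <- pp$phase == "phase3" & !is.na(pp$cost)
  pp$cost[is_p3] <- pp$cost[is_p3] * (1 - 0.15 * adaptive_share)
  validate_phase_params(pp)
  pp
}
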