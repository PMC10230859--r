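#' Diseases covered by each design option
#'
#' Option 1 funds phase III trials of vaccines for HIV, TB, malaria and
#' pneumococcal pneumonia. Option 2 adds therapeutics and five neglected
#' tropical diseases. Option 3 covers the full early-stage PRND portfolio
#' (the complete printed disease list).
#'
#' @param option_id Design option, 1, 2 or 3.
#' @return Character vector of disease names.
#' @export
option_diseases <- function(option_id) {
  opt1 <- c("hiv", "tb", "malaria", "pneumonia")
  opt2 <- c(opt1, "chagas", "schistosomiasis", "leishmaniasis", "dengue", "leprosy")
  opt3 <- c(opt2, "shigellosis", "ebola", "hepatitis_c", "etec",
            "nt_salmonella", "hat", "onchocerciasis", "cholera", "hookworm",
            "meningitis", "rheumatic_fever", "diarrhoeal_diseases",
            "buruli_ulcer", "trachoma", "typhoid", "paratyphoid",
            "cryptosporidiosis", "mult_salmonella", "hepatitis_b",
            "herpes_simplex_2", "gonorrhoea", "chlamydia")
  switch(as.character(option_id),
         "1" = opt1, "2" = opt2, "3" = opt3,
         stop("unknown design option: ", option_id))
}

#' Product classes funded by each design option
#' @inheritParams option_diseases
#' @return Character vector drawn from "vaccine", "therapeutic", "diagnostic".
#' @export
option_classes <- function(option_id) {
  switch(as.character(option_id),
         "1" = "vaccine",
         "2" = c("vaccine", "therapeutic"),
         "3" = c("vaccine", "therapeutic", "diagnostic"),
         stop("unknown design option: ", option_id))
}

#' Default archetype split within each product class
#'
#' The portfolio source does not publish the simple/complex breakdown, so by
#' default mass is spread evenly within each product class: 50/50 between
#' simple and complex vaccines, uniformly over the six therapeutic
#' archetypes, and 50/50 between the two diagnostic archetypes.
#'
#' @return Named numeric vector over all ten archetypes; sums to 1 within
#'   each product class.
#' @export
default_archetype_split <- function() {
  c("vaccine-simple" = 0.5, "vaccine-complex" = 0.5,
    "nce-simple" = 1 / 6, "nce-complex" = 1 / 6,
    "repurposed-simple" = 1 / 6, "repurposed-complex" = 1 / 6,
    "biologic-simple" = 1 / 6, "biologic-complex" = 1 / 6,
    "dx-assay" = 0.5, "dx-platform" = 0.5)
}

check_archetype_split <- function(split) {
  stopifnot(all(archetypes() %in% names(split)), all(split >= 0))
  cls <- archetype_class(names(split))
  for (k in unique(cls)) {
    s <- sum(split[cls == k])
    if (abs(s - 1) > 1e-9) {
      stop("archetype split does not sum to 1 within product class '", k,
           "' (sum = ", format(s), ")")
    }
  }
  invisible(split)
}

# Phase distribution of the 2019 early-stage portfolio: 23/63/30 of 116
# candidates in advanced preclinical / phase I / phase II for option 1; the
# same proportions (20/54/26%) are reused for options 2-3, whose breakdown
# is not published.
option1_phase_counts <- function() {
  c(preclinical = 23L, phase1 = 63L, phase2 = 30L)
}

option_total <- function(option_id) {
  switch(as.character(option_id), "1" = 116L, "2" = 327L, "3" = 506L)
}

# Printed disease marginals for option 2: 272 candidates target HIV, TB or
# malaria jointly; the rest are pinned per disease.
option2_disease_counts <- function() {
  c(hiv_tb_malaria = 272L, leishmaniasis = 16L, chagas = 14L,
    pneumonia = 9L, schistosomiasis = 9L, dengue = 5L, leprosy = 2L)
}

# Option 3 disease shares: malaria 19%, TB 17%, HIV 17%, Ebola 14% are
# printed; the classic NTDs other than Chagas jointly hold 11.5%; the
# remaining mass is spread uniformly over the other diseases.
option3_disease_probs <- function() {
  d <- option_diseases(3)
  p <- setNames(rep(NA_real_, length(d)), d)
  p[c("malaria", "tb", "hiv", "ebola")] <- c(0.19, 0.17, 0.17, 0.14)
  ntds <- c("schistosomiasis", "leishmaniasis", "dengue", "leprosy", "hat",
            "onchocerciasis", "hookworm", "buruli_ulcer", "trachoma")
  p[ntds] <- 0.115 / length(ntds)
  rest <- is.na(p)
  p[rest] <- (1 - sum(p, na.rm = TRUE)) / sum(rest)
  p
}

#' Generate a synthetic product-candidate portfolio
#'
#' Builds a portfolio of early-stage (preclinical, phase I, phase II)
#' candidates honouring the printed marginals of the 2019 PRND pipeline:
#' option 1 has exactly 116 vaccine candidates split 23/63/30 across phases
#' for the four option-1 diseases; option 2 has 327 candidates of which 272
#' target HIV, TB or malaria; option 3 has 506 candidates with the printed
#' disease shares. Cells the source does not constrain (disease x archetype
#' x phase within a marginal) are allocated multinomially under
#' `archetype_split` and the option-1 phase proportions.
#'
#' Candidates already in phase III in 2019 are excluded by construction
#' (their trials are assumed already funded). Archetypes that lack a
#' generated entry phase (e.g. repurposed drugs have no preclinical or phase
#' I stage) are recorded at their earliest active phase at or after it.
#'
#' @param option_id Design option, 1, 2 or 3.
#' @param archetype_split Named split over archetypes, summing to 1 within
#'   each product class; see [default_archetype_split()].
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param phase_params Phase parameter table used to clamp entry phases to
#'   phases each archetype actually possesses.
#' @return A `data.frame` of class `portfolio_spec` with columns `disease`,
#'   `archetype`, `phase_at_start`, `count`, and attribute `option_id`.
#' @export
generate_portfolio <- function(option_id, archetype_split = default_archetype_split(),
                               seed, phase_params = base_phase_params()) {
  if (!option_id %in% 1:3) stop("unknown design option: ", option_id)
  check_archetype_split(archetype_split)
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))

  classes <- option_classes(option_id)
  class_w <- setNames(rep(1 / length(classes), length(classes)), classes)
  arch <- archetypes()[archetype_class(archetypes()) %in% classes]
  arch_p <- archetype_split[arch] * class_w[archetype_class(arch)]
  arch_p <- arch_p / sum(arch_p)

  phase_props <- option1_phase_counts() / sum(option1_phase_counts())

  alloc_cells <- function(n, diseases, disease_p, phase_counts = NULL) {
    # diseases x archetypes x phases cell probabilities
    if (is.null(phase_counts)) {
      cells <- expand.grid(disease = diseases, archetype = arch,
                           phase_at_start = names(phase_props),
                           stringsAsFactors = FALSE)
      p <- disease_p[cells$disease] * arch_p[cells$archetype] *
        phase_props[cells$phase_at_start]
      cells$count <- as.integer(stats::rmultinom(1, n, p))
    } else {
      # exact per-phase marginals (option 1)
      parts <- lapply(names(phase_counts), function(ph) {
        cells <- expand.grid(disease = diseases, archetype = arch,
                             phase_at_start = ph, stringsAsFactors = FALSE)
        p <- disease_p[cells$disease] * arch_p[cells$archetype]
        cells$count <- as.integer(stats::rmultinom(1, phase_counts[[ph]], p))
        cells
      })
      cells <- do.call(rbind, parts)
    }
    cells
  }

  if (option_id == 1) {
    d <- option_diseases(1)
    dp <- setNames(rep(1 / length(d), length(d)), d)
    cells <- alloc_cells(NULL, d, dp, phase_counts = option1_phase_counts())
  } else if (option_id == 2) {
    dc <- option2_disease_counts()
    htm <- c("hiv", "tb", "malaria")
    parts <- list()
    cells_htm <- alloc_cells(dc[["hiv_tb_malaria"]], htm,
                             setNames(rep(1 / 3, 3), htm))
    parts <- c(parts, list(cells_htm))
    for (dz in setdiff(names(dc), "hiv_tb_malaria")) {
      parts <- c(parts, list(alloc_cells(dc[[dz]], dz, setNames(1, dz))))
    }
    cells <- do.call(rbind, parts)
  } else {
    dp <- option3_disease_probs()
    cells <- alloc_cells(option_total(3), names(dp), dp)
  }

  cells <- cells[cells$count > 0, c("disease", "archetype", "phase_at_start", "count")]
  # clamp entry phase to the archetype's earliest active phase at/after it
  cells$phase_at_start <- mapply(function(a, ph) {
    act <- archetype_phases(a, phase_params)
    ord <- trial_phases()
    cand <- act[match(act, ord) >= match(ph, ord)]
    if (!length(cand)) stop("archetype ", a, " has no active phase at/after ", ph)
    cand[[1]]
  }, cells$archetype, cells$phase_at_start, USE.NAMES = FALSE)
  # merge rows made identical by clamping
  cells <- stats::aggregate(count ~ disease + archetype + phase_at_start,
                            data = cells, FUN = sum)
  cells <- cells[order(cells$disease, cells$archetype, cells$phase_at_start), ]
  rownames(cells) <- NULL
  structure(cells, option_id = option_id,
            class = c("portfolio_spec", "data.frame"))
}

#' Default plausible ranges for synthetic disease parameters
#'
#' Uniform-draw bounds for each epidemiological and cost field, standing in
#' for literature-review inputs. Scales are global annual figures for
#' high-burden PRNDs (incidence in cases/year across an age group, deaths
#' tied to incidence, residual life expectancy by age group, 2020 USD
#' treatment costs per case).
#'
#' @return Named list of `c(min, max)` pairs; `life_expectancy` is a list
#'   with one pair per age group.
#' @export
default_epi_ranges <- function() {
  list(
    incidence = c(2e5, 5e6),          # cases / age group / year
    deaths_per_case = c(0.005, 0.05), # annual deaths as share of incidence
    dw_untreated = c(0.10, 0.60),
    dw_treated_frac = c(0.20, 0.80),  # DW_treated = frac * DW_untreated
    dur_untreated = c(0.20, 2.00),    # years
    dur_treated_frac = c(0.20, 0.80), # T_treated = frac * T_untreated
    cfr_untreated = c(0.02, 0.30),
    cfr_treated_frac = c(0.20, 0.80), # CFRT = frac * CFR
    coverage_baseline = c(0.10, 0.60),
    treatment_cost = c(20, 200),      # 2020 USD per case
    life_expectancy = list(`0-4` = c(60, 70), `5-14` = c(55, 65),
                           `15-49` = c(35, 50), `50-69` = c(15, 25),
                           `70+` = c(4, 10)))
}

#' Age groups used by the synthetic generator
#' @return Character vector of the five default age-group labels.
#' @export
age_groups <- function() names(default_epi_ranges()$life_expectancy)

#' Generate synthetic disease epidemiology/cost parameters
#'
#' Draws one record per disease per age group from uniform distributions on
#' `ranges`. Derived fields are constructed so the model's ordering
#' constraints hold by design: treated case fatality never exceeds untreated
#' case fatality, treated disability weight and duration never exceed their
#' untreated counterparts, all proportions lie in \[0, 1\]. Coverage, case
#' fatality and treatment cost are drawn once per disease (age-invariant).
#'
#' @param diseases Character vector of disease names (may be empty).
#' @param ranges Field ranges, see [default_epi_ranges()].
#' @param seed Integer seed; deterministic given the seed.
#' @return A `data.frame` of class `epi_params`, one row per disease x age
#'   group, columns `disease`, `age_group`, `incidence`, `deaths`,
#'   `life_expectancy`, `dw_untreated`, `dw_treated`, `dur_untreated`,
#'   `dur_treated`, `cfr_untreated`, `cfr_treated`, `coverage_baseline`,
#'   `treatment_cost`.
#' @export
generate_disease_params <- function(diseases, ranges = default_epi_ranges(), seed) {
  stopifnot(!missing(seed))
  for (nm in setdiff(names(ranges), "life_expectancy")) {
    r <- ranges[[nm]]
    if (r[1] > r[2]) stop("range min > max for field '", nm, "'")
    if (r[1] < 0) stop("negative lower bound for non-negative field '", nm, "'")
  }
  ag <- names(ranges$life_expectancy)
  cols <- c("disease", "age_group", "incidence", "deaths", "life_expectancy",
            "dw_untreated", "dw_treated", "dur_untreated", "dur_treated",
            "cfr_untreated", "cfr_treated", "coverage_baseline", "treatment_cost")
  if (length(diseases) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 2), cols[1:2]))
    for (nm in cols[-(1:2)]) out[[nm]] <- numeric(0)
    class(out) <- c("epi_params", "data.frame")
    return(out)
  }
  set.seed(as.integer(seed))
  u <- function(r, n = 1L) stats::runif(n, r[1], r[2])
  rows <- lapply(diseases, function(dz) {
    dw_u <- u(ranges$dw_untreated)
    t_u <- u(ranges$dur_untreated)
    cfr <- u(ranges$cfr_untreated)
    rec <- data.frame(
      disease = dz, age_group = ag,
      incidence = u(ranges$incidence, length(ag)),
      deaths = NA_real_,
      life_expectancy = vapply(ranges$life_expectancy, u, numeric(1)),
      dw_untreated = dw_u,
      dw_treated = dw_u * u(ranges$dw_treated_frac),
      dur_untreated = t_u,
      dur_treated = t_u * u(ranges$dur_treated_frac),
      cfr_untreated = cfr,
      cfr_treated = cfr * u(ranges$cfr_treated_frac),
      coverage_baseline = u(ranges$coverage_baseline),
      treatment_cost = u(ranges$treatment_cost),
      stringsAsFactors = FALSE)
    rec$deaths <- rec$incidence * u(ranges$deaths_per_case, length(ag))
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("epi_params", "data.frame")
  validate_epi_params(out)
  out
}

validate_epi_params <- function(ep) {
  props <- c("dw_untreated", "dw_treated", "cfr_untreated", "cfr_treated",
             "coverage_baseline")
  for (nm in props) stopifnot(all(ep[[nm]] >= 0 & ep[[nm]] <= 1))
  for (nm in c("incidence", "deaths", "life_expectancy", "dur_untreated",
               "dur_treated", "treatment_cost")) {
    stopifnot(all(ep[[nm]] >= 0))
  }
  stopifnot(all(ep$cfr_treated <= ep$cfr_untreated),
            all(ep$dw_treated <= ep$dw_untreated))
  invisible(ep)
}

#' Hand-checkable single-candidate fixture
#'
#' One vaccine-simple candidate in phase II for one disease with one age
#' group and round-number parameters, so every downstream quantity can be
#' verified by hand: YLL per death is 30, the analytic launch probability is
#' 0.459 x 0.708 = 0.324972, and the benefit equations reduce to one-line
#' arithmetic.
#'
#' @return List with elements `portfolio` (a `portfolio_spec`) and `epi`
#'   (an `epi_params` table).
#' @export
worked_fixture <- function() {
  portfolio <- structure(
    data.frame(disease = "malaria", archetype = "vaccine-simple",
               phase_at_start = "phase2", count = 1L,
               stringsAsFactors = FALSE),
    option_id = 1L, class = c("portfolio_spec", "data.frame"))
  epi <- data.frame(
    disease = "malaria", age_group = "all",
    incidence = 1000, deaths = 100, life_expectancy = 30,
    dw_untreated = 0.2, dw_treated = 0.1,
    dur_untreated = 0.5, dur_treated = 0.25,
    cfr_untreated = 0.1, cfr_treated = 0.05,
    coverage_baseline = 0.2, treatment_cost = 50,
    stringsAsFactors = FALSE)
  class(epi) <- c("epi_params", "data.frame")
  list(portfolio = portfolio, epi = epi)
}

#' Read/write portfolio and epi-parameter CSV files
#'
#' Round-trip-safe UTF-8 CSV with a header row.
#'
#' @param x Object to write.
#' @param path File path.
#' @return `read_*` return the typed object; `write_*` return `path`
#'   invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @param option_id Design option recorded in the file's `option_id` column.
#' @export
write_portfolio_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$option_id <- attr(x, "option_id")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_portfolio_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  opt <- unique(df$option_id)
  stopifnot(length(opt) == 1L)
  df$option_id <- NULL
  structure(df, option_id = as.integer(opt),
            class = c("portfolio_spec", "data.frame"))
}

#' @rdname csv_io
#' @export
write_epi_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_epi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(df) <- c("epi_params", "data.frame")
  validate_epi_params(df)
  df
}
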