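two_group_epi <- function() {
  data.frame(disease = "d", age_group = c("young", "old"),
             incidence = c(1000, 1000), deaths = c(100, 300),
             life_expectancy = c(40, 20),
             dw_untreated = 0.2, dw_treated = 0.1,
             dur_untreated = 0.5, dur_treated = 0.25,
             cfr_untreated = 0.1, cfr_treated = 0.05,
             coverage_baseline = 0.2, treatment_cost = 50)
}

test_that("per-death and per-case burden rates match hand arithmetic", {
  ep <- two_group_epi()
  expect_equal(yll_per_death(ep), (100 * 40 + 300 * 20) / 400) # 25

  one <- worked_fixture()$epi
  expect_equal(yll_per_death(one), 30)
  expect_equal(yld_per_untreated_case(one), 0.5 * 0.2) # I=1000,T=0.5,DW=0.2
  expect_equal(yld_per_treated_case(one), 0.25 * 0.1)

  zero_dw <- one; zero_dw$dw_untreated <- 0
  expect_equal(yld_per_untreated_case(zero_dw), 0)

  dead <- one; dead$deaths <- 0
  expect_error(yll_per_death(dead), "positive")
  none <- one; none$incidence <- 0
  expect_error(yld_per_untreated_case(none), "positive")
})

test_that("treated YLD never exceeds untreated YLD over random draws", {
  for (s in 1:20) {
    ep <- random_epi(c("a", "b", "c"), seed = s)
    for (dz in unique(ep$disease)) {
      rows <- ep[ep$disease == dz, ]
      expect_lte(yld_per_treated_case(rows), yld_per_untreated_case(rows))
    }
  }
})

test_that("vaccine incidence ramp: 10 points per year, capped at 90%", {
  IB <- setNames(rep(1000, 15), 2024 + 0:14)
  IV <- incidence_with_vaccine(IB, 2024)
  expect_equal(as.numeric(IV[1:9]), seq(900, 100, by = -100))
  expect_equal(as.numeric(IV[10:15]), rep(100, 6)) # floor from year 9 on
  expect_true(all(IV >= 0.1 * IB - 1e-12))

  # before entry, incidence equals base case
  IB2 <- setNames(rep(1000, 5), 2020:2024)
  expect_equal(incidence_with_vaccine(IB2, 2023),
               setNames(c(1000, 1000, 1000, 900, 800), 2020:2024))
  # long after entry the cap binds
  expect_equal(as.numeric(incidence_with_vaccine(
    setNames(1000, 2044), 2024)), 100)
  # no vaccine, no effect
  expect_equal(incidence_with_vaccine(IB, NA), IB)
})

test_that("coverage ramp: additive 10 points, max attainment 90%", {
  expect_equal(coverage_with_product(0.5, 2024, 2025), 0.7) # year 2 of ramp
  expect_equal(coverage_with_product(0.95, 2024, 2030), 0.95) # cap never reduces
  expect_equal(coverage_with_product(0.2, 2024, 2033), 0.9)  # cap binds
  expect_equal(coverage_with_product(0.5, 2024, 2020), 0.5)  # before entry
  expect_equal(coverage_with_product(0.5, NA, 2030), 0.5)
  expect_equal(coverage_with_product(0.2, 2024, 2024:2026), c(0.3, 0.4, 0.5))
})

test_that("averted-outcome equations match their hand-computed examples", {
  rates <- list(I = 1000, CB = 0.2, CFR = 0.1, CFRT = 0.05, K = 50,
                yll = 30, yld_untreated = 0.1, yld_treated = 0.025)
  traj1 <- data.frame(year = 2024, IB = 1000, IV = 900, CB = 0.2, CD = 0.3)
  expect_equal(deaths_averted(traj1, rates), 13.5, tolerance = 1e-9)
  expect_equal(treatment_costs_averted(traj1, rates, N = 100), 1500,
               tolerance = 1e-9)

  traj3 <- data.frame(year = 2024:2026, IB = 1000,
                      IV = c(900, 800, 700), CB = 0.2, CD = 0.2)
  expect_equal(cases_averted(traj3), 600, tolerance = 1e-9)

  # no product: IV = IB and CD = CB collapse every difference to zero
  null_traj <- data.frame(year = 2024:2030, IB = 1000, IV = 1000,
                          CB = 0.2, CD = 0.2)
  ao <- averted_outcomes(null_traj, rates)
  for (col in setdiff(names(ao), "year")) expect_equal(ao[[col]], rep(0, 7))
})

test_that("DALY additivity holds exactly for every disease-year", {
  for (s in 1:10) {
    ep <- random_epi("dz", seed = s)
    rates <- disease_rates(ep)
    traj <- build_trajectory(rates, vaccine_entry_year = 2024,
                             treatment_entry_year = 2026)
    ao <- averted_outcomes(traj, rates)
    expect_identical(ao$dalys_averted, ao$yll_averted + ao$yld_averted)
    expect_equal(dalys_averted(ao$yll_averted, ao$yld_averted),
                 ao$dalys_averted)
  }
})

test_that("averted series are non-negative under the model's orderings", {
  for (s in 1:20) {
    ep <- random_epi("dz", seed = 100 + s)
    rates <- disease_rates(ep)
    traj <- build_trajectory(rates, vaccine_entry_year = 2023 + s %% 5,
                             treatment_entry_year = 2024 + s %% 7)
    ao <- averted_outcomes(traj, rates)
    # treatment costs averted is excluded: expanding coverage treats more
    # cases, so its yearly series can legitimately go negative
    for (col in c("cases_averted", "deaths_averted", "yll_averted",
                  "yld_averted", "dalys_averted")) {
      expect_true(all(ao[[col]] >= -1e-9), label = col)
    }
  }
})

test_that("coverage expansion alone makes averted treatment costs negative", {
  rates <- disease_rates(worked_fixture()$epi)
  traj <- build_trajectory(rates, NA, 2024, end_year = 2026)
  ao <- averted_outcomes(traj, rates)
  expect_true(all(ao$treatment_costs_averted < 0))
  expect_true(all(ao$cases_averted == 0))
})

test_that("vectorised implementation matches the naive loop oracle", {
  for (s in 1:10) {
    ep <- random_epi("dz", seed = 200 + s)
    rates <- disease_rates(ep)
    traj <- build_trajectory(rates, vaccine_entry_year = 2024,
                             treatment_entry_year = 2025)
    got <- averted_outcomes(traj, rates)
    want <- naive_averted(traj, ep)
    for (col in names(want)) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-9, label = col)
    }
  }
})

test_that("only the first launch per product class starts a ramp", {
  epi <- worked_fixture()$epi
  launches <- data.frame(
    disease = "malaria",
    archetype = c("vaccine-simple", "vaccine-complex", "nce-simple",
                  "dx-assay"),
    class = c("vaccine", "vaccine", "therapeutic", "diagnostic"),
    launch_time = c(4.2, 6.1, 5.0, 7.0),
    launch_year = c(2023, 2025, 2024, 2026),
    market_entry_year = c(2024, 2026, 2025, 2027))
  got <- benefits_for_launches(launches, epi)

  # oracle: ramps keyed to earliest vaccine (2024) and earliest
  # therapeutic/diagnostic (2025) market entries only
  rates <- disease_rates(epi)
  traj <- build_trajectory(rates, 2024, 2025)
  want <- averted_outcomes(traj, rates)
  expect_equal(got$dalys_averted, want$dalys_averted, tolerance = 1e-12)
  expect_equal(got$treatment_costs_averted, want$treatment_costs_averted,
               tolerance = 1e-12)

  # dropping the later same-class launches changes nothing
  got2 <- benefits_for_launches(launches[c(1, 3), ], epi)
  expect_equal(got2$dalys_averted, got$dalys_averted)

  # no launches at all: zero-row table
  none <- launches[0, ]
  expect_equal(nrow(benefits_for_launches(none, epi)), 0L)
})
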