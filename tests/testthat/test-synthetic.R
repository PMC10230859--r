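test_that("option 1 portfolio reproduces the printed marginals exactly", {
  pf <- generate_portfolio(1, seed = 1)
  expect_s3_class(pf, "portfolio_spec")
  expect_equal(sum(pf$count), 116L)
  phase_tot <- tapply(pf$count, pf$phase_at_start, sum)
  expect_equal(phase_tot[["preclinical"]], 23L)
  expect_equal(phase_tot[["phase1"]], 63L)
  expect_equal(phase_tot[["phase2"]], 30L)
  expect_true(all(pf$archetype %in% c("vaccine-simple", "vaccine-complex")))
  expect_true(all(pf$disease %in% option_diseases(1)))
})

test_that("option 2 and 3 portfolios honour printed totals and disease counts", {
  pf2 <- generate_portfolio(2, seed = 7)
  expect_equal(sum(pf2$count), 327L)
  by_dis <- tapply(pf2$count, pf2$disease, sum)
  expect_equal(sum(by_dis[c("hiv", "tb", "malaria")]), 272L)
  expect_equal(by_dis[["leishmaniasis"]], 16L)
  expect_equal(by_dis[["chagas"]], 14L)
  expect_equal(by_dis[["pneumonia"]], 9L)
  expect_equal(by_dis[["schistosomiasis"]], 9L)
  expect_equal(by_dis[["dengue"]], 5L)
  expect_equal(by_dis[["leprosy"]], 2L)
  expect_true(all(archetype_class(pf2$archetype) %in%
                    c("vaccine", "therapeutic")))

  pf3 <- generate_portfolio(3, seed = 2)
  expect_equal(sum(pf3$count), 506L)
  expect_true(all(pf3$disease %in% option_diseases(3)))
})

test_that("portfolio generation is deterministic given the seed", {
  for (opt in 1:3) {
    expect_identical(generate_portfolio(opt, seed = 42),
                     generate_portfolio(opt, seed = 42))
  }
  # different seeds move mass within unconstrained cells but keep marginals
  a <- generate_portfolio(1, seed = 1)
  b <- generate_portfolio(1, seed = 2)
  expect_false(identical(a, b))
  expect_equal(sum(a$count), sum(b$count))
})

test_that("degenerate archetype split and bad splits behave as specified", {
  split <- setNames(rep(0, 10), archetypes())
  split["vaccine-simple"] <- 1
  split[c("nce-simple", "nce-complex", "repurposed-simple",
          "repurposed-complex", "biologic-simple", "biologic-complex")] <- 1 / 6
  split[c("dx-assay", "dx-platform")] <- 0.5
  pf <- generate_portfolio(1, archetype_split = split, seed = 9)
  expect_true(all(pf$archetype == "vaccine-simple"))

  bad <- split
  bad["vaccine-simple"] <- 0.7
  expect_error(generate_portfolio(1, archetype_split = bad, seed = 1),
               "sum to 1")
  expect_error(generate_portfolio(4, seed = 1), "unknown design option")
})

test_that("epi generator honours point ranges, empty input and invariants", {
  rng <- default_epi_ranges()
  for (nm in setdiff(names(rng), "life_expectancy")) {
    rng[[nm]] <- rep(mean(rng[[nm]]), 2)
  }
  rng$life_expectancy <- lapply(rng$life_expectancy, function(r) rep(r[1], 2))
  ep <- generate_disease_params("malaria", rng, seed = 5)
  expect_equal(unique(ep$dw_untreated), mean(default_epi_ranges()$dw_untreated))
  expect_equal(ep$life_expectancy,
               vapply(default_epi_ranges()$life_expectancy, `[`, numeric(1), 1),
               ignore_attr = TRUE)

  expect_equal(nrow(generate_disease_params(character(0), seed = 1)), 0L)

  ep4 <- generate_disease_params(option_diseases(1), seed = 3)
  expect_equal(nrow(ep4), 4L * length(age_groups()))

  bad <- default_epi_ranges(); bad$incidence <- c(10, 5)
  expect_error(generate_disease_params("x", bad, seed = 1), "min > max")
  bad2 <- default_epi_ranges(); bad2$treatment_cost <- c(-5, 10)
  expect_error(generate_disease_params("x", bad2, seed = 1), "negative")
})

test_that("epi invariants hold property-wise over many seeds", {
  for (s in 1:25) {
    ep <- generate_disease_params(option_diseases(2), seed = s)
    expect_identical(generate_disease_params(option_diseases(2), seed = s), ep)
    expect_true(all(ep$cfr_treated <= ep$cfr_untreated))
    expect_true(all(ep$dw_treated <= ep$dw_untreated))
    expect_true(all(ep$dur_treated <= ep$dur_untreated))
    props <- c("cfr_treated", "cfr_untreated", "dw_treated", "dw_untreated",
               "coverage_baseline")
    for (nm in props) expect_true(all(ep[[nm]] >= 0 & ep[[nm]] <= 1))
    expect_true(all(ep$incidence >= 0 & ep$deaths >= 0 & ep$treatment_cost >= 0))
  }
})

test_that("portfolio and epi CSVs round-trip losslessly", {
  pf <- generate_portfolio(2, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_portfolio_csv(pf, f)
  back <- read_portfolio_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(pf))
  expect_equal(attr(back, "option_id"), attr(pf, "option_id"))

  ep <- generate_disease_params(option_diseases(1), seed = 8)
  g <- withr::local_tempfile(fileext = ".csv")
  write_epi_csv(ep, g)
  expect_equal(as.data.frame(read_epi_csv(g)), as.data.frame(ep),
               tolerance = 1e-12)
})

test_that("worked fixture is internally consistent and hand-checkable", {
  fx <- worked_fixture()
  expect_equal(sum(fx$portfolio$count), 1L)
  expect_equal(fx$portfolio$archetype, "vaccine-simple")
  expect_equal(fx$portfolio$phase_at_start, "phase2")
  expect_equal(yll_per_death(fx$epi), 30)
  expect_equal(expected_launch_probability("vaccine-simple", "phase2"),
               0.459 * 0.708)
})
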