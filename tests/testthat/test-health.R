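test_that("scenario rate endpoints reproduce the anchored reductions", {
  bl <- benin_baseline()
  sc <- builtin_scenarios()
  ep <- function(s) mortality_response(bl, s)
  expect_equal(ep(sc$base)$mmr_2030, 340)
  expect_equal(ep(sc$low)$mmr_2030, 300)
  expect_equal(ep(sc$moderate)$mmr_2030, 265.6)
  expect_equal(ep(sc$optimistic)$mmr_2030, 207.5)
  expect_equal(ep(sc$low)$u5mr_2030, 67.5)
  expect_equal(ep(sc$optimistic)$u5mr_2030, 75 - 42.6)
  # moderate U5MR: linear in 2030 CPR between the low and optimistic anchors
  expect_equal(ep(sc$moderate)$u5mr_2030,
               67.5 + (32.4 - 67.5) * (23.425 - 12.90) / (33.95 - 12.90))
  # infant endpoints never exceed the under-five endpoint
  for (s in sc) {
    e <- ep(s)
    expect_lte(e$imr_2030, e$u5mr_2030)
    expect_lte(e$mmr_2030, 340)
  }
})

test_that("rate trajectories follow contraceptive progress over the window", {
  bl <- benin_baseline()
  tr <- policy_trajectories(bl, builtin_scenarios()$optimistic)
  cpr <- dplyr::filter(tr, variable == "cpr_modern")
  mmr <- rate_trajectory(340, 207.5, cpr)
  expect_equal(mmr$rate[mmr$year == 2015], 340)
  expect_equal(mmr$rate[mmr$year == 2030], 207.5)
  # constant after 2030, base level before 2015
  expect_equal(mmr$rate[mmr$year > 2030], rep(207.5, 20))
  expect_equal(mmr$rate[mmr$year < 2015], rep(340, 5))
  # linear CPR makes the in-window decline linear in time
  win <- mmr$rate[mmr$year >= 2015 & mmr$year <= 2030]
  expect_equal(diff(win, differences = 2), rep(0, 14))
  # base scenario: constant regardless of CPR
  base_cpr <- dplyr::filter(policy_trajectories(bl, builtin_scenarios()$base),
                            variable == "cpr_modern")
  expect_equal(unique(rate_trajectory(340, 340, base_cpr)$rate), 340)
  expect_error(rate_trajectory(340, 207.5, base_cpr),
               class = "fp_domain_error")
})

test_that("death accounting follows the rate definitions", {
  b <- tibble::tibble(year = 2016, births = 1e5)
  r <- function(x) tibble::tibble(year = 2016, rate = x)
  expect_equal(maternal_deaths(b, r(340))$deaths, 340)
  expect_equal(maternal_deaths(b, r(0))$deaths, 0)
  expect_equal(infant_deaths(tibble::tibble(year = 2016, births = 1000),
                             r(46))$deaths, 46)
  expect_equal(under5_deaths(tibble::tibble(year = 2016, births = 0),
                             r(75), 0.9265)$deaths, 0)
  expect_error(under5_deaths(b, r(75), 1.2), class = "fp_domain_error")
  expect_error(under5_deaths(b, r(75), 0), class = "fp_domain_error")
  expect_error(maternal_deaths(b, tibble::tibble(year = 2017, rate = 340)),
               "mismatched")
})

test_that("averted tables satisfy averted = base - scenario and the printed row", {
  yrs <- 2015:2030
  lump <- function(total) tibble::tibble(
    year = yrs, deaths = c(0, rep(total / 15, 15)))
  deaths <- list(base = lump(24161), low = lump(22142),
                 moderate = lump(17760), optimistic = lump(14196))
  tab <- averted_table(deaths, milestones = 2030)
  at30 <- tab[tab$year == 2030, ]
  expect_equal(at30$deaths_averted[match(c("low", "moderate", "optimistic"),
                                         at30$scenario)],
               c(2019, 6401, 9965), tolerance = 1e-9)
  expect_equal(at30$deaths_averted[at30$scenario == "base"], 0)
  # under-five printed row
  tab5 <- averted_table(list(base = lump(493792), optimistic = lump(294932)),
                        milestones = 2030)
  expect_equal(tab5$deaths_averted[tab5$scenario == "optimistic" &
                                     tab5$year == 2030], 198860,
               tolerance = 1e-9)
  # window-start row is empty by convention
  expect_true(all(is.na(tab$cumulative_deaths[tab$year == 2015])))
  # scenario identical to base averts nothing
  same <- averted_table(list(base = lump(100), twin = lump(100)))
  expect_equal(unique(same$deaths_averted[same$scenario == "twin" &
                                            !is.na(same$deaths_averted)]), 0)
  expect_error(averted_table(list(base = lump(10),
                                  bad = tibble::tibble(year = 2016:2031,
                                                       deaths = 1))),
               "mismatched")
})

test_that("percent reduction reports at integer precision", {
  expect_identical(percent_reduction(340, 207.5), 39L)
  expect_identical(percent_reduction(75, 67.5), 10L)
  expect_identical(percent_reduction(50, 50), 0L)
  expect_error(percent_reduction(0, 10), class = "fp_domain_error")
})

test_that("engine outcome tables keep the accounting identities", {
  fit <- study_fit()
  for (oc in names(fit$outcomes)) {
    tab <- fit$outcomes[[oc]]
    for (m in milestone_years) {
      base <- cum_cell(fit, oc, "base", m)
      for (s in c("low", "moderate", "optimistic")) {
        row <- tab[tab$scenario == s & tab$year == m, ]
        expect_equal(row$deaths_averted, base - row$cumulative_deaths)
        expect_gte(row$deaths_averted, 0)
      }
    }
    # cumulative deaths non-decreasing in year within each scenario
    for (s in unique(tab$scenario)) {
      v <- tab$cumulative_deaths[tab$scenario == s & !is.na(tab$cumulative_deaths)]
      expect_true(all(diff(v) >= 0))
    }
  }
  # with constant base rates, maternal/infant cumulative ratio is fixed
  for (m in milestone_years) {
    expect_equal(cum_cell(fit, "maternal", "base", m) /
                   cum_cell(fit, "infant", "base", m),
                 (340 / 1e5) / (46 / 1e3), tolerance = 1e-9)
  }
})

test_that("deaths averted increase strictly with the strength of the scenario", {
  fit <- study_fit()
  for (oc in names(fit$outcomes)) {
    tab <- fit$outcomes[[oc]]
    for (m in milestone_years) {
      av <- vapply(c("low", "moderate", "optimistic"), function(s)
        tab$deaths_averted[tab$scenario == s & tab$year == m], numeric(1))
      expect_true(all(diff(av) > 0), info = paste(oc, m))
    }
  }
})
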