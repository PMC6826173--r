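test_that("projection equals an independent Leslie-matrix iteration", {
  bl <- benin_baseline()
  d <- bl$demography
  lts <- list(
    female = make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                             d$imr, d$u5mr, "female"),
    male = make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                           d$imr, d$u5mr, "male")
  )
  sf <- survival_schedule(lts$female)
  sm <- survival_schedule(lts$male)
  k <- 17
  aging <- function(p) {
    M <- matrix(0, k, k)
    for (i in seq_len(k)) M[i, i] <- p[i] * 4 / 5
    M[k, k] <- p[k]
    for (i in 2:k) M[i, i - 1] <- p[i - 1] / 5
    M
  }
  shape <- default_asfr_shape()
  w <- shape$weight / sum(shape$weight)
  fertile <- which(seq(0, 80, 5) %in% shape$age_start)
  tfr0 <- 4.9
  A <- matrix(0, 2 * k, 2 * k)
  A[1:k, 1:k] <- aging(sf$annual)
  A[(k + 1):(2 * k), (k + 1):(2 * k)] <- aging(sm$annual)
  frow <- numeric(k)
  frow[fertile] <- (tfr0 / 5) * w
  A[1, 1:k] <- A[1, 1:k] + (1 / 2.05) * sf$newborn * frow
  A[k + 1, 1:k] <- A[k + 1, 1:k] + (1.05 / 2.05) * sm$newborn * frow

  pyr <- d$pyramid
  x <- c(pyr$count[pyr$sex == "female"][order(pyr$age_start[pyr$sex == "female"])],
         pyr$count[pyr$sex == "male"][order(pyr$age_start[pyr$sex == "male"])])
  years <- 2010:2015
  proj <- project_population(pyr, tibble::tibble(year = years, tfr = tfr0),
                             lts, years)
  for (j in seq_along(years)) {
    got <- proj$pyramids[proj$pyramids$year == years[j], ]
    gotv <- c(got$count[got$sex == "female"][order(got$age_start[got$sex == "female"])],
              got$count[got$sex == "male"][order(got$age_start[got$sex == "male"])])
    expect_equal(gotv, x, tolerance = 1e-12)
    expect_equal(proj$series$births[j], sum(frow * x[1:k]), tolerance = 1e-12)
    x <- as.vector(A %*% x)
  }
})

test_that("population is conserved: survivors plus surviving newborns only", {
  # with certain survival, the population grows by exactly the births
  no_mort <- survival_schedule(annual = rep(1, 17), newborn = 1)
  lts <- list(female = no_mort, male = no_mort)
  pyr <- make_pyramid(1e6, 0.45, 0.03, 0.03)
  years <- 2010:2020
  proj <- project_population(pyr, tibble::tibble(year = years, tfr = 4),
                             lts, years)
  s <- proj$series
  expect_equal(diff(s$pop_total), s$births[-length(years)], tolerance = 1e-9)
})

test_that("zero fertility gives zero births and a shrinking population", {
  bl <- benin_baseline()
  d <- bl$demography
  lt <- make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                        d$imr, d$u5mr, "female")
  years <- 2010:2030
  proj <- project_population(d$pyramid,
                             tibble::tibble(year = years, tfr = 0),
                             list(female = lt, male = lt), years)
  expect_equal(proj$series$births, rep(0, length(years)))
  expect_true(all(diff(proj$series$pop_total) < 0))
})

test_that("empty pyramids are rejected", {
  bl <- benin_baseline()
  empty <- bl$demography$pyramid
  empty$count <- 0
  lt <- survival_schedule(annual = rep(1, 17), newborn = 1)
  expect_error(
    project_population(empty, tibble::tibble(year = 2010, tfr = 4),
                       list(female = lt, male = lt), 2010),
    class = "fp_validation_error")
})

test_that("dependency ratio matches its definition", {
  pyr <- tibble::tibble(age_start = c(0, 20, 70), count = c(46.7, 50.6, 2.7))
  expect_equal(dependency_ratio(pyr), (46.7 + 2.7) / 50.6)
  expect_equal(dependency_ratio(tibble::tibble(age_start = 30, count = 100)), 0)
  expect_error(dependency_ratio(tibble::tibble(age_start = 0, count = 10)),
               class = "fp_domain_error")
})

test_that("life-expectancy overlay is driven by under-five mortality", {
  lam <- 5.3 / 42.6
  const <- tibble::tibble(year = 2010:2030, u5mr = 75)
  e0 <- project_e0_female(const)
  # constant U5MR: constant e0 from 2015 on, linear bridge before
  expect_equal(e0$e0[e0$year >= 2015], rep(61.5, 16))
  expect_equal(e0$e0[e0$year == 2010], 59.6)
  expect_equal(e0$e0[e0$year == 2012], 59.6 + 2 / 5 * (61.5 - 59.6))
  # a 42.6-point decline buys the calibrated 5.3 years
  falling <- tibble::tibble(year = 2015:2030,
                            u5mr = seq(75, 75 - 42.6, length.out = 16))
  e0f <- project_e0_female(falling)
  expect_equal(e0f$e0[e0f$year == 2030], 61.5 + lam * 42.6)
  expect_equal(e0f$e0[e0f$year == 2030], 66.8)
})

test_that("births calibration hits the base-path cumulative-births targets", {
  fit <- study_fit()
  s <- fit$series[fit$series$scenario == "base", ]
  cb <- function(y) sum(s$births[s$year > 2015 & s$year <= y])
  expect_equal(cb(2030), 326883 / 0.046, tolerance = 1e-6)
  expect_equal(cb(2020), 94088 / 0.046, tolerance = 1e-6)
  expect_true(fit$calibration$birth_scale > 0.5 &&
                fit$calibration$birth_scale < 2)
})

test_that("stronger family planning gives smaller, less dependent populations", {
  fit <- study_fit()
  at <- function(scn, col) series_cell(fit, scn, 2030, col)
  ordering <- c("base", "low", "moderate", "optimistic")
  pop <- vapply(ordering, at, numeric(1), col = "pop_total")
  dep <- vapply(ordering, at, numeric(1), col = "dependency_ratio")
  expect_true(all(diff(pop) < 0))
  expect_true(all(diff(dep) < 0))
})
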