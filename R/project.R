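# Annual cohort-component population projection on 5-year age groups:
# one fifth of each group ages up every year, survival follows the life-table
# schedule, births come from an age-specific fertility shape scaled to the
# year's TFR, and the population is closed to migration.

#' Default age-specific fertility shape
#'
#' Relative fertility weights for the seven reproductive 5-year age groups
#' (15-19 ... 45-49) with the peak at 20-29, typical of West-African
#' schedules. Only the shape matters: [project_population()] rescales it each
#' year so that the implied age-specific rates sum to `TFR(t) / 5`.
#'
#' @return A tibble with columns `age_start`, `weight`.
#' @export
default_asfr_shape <- function() {
  tibble(
    age_start = seq(15, 45, 5),
    weight = c(0.094, 0.206, 0.214, 0.180, 0.130, 0.060, 0.016)
  )
}

#' Dependency ratio of a pyramid
#'
#' `(population 0-14 + population 65+) / population 15-64`.
#'
#' @param pyramid A pyramid tibble (columns `age_start`, `count`).
#' @return The dependency ratio (a fraction).
#' @examples
#' dependency_ratio(make_pyramid(1e6, 0.467, 0.027))
#' @export
dependency_ratio <- function(pyramid) {
  young <- sum(pyramid$count[pyramid$age_start < 15])
  work <- sum(pyramid$count[pyramid$age_start >= 15 & pyramid$age_start < 65])
  old <- sum(pyramid$count[pyramid$age_start >= 65])
  if (work <= 0) abort("zero working-age population", class = "fp_domain_error")
  (young + old) / work
}

#' Cohort-component population projection
#'
#' Advances an age-sex pyramid annually: each year, every 5-year group is
#' survived with its annual life-table probability and one fifth of it ages
#' into the next group; births are `scale * sum(ASFR(a) * women(a))` with the
#' packaged fertility shape rescaled to the year's TFR, split 1.05 male per
#' female at birth and survived into the 0-4 group. The population is closed
#' (no migration).
#'
#' @param pyramid Starting pyramid tibble (base year).
#' @param tfr Tibble with columns `year`, `tfr` covering every projection
#'   year.
#' @param life_tables List with elements `female` and `male`: `fp_life_table`
#'   or `fp_survival` objects.
#' @param years Projection years (first year is the pyramid's year).
#' @param asfr_shape Fertility shape tibble (see [default_asfr_shape()]).
#' @param birth_scale Scalar multiplier on the births level (see
#'   [calibrate_projection()]).
#' @return An `fp_projection`: list with `series` (tibble: `year`, `births`,
#'   `pop_total`, `pop_0_14`, `pop_15_64`, `pop_65plus`, `pop_15plus`,
#'   `women_15_49`, `dependency_ratio`, `tfr`) and `pyramids` (long tibble:
#'   `year`, `age_group`, `age_start`, `sex`, `count`).
#' @export
project_population <- function(pyramid, tfr, life_tables,
                               years = sort(unique(tfr$year)),
                               asfr_shape = default_asfr_shape(),
                               birth_scale = 1) {
  if (!is.data.frame(pyramid) || nrow(pyramid) == 0 || sum(pyramid$count) <= 0)
    abort("empty pyramid", class = "fp_validation_error")
  stopifnot(all(years %in% tfr$year))
  surv <- lapply(life_tables[c("female", "male")], function(x) {
    if (inherits(x, "fp_survival")) x else survival_schedule(x)
  })
  ord <- order(AGE_STARTS)
  nf <- pyramid$count[pyramid$sex == "female"][order(pyramid$age_start[pyramid$sex == "female"])]
  nm <- pyramid$count[pyramid$sex == "male"][order(pyramid$age_start[pyramid$sex == "male"])]
  fertile <- which(AGE_STARTS %in% asfr_shape$age_start)
  w <- asfr_shape$weight[match(AGE_STARTS[fertile], asfr_shape$age_start)]
  w <- w / sum(w)
  tfr_by_year <- setNames(tfr$tfr, tfr$year)
  female_frac <- 1 / 2.05

  n_years <- length(years)
  series <- vector("list", n_years)
  pyr_rows <- vector("list", n_years)

  age_step <- function(n, p, inflow) {
    k <- length(n)
    s <- n * p
    out <- numeric(k)
    out[1] <- s[1] * 4 / 5 + inflow
    for (i in 2:(k - 1)) out[i] <- s[i] * 4 / 5 + s[i - 1] / 5
    out[k] <- s[k] + s[k - 1] / 5
    out
  }

  for (j in seq_len(n_years)) {
    yr <- years[j]
    tfr_t <- tfr_by_year[[as.character(yr)]]
    births <- birth_scale * (tfr_t / 5) * sum(w * nf[fertile])
    young <- sum(nf[AGE_STARTS < 15]) + sum(nm[AGE_STARTS < 15])
    work <- sum(nf[AGE_STARTS >= 15 & AGE_STARTS < 65]) +
      sum(nm[AGE_STARTS >= 15 & AGE_STARTS < 65])
    old <- sum(nf[AGE_STARTS >= 65]) + sum(nm[AGE_STARTS >= 65])
    series[[j]] <- tibble(
      year = yr, births = births,
      pop_total = young + work + old,
      pop_0_14 = young, pop_15_64 = work, pop_65plus = old,
      pop_15plus = work + old,
      women_15_49 = sum(nf[AGE_STARTS >= 15 & AGE_STARTS < 50]),
      dependency_ratio = (young + old) / work,
      tfr = tfr_t
    )
    pyr_rows[[j]] <- tibble(
      year = yr,
      age_group = rep(age_group_labels(), 2),
      age_start = rep(AGE_STARTS, 2),
      sex = rep(c("female", "male"), each = length(AGE_STARTS)),
      count = c(nf, nm)
    )
    if (j < n_years) {
      bf <- births * female_frac * surv$female$newborn
      bm <- births * (1 - female_frac) * surv$male$newborn
      nf <- age_step(nf, surv$female$annual, bf)
      nm <- age_step(nm, surv$male$annual, bm)
    }
  }
  structure(list(series = bind_rows(series), pyramids = bind_rows(pyr_rows)),
            class = "fp_projection")
}

#' @export
print.fp_projection <- function(x, ...) {
  rng <- range(x$series$year)
  cat(sprintf("<fp_projection> %d-%d: population %s -> %s\n", rng[1], rng[2],
              format(round(x$series$pop_total[1]), big.mark = ","),
              format(round(x$series$pop_total[nrow(x$series)]), big.mark = ",")))
  invisible(x)
}

#' Study anchors used for calibration
#'
#' The printed study outputs the engine is calibrated against: the base-path
#' cumulative infant deaths at 2020 and 2030 (which, at the constant base IMR,
#' pin cumulative births over 2016-2020 and 2016-2030), the base under-five
#' 2030 cell (pinning the under-five window factor kappa), the base-path
#' female life expectancy at 2015, the optimistic e0 gain per unit U5MR
#' decline, and the base-2015 HDI level. Scenario 2030 mortality-rate
#' endpoints are also listed (MMR low/moderate/optimistic 300 / 265.6 / 207.5;
#' U5MR reductions 10 percent for low and 42.6 points for optimistic, the
#' moderate endpoint interpolated linearly in 2030 contraceptive prevalence).
#'
#' @return A named list of anchor constants.
#' @export
benin_anchors <- function() {
  list(
    window = c(2015, 2030),  # cumulative sums over (2015, 2030]
    cum_infant_deaths_2020 = 94088,
    cum_infant_deaths_2030 = 326883,
    cum_under5_deaths_2030 = 493792,
    e0_2010 = 59.6,
    e0_2015 = 61.5,
    e0_gain_optimistic = 5.3,
    u5mr_drop_optimistic = 42.6,
    hdi_2015 = 0.37,
    mmr_endpoints = c(low = 300, moderate = 265.6, optimistic = 207.5)
  )
}

#' Calibrate the projection to the base-path births implied by the study
#'
#' Two constants absorb the unprinted detail of the source model: the births
#' level scalar (a multiplier on the fertility schedule) and the base-year
#' pyramid's within-band taper (its shape parameter). They are fitted so the
#' base-scenario cumulative births over 2016-2020 and 2016-2030 equal the
#' values implied by the base-path cumulative infant deaths at constant IMR
#' (94,088 / 0.046 and 326,883 / 0.046). Maternal and under-five cells are
#' deliberately not used, so they remain out-of-sample checks.
#'
#' @param baseline An `fp_baseline`.
#' @param anchors Anchor list (see [benin_anchors()]).
#' @return A list with `birth_scale`, `taper`, `pyramid` (the recalibrated
#'   base-year pyramid), and `life_tables`.
#' @export
calibrate_projection <- function(baseline, anchors = benin_anchors()) {
  d <- baseline$demography
  target30 <- anchors$cum_infant_deaths_2030 / (d$imr / 1000)
  target20 <- anchors$cum_infant_deaths_2020 / (d$imr / 1000)
  lts <- list(
    female = make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                             d$imr, d$u5mr, "female"),
    male = make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                           d$imr, d$u5mr, "male")
  )
  total <- sum(d$pyramid$count)
  years <- baseline$meta$base_year:anchors$window[2]
  tfr_base <- tibble(year = years, tfr = d$tfr)
  cum_births <- function(proj, upto) {
    s <- proj$series
    sum(s$births[s$year > anchors$window[1] & s$year <= upto])
  }
  solve_scale <- function(pyr) {
    f <- function(s) {
      proj <- project_population(pyr, tfr_base, lts, years, birth_scale = s)
      cum_births(proj, anchors$window[2]) - target30
    }
    uniroot(f, c(0.1, 10), tol = 1e-9)$root
  }
  shape_gap <- function(taper) {
    pyr <- make_pyramid(total, share_0_14 = 0.467, share_65plus = 0.027,
                        taper = taper)
    s <- solve_scale(pyr)
    proj <- project_population(pyr, tfr_base, lts, years, birth_scale = s)
    cum_births(proj, 2020) - target20
  }
  taper <- uniroot(shape_gap, c(0.001, 0.09), tol = 1e-7)$root
  pyramid <- make_pyramid(total, share_0_14 = 0.467, share_65plus = 0.027,
                          taper = taper)
  birth_scale <- solve_scale(pyramid)
  list(birth_scale = birth_scale, taper = taper, pyramid = pyramid,
       life_tables = lts)
}

#' Project female life expectancy from the under-five mortality path
#'
#' Before 2015, life expectancy bridges linearly from its 2010 base value to
#' the 2015 level (a secular drift confined to the pre-reporting window).
#' From 2015 on it moves only with under-five mortality:
#' `e0(t) = e0(2015) + lambda * (U5MR(2015) - U5MR(t))`, with `lambda`
#' calibrated once as the optimistic e0 gain divided by the optimistic U5MR
#' decline (5.3 / 42.6 = 0.124 years per point).
#'
#' @param u5mr Tibble with columns `year`, `u5mr`.
#' @param e0_2015,e0_2010 Base-path life expectancy levels (years).
#' @param lambda Years of e0 per unit of U5MR decline.
#' @return A tibble with columns `year`, `e0`.
#' @export
project_e0_female <- function(u5mr,
                              e0_2015 = benin_anchors()$e0_2015,
                              e0_2010 = benin_anchors()$e0_2010,
                              lambda = benin_anchors()$e0_gain_optimistic /
                                benin_anchors()$u5mr_drop_optimistic) {
  u5mr_2015 <- u5mr$u5mr[u5mr$year == 2015]
  if (length(u5mr_2015) != 1) abort("u5mr trajectory must include 2015")
  e0 <- ifelse(
    u5mr$year < 2015,
    e0_2010 + (e0_2015 - e0_2010) * (u5mr$year - 2010) / 5,
    e0_2015 + lambda * (u5mr_2015 - u5mr$u5mr)
  )
  tibble(year = u5mr$year, e0 = e0)
}
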