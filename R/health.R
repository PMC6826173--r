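# Health outcomes: mortality-rate trajectories driven by contraceptive
# progress, annual deaths as births x rate (period accounting on the year of
# birth), cumulative milestone tables and deaths averted versus the base
# scenario.

#' Scenario 2030 mortality-rate endpoints
#'
#' Returns the 2030 MMR, U5MR and IMR endpoints for a scenario. The anchored
#' reductions are: MMR to 300 / 265.6 / 207.5 (low / moderate / optimistic)
#' from the base 340; U5MR down 10 percent under the low hypothesis and down
#' 42.6 points (from 75) under the optimistic one, with other scenarios
#' interpolated linearly in their 2030 modern contraceptive prevalence between
#' those two; the infant risk falls by the same relative amount as the
#' maternal risk (capped so `imr <= u5mr` is preserved), the reconstruction
#' consistent with the printed infant tables. Reductions are applied
#' multiplicatively, so a baseline with
#' different base rates gets the same relative response. The base scenario
#' keeps all rates constant.
#'
#' @param baseline An `fp_baseline`.
#' @param spec An `fp_scenario`.
#' @param anchors Anchor list (see [benin_anchors()]).
#' @return A tibble with columns `scenario`, `mmr_2030`, `u5mr_2030`,
#'   `imr_2030`, `cpr_modern_2030`.
#' @export
mortality_response <- function(baseline, spec, anchors = benin_anchors()) {
  d <- baseline$demography
  if (length(spec$targets) == 0) {
    return(tibble(scenario = spec$name, mmr_2030 = d$mmr, u5mr_2030 = d$u5mr,
                  imr_2030 = d$imr, cpr_modern_2030 = baseline$policy$cpr_modern))
  }
  y0 <- baseline$meta$base_year
  y1 <- baseline$meta$end_year
  cpr0 <- baseline$policy$cpr_modern
  cpr_2030 <- function(target) interpolate(cpr0, target, y0, y1, 2030)
  builtins <- builtin_scenarios()
  cpr_low <- cpr_2030(builtins$low$targets$cpr_modern)
  cpr_opt <- cpr_2030(builtins$optimistic$targets$cpr_modern)
  cpr_this <- cpr_2030(spec$targets$cpr_modern %||% cpr0)

  # U5MR: anchored reduction fractions at the low and optimistic 2030 CPRs,
  # linear in 2030 CPR elsewhere (this reconstructs the moderate endpoint)
  red_low <- 0.10
  red_opt <- anchors$u5mr_drop_optimistic / 75
  frac <- (cpr_this - cpr_low) / (cpr_opt - cpr_low)
  red_u5 <- red_low + (red_opt - red_low) * frac
  u5mr_2030 <- d$u5mr * (1 - red_u5)

  mmr_anchor <- anchors$mmr_endpoints
  mmr_2030 <- if (spec$name %in% names(mmr_anchor)) {
    d$mmr * mmr_anchor[[spec$name]] / 340
  } else {
    red_m <- (1 - mmr_anchor[["low"]] / 340) +
      ((1 - mmr_anchor[["optimistic"]] / 340) - (1 - mmr_anchor[["low"]] / 340)) * frac
    d$mmr * (1 - red_m)
  }
  tibble(scenario = spec$name, mmr_2030 = mmr_2030, u5mr_2030 = u5mr_2030,
         imr_2030 = pmin(d$imr * mmr_2030 / d$mmr, u5mr_2030),
         cpr_modern_2030 = cpr_this)
}

#' Mortality-rate trajectory driven by contraceptive progress
#'
#' `rate(t) = base_rate - (base_rate - endpoint_2030) * progress(t)` with
#' `progress(t) = (cpr(t) - cpr(2015)) / (cpr(2030) - cpr(2015))`, clamped to
#' \[0, 1\] (rates are at their base value before 2015 and constant after
#' 2030 for reporting purposes). With no rate change the trajectory is
#' constant regardless of the contraceptive path.
#'
#' @param base_rate Base-year rate.
#' @param endpoint_2030 Scenario 2030 endpoint (equal to `base_rate` for the
#'   base scenario).
#' @param cpr_trajectory Tibble with columns `year`, `value`: the scenario's
#'   modern-CPR path.
#' @return A tibble with columns `year`, `rate`.
#' @export
rate_trajectory <- function(base_rate, endpoint_2030, cpr_trajectory) {
  stopifnot(base_rate >= 0, endpoint_2030 >= 0)
  yrs <- cpr_trajectory$year
  cpr <- cpr_trajectory$value
  if (base_rate == endpoint_2030)
    return(tibble(year = yrs, rate = rep(base_rate, length(yrs))))
  c15 <- cpr[yrs == 2015]
  c30 <- cpr[yrs == 2030]
  if (length(c15) != 1 || length(c30) != 1)
    abort("cpr trajectory must cover 2015 and 2030")
  if (c30 == c15)
    abort("zero CPR progress with nonzero rate change",
          class = "fp_domain_error")
  progress <- pmin(pmax((cpr - c15) / (c30 - c15), 0), 1)
  tibble(year = yrs, rate = base_rate - (base_rate - endpoint_2030) * progress)
}

check_deaths_inputs <- function(births, rates) {
  if (any(births$births < 0) || any(rates$rate < 0))
    abort("births and rates must be non-negative")
  if (!all(births$year %in% rates$year))
    abort("mismatched year spans between births and rate trajectory")
}

#' Annual maternal deaths
#'
#' `deaths(t) = births(t) * MMR(t) / 100,000` (period accounting on the year
#' of birth).
#'
#' @param births Tibble with columns `year`, `births`.
#' @param mmr Tibble with columns `year`, `rate` (per 100,000 live births).
#' @return A tibble with columns `year`, `deaths`.
#' @export
maternal_deaths <- function(births, mmr) {
  check_deaths_inputs(births, mmr)
  r <- mmr$rate[match(births$year, mmr$year)]
  tibble(year = births$year, deaths = births$births * r / 1e5)
}

#' Annual infant deaths
#'
#' `deaths(t) = births(t) * IMR(t) / 1,000`.
#'
#' @inheritParams maternal_deaths
#' @param imr Tibble with columns `year`, `rate` (per 1,000 live births).
#' @return A tibble with columns `year`, `deaths`.
#' @export
infant_deaths <- function(births, imr) {
  check_deaths_inputs(births, imr)
  r <- imr$rate[match(births$year, imr$year)]
  tibble(year = births$year, deaths = births$births * r / 1e3)
}

#' Annual under-five deaths
#'
#' `deaths(t) = births(t) * kappa * U5MR(t) / 1,000`, attributing a birth
#' cohort's under-five deaths to its birth year. The window factor `kappa`
#' (in (0, 1\]) captures the part of lifetime under-five mortality the
#' reporting convention counts inside the window; it is calibrated once on
#' the base-scenario 2030 cell (about 0.9265) and validated on the 2020 and
#' 2025 cells.
#'
#' @inheritParams maternal_deaths
#' @param u5mr Tibble with columns `year`, `rate` (per 1,000 live births).
#' @param kappa Under-five window factor.
#' @return A tibble with columns `year`, `deaths`.
#' @export
under5_deaths <- function(births, u5mr, kappa) {
  if (!(kappa > 0 && kappa <= 1))
    abort("kappa must be in (0, 1]", class = "fp_domain_error")
  check_deaths_inputs(births, u5mr)
  r <- u5mr$rate[match(births$year, u5mr$year)]
  tibble(year = births$year, deaths = births$births * kappa * r / 1e3)
}

#' Cumulative deaths and deaths averted at milestone years
#'
#' Cumulates annual deaths over the reporting window (years after
#' `window_start`, so the `window_start` row is empty by convention) and
#' takes base-minus-scenario differences. The identity
#' `averted = base - scenario` holds exactly, to the person, in the emitted
#' table.
#'
#' @param deaths Named list of annual-deaths tibbles (columns `year`,
#'   `deaths`); must contain an element named `base`.
#' @param milestones Milestone years to report.
#' @param window_start Cumulation starts after this year.
#' @return A tibble with columns `year`, `scenario`, `cumulative_deaths`,
#'   `deaths_averted` (`NA` in the `window_start` row; 0 for the base
#'   scenario).
#' @examples
#' b <- tibble::tibble(year = 2015:2030, deaths = 100)
#' s <- tibble::tibble(year = 2015:2030, deaths = 80)
#' averted_table(list(base = b, fp = s), milestones = 2030)
#' @export
averted_table <- function(deaths, milestones = c(2020, 2025, 2030),
                          window_start = 2015) {
  if (!"base" %in% names(deaths)) abort("deaths list must contain 'base'")
  yrs <- deaths$base$year
  for (nm in names(deaths)) {
    if (!identical(sort(deaths[[nm]]$year), sort(yrs)))
      abort("mismatched year spans across scenarios")
  }
  cum_at <- function(d, m) sum(d$deaths[d$year > window_start & d$year <= m])
  purrr::map_dfr(names(deaths), function(nm) {
    purrr::map_dfr(c(window_start, milestones), function(m) {
      if (m <= window_start)
        return(tibble(year = m, scenario = nm, cumulative_deaths = NA_real_,
                      deaths_averted = NA_real_))
      cum <- cum_at(deaths[[nm]], m)
      tibble(year = m, scenario = nm, cumulative_deaths = cum,
             deaths_averted = cum_at(deaths$base, m) - cum)
    })
  })
}

#' Percent reduction of a rate
#'
#' `100 * (base - projected) / base`, rounded to the nearest integer for
#' reporting.
#'
#' @param base_rate Base rate (> 0).
#' @param projected_rate Projected rate.
#' @return Integer percent reduction.
#' @examples
#' percent_reduction(340, 207.5) # 39
#' @export
percent_reduction <- function(base_rate, projected_rate) {
  if (base_rate <= 0) abort("base rate must be > 0", class = "fp_domain_error")
  as.integer(round(100 * (base_rate - projected_rate) / base_rate))
}
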