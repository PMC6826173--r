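# Orchestrator: baseline -> scenarios -> fertility -> population ->
# health outcomes -> economy, returning a single fitted-object-like result
# with tidy(), glance() and autoplot() methods.

#' Run the full demographic-economic scenario projection
#'
#' Executes the whole pipeline for a set of scenarios: policy trajectories,
#' the Bongaarts-index TFR response, the annual cohort-component population
#' projection, mortality-rate trajectories and cumulative deaths/averted
#' tables over the reporting window, the life-expectancy overlay, and the
#' economic component. With `calibrate = TRUE` (the study configuration) the
#' births level and pyramid shape are first fitted to the base-path infant
#' identity, the under-five window factor kappa to the base 2030 under-five
#' cell, and the HDI constant to the base 2015 level.
#'
#' @param baseline An `fp_baseline`.
#' @param scenarios Named list of [scenario_spec()] objects; must include one
#'   named `"base"` (the reference).
#' @param window Reporting window `c(start, end)`; cumulative sums cover
#'   years after `start` up to `end`.
#' @param milestones Milestone years for the outcome tables.
#' @param calibrate Logical; fit the study calibration constants (requires
#'   the anchors to be meaningful for the baseline) or use neutral defaults.
#' @param anchors Anchor list (see [benin_anchors()]).
#' @return An `fp_dividend` object: list with `series` (per year x scenario:
#'   population aggregates, TFR, dependency ratio, e0, economy columns),
#'   `rates` (year x scenario MMR/IMR/U5MR), `outcomes` (list of maternal /
#'   under5 / infant milestone tibbles), `pyramids`, `calibration`,
#'   `baseline`, `window`, `milestones`.
#' @examples
#' \donttest{
#' fit <- project_dividend(benin_baseline())
#' glance(fit)
#' }
#' @export
project_dividend <- function(baseline,
                             scenarios = builtin_scenarios(),
                             window = c(2015, 2030),
                             milestones = c(2020, 2025, 2030),
                             calibrate = TRUE,
                             anchors = benin_anchors()) {
  validate_baseline(baseline)
  if (!"base" %in% names(scenarios))
    abort("scenarios must include a reference scenario named 'base'")
  years <- baseline$meta$base_year:baseline$meta$end_year
  d <- baseline$demography

  if (calibrate) {
    cal <- calibrate_projection(baseline, anchors)
  } else {
    cal <- list(
      birth_scale = 1, taper = NA_real_, pyramid = d$pyramid,
      life_tables = list(
        female = make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                                 d$imr, d$u5mr, "female"),
        male = make_life_table(d$e0_female, d$e0_gap_female_minus_male,
                               d$imr, d$u5mr, "male")
      )
    )
  }
  lambda <- anchors$e0_gain_optimistic / anchors$u5mr_drop_optimistic

  per_scenario <- purrr::map(scenarios, function(spec) {
    traj <- policy_trajectories(baseline, spec, years)
    tfr <- project_tfr(baseline, traj, years)
    proj <- project_population(cal$pyramid, tfr[, c("year", "tfr")],
                               cal$life_tables, years,
                               birth_scale = cal$birth_scale)
    endpoints <- mortality_response(baseline, spec, anchors)
    cpr_traj <- dplyr::filter(traj, .data$variable == "cpr_modern")
    rates <- tibble(
      year = years,
      scenario = spec$name,
      mmr = rate_trajectory(d$mmr, endpoints$mmr_2030, cpr_traj)$rate,
      imr = rate_trajectory(d$imr, endpoints$imr_2030, cpr_traj)$rate,
      u5mr = rate_trajectory(d$u5mr, endpoints$u5mr_2030, cpr_traj)$rate
    )
    e0 <- project_e0_female(rates[, c("year", "u5mr")],
                            e0_2015 = anchors$e0_2015,
                            e0_2010 = anchors$e0_2010, lambda = lambda)
    list(spec = spec, trajectories = traj, proj = proj, rates = rates, e0 = e0)
  })

  base_births <- per_scenario$base$proj$series[, c("year", "births")]
  cum_births_end <- sum(base_births$births[base_births$year > window[1] &
                                             base_births$year <= window[2]])
  kappa <- if (calibrate) {
    anchors$cum_under5_deaths_2030 / (cum_births_end * d$u5mr / 1000)
  } else {
    0.9265
  }

  deaths <- list(maternal = list(), under5 = list(), infant = list())
  for (nm in names(per_scenario)) {
    ps <- per_scenario[[nm]]
    births <- ps$proj$series[, c("year", "births")]
    r <- function(col) tibble(year = ps$rates$year, rate = ps$rates[[col]])
    deaths$maternal[[nm]] <- maternal_deaths(births, r("mmr"))
    deaths$under5[[nm]] <- under5_deaths(births, r("u5mr"), kappa)
    deaths$infant[[nm]] <- infant_deaths(births, r("imr"))
  }
  outcomes <- purrr::map(deaths, averted_table, milestones = milestones,
                         window_start = window[1])

  # HDI calibration on the base path at the window start
  econ0 <- project_economy(baseline, per_scenario$base$proj$series,
                           per_scenario$base$e0, hdi_scale = 1)
  raw_hdi <- econ0$hdi[econ0$year == window[1]] /
    1  # raw geometric-mean value at scale 1
  hdi_scale <- if (calibrate && length(raw_hdi) == 1 && raw_hdi > 0) {
    anchors$hdi_2015 / raw_hdi
  } else {
    1
  }

  series <- purrr::map_dfr(names(per_scenario), function(nm) {
    ps <- per_scenario[[nm]]
    econ <- project_economy(baseline, ps$proj$series, ps$e0,
                            hdi_scale = hdi_scale)
    ps$proj$series |>
      mutate(scenario = nm) |>
      left_join(ps$e0, by = "year") |>
      left_join(econ, by = "year") |>
      select("year", "scenario", dplyr::everything())
  })
  pyramids <- purrr::map_dfr(names(per_scenario), function(nm) {
    mutate(per_scenario[[nm]]$proj$pyramids, scenario = nm)
  })
  rates <- purrr::map_dfr(per_scenario, "rates")
  trajectories <- purrr::map_dfr(names(per_scenario), function(nm) {
    mutate(per_scenario[[nm]]$trajectories, scenario = nm)
  })

  structure(
    list(
      baseline = baseline,
      scenarios = purrr::map(per_scenario, "spec"),
      series = series,
      rates = rates,
      trajectories = trajectories,
      outcomes = outcomes,
      pyramids = pyramids,
      calibration = list(birth_scale = cal$birth_scale, taper = cal$taper,
                         kappa = kappa, lambda = lambda,
                         hdi_scale = hdi_scale),
      window = window,
      milestones = milestones
    ),
    class = "fp_dividend"
  )
}

#' @export
print.fp_dividend <- function(x, ...) {
  cat("<fp_dividend>", x$baseline$meta$country,
      sprintf("| scenarios: %s | window %d-%d\n",
              paste(names(x$scenarios), collapse = ", "),
              x$window[1], x$window[2]))
  cat(sprintf("  calibration: birth_scale %.4f, taper %.4f, kappa %.4f, lambda %.4f, hdi_scale %.4f\n",
              x$calibration$birth_scale, x$calibration$taper,
              x$calibration$kappa, x$calibration$lambda,
              x$calibration$hdi_scale))
  invisible(x)
}

#' Tidy the milestone outcome tables of a projection
#'
#' @param x An `fp_dividend`.
#' @param ... Unused.
#' @return A long tibble: `outcome` (maternal/under5/infant), `year`,
#'   `scenario`, `cumulative_deaths`, `deaths_averted`.
#' @export
tidy.fp_dividend <- function(x, ...) {
  purrr::map_dfr(names(x$outcomes), function(nm) {
    mutate(x$outcomes[[nm]], outcome = nm) |>
      select("outcome", dplyr::everything())
  })
}

#' One-row summary of a projection
#'
#' @param x An `fp_dividend`.
#' @param ... Unused.
#' @return A one-row tibble with calibration constants and headline 2030
#'   base-vs-most-ambitious quantities.
#' @export
glance.fp_dividend <- function(x, ...) {
  yend <- x$window[2]
  s <- x$series
  sc <- names(x$scenarios)
  last_fp <- if (length(sc) > 1) sc[length(sc)] else "base"
  pick <- function(scn, col) s[[col]][s$scenario == scn & s$year == yend]
  mat <- x$outcomes$maternal
  averted <- mat$deaths_averted[mat$scenario == last_fp & mat$year == yend]
  tibble(
    country = x$baseline$meta$country,
    n_scenarios = length(sc),
    window_start = x$window[1],
    window_end = yend,
    birth_scale = x$calibration$birth_scale,
    taper = x$calibration$taper,
    kappa = x$calibration$kappa,
    lambda = x$calibration$lambda,
    hdi_scale = x$calibration$hdi_scale,
    tfr_base_end = pick("base", "tfr"),
    tfr_fp_end = pick(last_fp, "tfr"),
    dependency_base_end = pick("base", "dependency_ratio"),
    maternal_averted_fp_end = if (length(averted)) averted else NA_real_
  )
}

#' Plot a scenario projection
#'
#' @param object An `fp_dividend`.
#' @param type One of `"averted"` (cumulative deaths averted by outcome and
#'   scenario), `"rates"` (MMR/IMR/U5MR trajectories), `"tfr"`, or
#'   `"population"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_dividend <- function(object, type = c("averted", "rates", "tfr",
                                                  "population"), ...) {
  type <- match.arg(type)
  if (type == "averted") {
    dat <- tidy(object) |>
      filter(.data$scenario != "base", !is.na(.data$deaths_averted))
    return(
      ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$deaths_averted,
                                        colour = .data$scenario)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::facet_wrap(~outcome, scales = "free_y") +
        ggplot2::labs(x = NULL, y = "Cumulative deaths averted vs base")
    )
  }
  if (type == "rates") {
    dat <- tidyr::pivot_longer(object$rates, c("mmr", "imr", "u5mr"),
                               names_to = "rate", values_to = "value")
    return(
      ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$value,
                                        colour = .data$scenario)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~rate, scales = "free_y") +
        ggplot2::labs(x = NULL, y = "Rate")
    )
  }
  col <- if (type == "tfr") "tfr" else "pop_total"
  lab <- if (type == "tfr") "Total fertility rate" else "Total population"
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$year, .data[[col]],
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = lab)
}
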