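# Scenarios: named end-year (2050) policy targets plus a linear interpolation
# rule turning them into per-year policy-variable trajectories.

#' Create a scenario specification
#'
#' A scenario is a named map from policy variables to end-year (2050) target
#' values, interpolated linearly in calendar year from the base-year value.
#' The base scenario has an empty target map (all variables constant).
#'
#' @param name Scenario label.
#' @param targets Named list/vector of end-year targets (fraction units for
#'   CPR and sterility).
#' @param interpolation Interpolation rule tag; only `"linear"` is supported.
#' @return An `fp_scenario` object.
#' @examples
#' scenario_spec("custom", targets = list(cpr_modern = 0.45))
#' @export
scenario_spec <- function(name, targets = list(), interpolation = "linear") {
  if (!identical(interpolation, "linear"))
    abort("only linear interpolation is supported")
  targets <- as.list(targets)
  unknown <- setdiff(names(targets), POLICY_FIELDS)
  if (length(unknown) > 0)
    abort(paste("unknown policy variable(s) in targets:",
                paste(unknown, collapse = ", ")))
  structure(list(name = name, targets = targets, interpolation = interpolation),
            class = "fp_scenario")
}

#' @export
print.fp_scenario <- function(x, ...) {
  cat("<fp_scenario>", x$name, "\n")
  if (length(x$targets) == 0) {
    cat("  no targets (all policy variables constant)\n")
  } else {
    for (v in names(x$targets))
      cat(sprintf("  %s -> %s by end year\n", v, format(x$targets[[v]])))
  }
  invisible(x)
}

#' Built-in family-planning scenarios
#'
#' The four study scenarios: `base` (no policy change) and three
#' family-planning hypotheses that move modern contraceptive prevalence among
#' married women from 7.9 percent (2010) to an end-year (2050) level of
#' 17.9 percent (`low`, the historical pace), 38.95 percent (`moderate`, the
#' midpoint of the low and optimistic end levels), or 60 percent
#' (`optimistic`, the FP2020-commitment pace). All three move traditional
#' prevalence from 5 to 2 percent and sterility among women 45-49 from 4.1 to
#' 3.0 percent, leave postpartum insusceptibility at 12.3 months, and keep
#' every education and economic variable at its base value.
#'
#' @return A named list of [scenario_spec()] objects
#'   (`base`, `low`, `moderate`, `optimistic`).
#' @examples
#' builtin_scenarios()$optimistic
#' @export
builtin_scenarios <- function() {
  fp <- function(cpr_modern_end) {
    list(cpr_modern = cpr_modern_end, cpr_traditional = 0.02,
         sterility_45_49 = 0.030)
  }
  list(
    base = scenario_spec("base", targets = list()),
    low = scenario_spec("low", targets = fp(0.179)),
    moderate = scenario_spec("moderate", targets = fp((0.179 + 0.60) / 2)),
    optimistic = scenario_spec("optimistic", targets = fp(0.60))
  )
}

#' Linear interpolation between base-year and end-year values
#'
#' Affine in calendar year, exact at both endpoints. Used for every policy
#' trajectory.
#'
#' @param base_value,end_value Values at `base_year` and `end_year`.
#' @param base_year,end_year Span endpoints (`base_year < end_year`).
#' @param query_year Year(s) at which to evaluate; must lie inside the span.
#' @return Interpolated value(s).
#' @examples
#' interpolate(7.9, 60, 2010, 2050, 2030) # 33.95
#' @export
interpolate <- function(base_value, end_value, base_year, end_year, query_year) {
  if (!(base_year < end_year)) abort("base_year must be < end_year")
  if (any(query_year < base_year | query_year > end_year))
    abort("query_year outside [base_year, end_year]",
          class = "fp_range_error")
  base_value + (end_value - base_value) *
    (query_year - base_year) / (end_year - base_year)
}

#' Per-year policy-variable trajectories under a scenario
#'
#' Untargeted variables stay constant at their baseline value; targeted
#' variables move linearly from the base-year value to the scenario's end-year
#' target.
#'
#' @param baseline An `fp_baseline` (its `policy` component is used).
#' @param spec An `fp_scenario`.
#' @param years Projection years (default base to end year of the baseline).
#' @return A tibble with columns `year`, `variable`, `value` covering every
#'   policy variable and year.
#' @examples
#' bl <- benin_baseline()
#' tr <- policy_trajectories(bl, builtin_scenarios()$optimistic)
#' dplyr::filter(tr, variable == "cpr_modern", year == 2030)
#' @export
policy_trajectories <- function(baseline, spec,
                                years = seq(baseline$meta$base_year,
                                            baseline$meta$end_year)) {
  stopifnot(inherits(baseline, "fp_baseline"), inherits(spec, "fp_scenario"))
  y0 <- baseline$meta$base_year
  y1 <- baseline$meta$end_year
  purrr::map_dfr(POLICY_FIELDS, function(v) {
    v0 <- baseline$policy[[v]]
    value <- if (v %in% names(spec$targets)) {
      interpolate(v0, spec$targets[[v]], y0, y1, years)
    } else {
      rep(v0, length(years))
    }
    tibble(year = years, variable = v, value = value)
  })
}

trajectory_value <- function(trajectories, var, year) {
  out <- trajectories$value[trajectories$variable == var &
                              trajectories$year %in% year]
  if (length(out) != length(year))
    abort(paste("trajectory not defined for", var, "at requested year(s)"))
  out
}
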