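# Run orchestration: execute the pipeline on a config file, emit the CSV
# outputs (milestone outcome tables, rates, trajectories, economy, pyramid
# snapshots) and a JSON run manifest with content checksums.

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

outcome_wide <- function(tab, scenario_order) {
  scen <- intersect(scenario_order, unique(tab$scenario))
  fp <- setdiff(scen, "base")
  wide <- tab |>
    mutate(cumulative_deaths = round_half_up(.data$cumulative_deaths)) |>
    select("year", "scenario", "cumulative_deaths") |>
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = "cumulative_deaths",
                       names_prefix = "cumulative_")
  # emitted averted columns equal base minus scenario to the person
  for (s in fp) {
    wide[[paste0("averted_", s)]] <-
      wide[["cumulative_base"]] - wide[[paste0("cumulative_", s)]]
  }
  wide[, c("year", paste0("cumulative_", scen),
           if (length(fp)) paste0("averted_", fp))]
}

#' Run the projection from a config file and write all outputs
#'
#' Loads (or accepts) a baseline, runs [project_dividend()] for the requested
#' scenarios and writes the milestone outcome tables (maternal, under-five,
#' infant; cumulative deaths rounded to persons, averted columns exactly base
#' minus scenario), the rate trajectories (1 decimal), the policy and TFR
#' trajectories, the economy series, pyramid snapshots at the milestone
#' years, and a JSON run manifest listing every file with an MD5 checksum and
#' the calibration constants. Identical inputs and seed give bit-identical
#' CSVs.
#'
#' @param config Path to a baseline config file, or an `fp_baseline`.
#' @param scenarios Character vector of built-in scenario names, or a named
#'   list of [scenario_spec()] objects (must include `"base"`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and applied to any
#'   randomness.
#' @param calibrate Passed to [project_dividend()].
#' @param end_year Optional override of the baseline's projection end year.
#' @param window Reporting window `c(start, end)` passed to
#'   [project_dividend()].
#' @return The manifest, invisibly, as a list; also written to
#'   `manifest.json`.
#' @export
run_projection <- function(config, scenarios = c("base", "low", "moderate",
                                                 "optimistic"),
                           out_dir, seed = 1, calibrate = TRUE,
                           end_year = NULL, window = c(2015, 2030)) {
  set.seed(seed)
  baseline <- if (inherits(config, "fp_baseline")) config else load_baseline(config)
  if (!is.null(end_year)) baseline$meta$end_year <- end_year
  if (is.character(scenarios)) {
    pool <- builtin_scenarios()
    unknown <- setdiff(scenarios, names(pool))
    if (length(unknown) > 0)
      abort(paste("unknown scenario name(s):", paste(unknown, collapse = ", ")),
            class = "fp_validation_error")
    scenarios <- pool[scenarios]
  }
  message("stage: projection (", paste(names(scenarios), collapse = ", "), ")")
  fit <- tryCatch(
    project_dividend(baseline, scenarios, window = window,
                     calibrate = calibrate),
    error = function(e) abort(paste("projection stage failed:",
                                    conditionMessage(e)), parent = e)
  )
  message(sprintf(
    "calibration: birth_scale=%.5f taper=%.5f kappa=%.5f lambda=%.5f hdi_scale=%.5f",
    fit$calibration$birth_scale, fit$calibration$taper, fit$calibration$kappa,
    fit$calibration$lambda, fit$calibration$hdi_scale))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen_order <- names(fit$scenarios)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
    path
  }
  for (nm in names(fit$outcomes))
    emit(outcome_wide(fit$outcomes[[nm]], scen_order),
         paste0("table_", nm, ".csv"))
  emit(mutate(fit$rates, across(c("mmr", "imr", "u5mr"),
                                ~ round_half_up(.x, 1))), "rates.csv")
  emit(fit$trajectories, "trajectories.csv")
  emit(fit$series |>
         mutate(tfr = round_half_up(.data$tfr, 2)) |>
         select("year", "scenario", "births", "pop_total", "dependency_ratio",
                "tfr", "e0", "gdp_pc", "hdi", "capital_pc", "employment"),
       "series.csv")
  emit(filter(fit$pyramids,
              .data$year %in% c(fit$window[1], fit$milestones)),
       "pyramids.csv")

  manifest <- list(
    engine = "fpdividend",
    version = as.character(utils::packageVersion("fpdividend")),
    config = if (is.character(config)) config else "<in-memory baseline>",
    country = baseline$meta$country,
    scenarios = scen_order,
    seed = seed,
    calibration = fit$calibration,
    window = fit$window,
    milestones = fit$milestones,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$fit <- fit
  invisible(manifest)
}

#' Render a plain-text summary of a completed run
#'
#' Headline numbers at the paper's rounding conventions: cumulative deaths as
#' integers with an approximate thousands-rounded rendering, TFR to 2
#' decimals, rates to 1 decimal.
#'
#' @param manifest The list returned by [run_projection()] (with its `fit`),
#'   or an `fp_dividend` object.
#' @return A character vector of report lines, invisibly; also printed.
#' @export
render_summary <- function(manifest) {
  fit <- if (inherits(manifest, "fp_dividend")) manifest else manifest$fit
  if (is.null(fit)) abort("incomplete manifest: no fitted projection attached")
  yend <- fit$window[2]
  scen <- names(fit$scenarios)
  fp <- setdiff(scen, "base")
  lines <- c(
    sprintf("Family-planning scenario projection: %s, window %d-%d",
            fit$baseline$meta$country, fit$window[1], yend),
    sprintf("Scenarios: %s", paste(scen, collapse = ", "))
  )
  tfr_line <- function(s) {
    v <- fit$series$tfr[fit$series$scenario == s & fit$series$year == yend]
    sprintf("  TFR %d [%s]: %.2f", yend, s, v)
  }
  lines <- c(lines, vapply(scen, tfr_line, character(1)))
  if (length(fp) == 0) {
    lines <- c(lines, "no deaths averted (reference scenario)")
  } else {
    for (nm in names(fit$outcomes)) {
      tab <- fit$outcomes[[nm]]
      for (s in fp) {
        av <- tab$deaths_averted[tab$scenario == s & tab$year == yend]
        lines <- c(lines, sprintf(
          "  %s deaths averted by %d [%s]: %s (~%s)", nm, yend, s,
          format(round_half_up(av), big.mark = ","),
          format(round_half_up(av, -3), big.mark = ",")))
      }
    }
    mmr30 <- fit$rates$mmr[fit$rates$year == yend & fit$rates$scenario == fp[length(fp)]]
    mmr0 <- fit$baseline$demography$mmr
    lines <- c(lines, sprintf(
      "  MMR %d [%s]: %.1f (risk of maternal death reduced by %d%%)",
      yend, fp[length(fp)], mmr30, percent_reduction(mmr0, mmr30)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
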