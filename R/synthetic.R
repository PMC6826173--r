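# Synthetic country baselines: valid random draws inside West-African
# plausibility ranges, for property testing every stage of the pipeline
# without real data beyond the packaged fixture.

#' Default sampling ranges for synthetic baselines
#'
#' Per-field (min, max) bounds bracketing West-African plausibility: TFR 3-8,
#' IMR 20-100 with U5MR between 1 and 2 times the IMR (joint constraint
#' enforced at sampling time), MMR 100-1,000, modern CPR 2-35 percent,
#' traditional CPR 0-15 percent, effectiveness 0.85-0.98 (modern) and
#' 0.3-0.7 (traditional), female e0 45-70 years, and broad positive ranges
#' for the education, institutional and economic variables.
#'
#' @return A named list of `c(min, max)` bounds, plus pyramid bounds.
#' @export
baseline_ranges <- function() {
  list(
    policy = list(
      expected_school_years_f = c(4, 13), expected_school_years_m = c(5, 14),
      mean_school_years_f = c(1, 8), mean_school_years_m = c(2, 9),
      mean_school_years_both = c(1.5, 8.5),
      cpr_modern = c(0.02, 0.35), cpr_traditional = c(0, 0.15),
      postpartum_insusceptibility = c(6, 24),
      sterility_45_49 = c(0.01, 0.10),
      gci_public_institutions = c(2, 5), gci_labor_flexibility = c(2, 5),
      gci_financial_efficiency = c(2, 5), gci_ict_use = c(1.5, 5),
      imports_pct_gdp = c(15, 60)
    ),
    demography = list(
      tfr = c(3, 8), pct_married = c(0.5, 0.85),
      pct_births_at_risk = c(0.3, 0.7),
      imr = c(20, 100), u5mr_over_imr = c(1, 2), mmr = c(100, 1000),
      eff_modern = c(0.85, 0.98), eff_traditional = c(0.3, 0.7),
      e0_female = c(45, 70), e0_gap_female_minus_male = c(1, 6)
    ),
    economy = list(
      gdp_pc = c(300, 3000), gdp_growth = c(0.01, 0.08),
      capital_formation_pc = c(50, 600), capital_stock_growth = c(0, 0.05),
      depreciation = c(0.02, 0.08),
      initial_employment_15plus = c(5e5, 2e7),
      employment_growth = c(0.01, 0.05),
      labor_force_participation = c(0.5, 1),
      primary_edu_cost_pct_gdp_pc = c(5, 30),
      capital_stock_per_15plus = c(2000, 30000)
    ),
    pyramid = list(
      total = c(2e6, 3e7), share_0_14 = c(0.38, 0.48),
      share_65plus = c(0.02, 0.05), taper = c(0.015, 0.055)
    )
  )
}

#' Draw a random, valid synthetic country baseline
#'
#' Uniform draws inside [baseline_ranges()], with joint constraints
#' (`imr <= u5mr`, CPR sum, the Bongaarts domain condition, employment below
#' the working-age population) enforced by construction or rejection
#' sampling. Deterministic under `seed`. Degenerate ranges pinned to the
#' packaged fixture values reproduce [benin_baseline()].
#'
#' @param ranges Ranges list (see [baseline_ranges()]).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget.
#' @return A validated `fp_baseline`.
#' @export
random_baseline <- function(ranges = baseline_ranges(), seed = 1,
                            max_tries = 100) {
  set.seed(seed)
  draw <- function(b) stats::runif(1, b[1], b[2])
  for (try in seq_len(max_tries)) {
    policy <- lapply(ranges$policy, draw)
    dem_r <- ranges$demography
    demography <- lapply(dem_r[setdiff(names(dem_r), "u5mr_over_imr")], draw)
    demography$u5mr <- demography$imr * draw(dem_r$u5mr_over_imr)
    economy <- lapply(ranges$economy, draw)
    pyr_r <- ranges$pyramid
    demography$pyramid <- make_pyramid(draw(pyr_r$total),
                                      draw(pyr_r$share_0_14),
                                      draw(pyr_r$share_65plus),
                                      draw(pyr_r$taper))
    # keep employment feasible for the drawn pyramid
    wa <- sum(demography$pyramid$count[demography$pyramid$age_start >= 15])
    economy$initial_employment_15plus <-
      min(economy$initial_employment_15plus,
          wa * economy$labor_force_participation)
    x <- new_baseline(policy, demography, economy,
                      meta = list(country = sprintf("synthetic-%d", seed),
                                  base_year = 2010, end_year = 2050))
    ok <- tryCatch({ validate_baseline(x); TRUE },
                   fp_validation_error = function(e) FALSE)
    if (ok) return(x)
  }
  abort("infeasible joint bounds: no valid baseline within the rejection budget",
        class = "fp_domain_error")
}

#' Perturb a single baseline field
#'
#' Returns a copy of the baseline with `delta` added to one scalar field
#' (searched across the policy, demography and economy components), for
#' monotonicity and sensitivity properties. The perturbed baseline is
#' revalidated.
#'
#' @param baseline An `fp_baseline`.
#' @param field Field name.
#' @param delta Additive change.
#' @return A validated `fp_baseline`.
#' @export
perturb_baseline <- function(baseline, field, delta) {
  comp <- c("policy", "demography", "economy")[c(
    field %in% POLICY_FIELDS, field %in% DEMOGRAPHY_FIELDS,
    field %in% ECONOMY_FIELDS)]
  if (length(comp) == 0) abort(paste("unknown baseline field:", field))
  baseline[[comp]][[field]] <- baseline[[comp]][[field]] + delta
  validate_baseline(baseline)
  baseline
}
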