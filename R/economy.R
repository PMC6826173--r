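# Compact economic component: capital accumulation, employment tracking the
# working-age population, total-factor-productivity growth linear in the
# policy variables, a Cobb-Douglas output equation, and an HDI-style
# composite. Functional forms and coefficients are a reconstruction (the
# source model's three economic equations are unpublished); only base-year
# normalisations, the dividend ordering and the HDI endpoints are validated.

ECON_ALPHA <- 1 / 3

#' One-year capital accumulation step
#'
#' `K' = K * (1 - depreciation) + investment`.
#'
#' @param K Capital stock (aggregate or per capita).
#' @param investment Investment over the year (same units as `K`).
#' @param depreciation Annual depreciation rate in \[0, 1\].
#' @return The next-year capital stock.
#' @examples
#' step_capital(100, 4, 0.04) # steady state: 100
#' @export
step_capital <- function(K, investment, depreciation) {
  stopifnot(depreciation >= 0, depreciation <= 1)
  if (any(K < 0)) abort("negative capital", class = "fp_domain_error")
  K * (1 - depreciation) + investment
}

#' One-year employment step
#'
#' Employment grows with the working-age (15+) population and is capped at
#' the working-age population times the participation rate.
#'
#' @param employment Current employment (persons).
#' @param working_age_pop Working-age (15+) population next year.
#' @param participation Labour-force participation ratio (in \[0, 1.5\]).
#' @param growth Growth factor of the working-age population over the year
#'   (next / current).
#' @return Next-year employment.
#' @export
step_employment <- function(employment, working_age_pop, participation,
                            growth = 1) {
  if (participation < 0 || participation > 1.5)
    abort("participation outside [0, 1.5]", class = "fp_domain_error")
  min(employment * growth, working_age_pop * participation)
}

#' GDP per capita from a Cobb-Douglas production function
#'
#' `A * K^alpha * L^(1-alpha) / population` with `alpha = 1/3`.
#'
#' @param K Aggregate capital stock.
#' @param L Employment.
#' @param tfp Total-factor-productivity level `A`.
#' @param population Total population.
#' @param alpha Capital share.
#' @return GDP per capita.
#' @export
gdp_per_capita <- function(K, L, tfp, population, alpha = ECON_ALPHA) {
  if (any(population <= 0)) abort("zero population", class = "fp_domain_error")
  stopifnot(all(K >= 0), all(L >= 0), all(tfp >= 0))
  tfp * K^alpha * L^(1 - alpha) / population
}

#' HDI-style composite index
#'
#' Geometric mean of health, education and income sub-indices with
#' UNDP-style goalposts (life expectancy 20-85 years; mean schooling 0-15 and
#' expected schooling 0-18 years, averaged; log income 100-75,000 USD), times
#' a single multiplicative calibration constant. Inputs at or below the
#' goalpost minima clamp their sub-index to 0.
#'
#' @param e0 Life expectancy at birth (years).
#' @param mean_school_years,expected_school_years Schooling (years).
#' @param gni_pc Income per capita (constant USD).
#' @param scale Multiplicative calibration constant.
#' @return The composite index in \[0, 1\] (vectorised).
#' @export
hdi_index <- function(e0, mean_school_years, expected_school_years, gni_pc,
                      scale = 1) {
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  health <- clamp01((e0 - 20) / (85 - 20))
  edu <- clamp01((clamp01(mean_school_years / 15) +
                    clamp01(expected_school_years / 18)) / 2)
  income <- clamp01((log(pmax(gni_pc, 100)) - log(100)) /
                      (log(75000) - log(100)))
  clamp01(scale * (health * edu * income)^(1 / 3))
}

# TFP growth rate: linear in the policy variables, normalised so the base
# scenario reproduces the printed base GDP growth rate at the printed capital
# and employment growth rates.
tfp_growth <- function(policy, economy, alpha = ECON_ALPHA) {
  g_target <- economy$gdp_growth - alpha * economy$capital_stock_growth -
    (1 - alpha) * economy$employment_growth
  gci_mean <- mean(c(policy$gci_public_institutions, policy$gci_labor_flexibility,
                     policy$gci_financial_efficiency, policy$gci_ict_use))
  score <- function(p) {
    gm <- mean(c(p$gci_public_institutions, p$gci_labor_flexibility,
                 p$gci_financial_efficiency, p$gci_ict_use))
    0.4 * gm / 7 + 0.4 * p$mean_school_years_both / 15 +
      0.2 * p$imports_pct_gdp / 100
  }
  theta <- g_target / score(policy)
  function(p) theta * score(p)
}

#' Project the economic component for one scenario
#'
#' Capital: aggregate stock starts at the base capital-per-adult ratio, with
#' investment per capita proportional to the working-age share (relative to
#' its base value) and normalised so the base-year stock growth matches the
#' printed rate. Employment: scales with the 15+ population, capped by
#' participation. TFP: grows at a rate linear in the (constant) education,
#' institutional and trade-openness variables, normalised to the printed base
#' GDP growth. Output: Cobb-Douglas with capital share 1/3, anchored so
#' base-year GDP per capita matches the baseline.
#'
#' @param baseline An `fp_baseline`.
#' @param series A projection series tibble (from [project_population()]).
#' @param e0 Tibble with columns `year`, `e0` (for the HDI health input).
#' @param hdi_scale HDI calibration constant (see [hdi_index()]).
#' @return A tibble: `year`, `capital_pc` (per 15+), `employment`, `tfp`,
#'   `gdp_pc`, `hdi`.
#' @export
project_economy <- function(baseline, series, e0, hdi_scale = 1) {
  p <- baseline$policy
  ec <- baseline$economy
  n <- nrow(series)
  wa <- series$pop_15plus
  pop <- series$pop_total
  ws <- series$pop_15_64 / pop
  K <- numeric(n); L <- numeric(n); A <- numeric(n)
  K[1] <- ec$capital_stock_per_15plus * wa[1]
  L[1] <- min(ec$initial_employment_15plus,
              wa[1] * ec$labor_force_participation)
  g_tfp <- tfp_growth(p, ec)(p)
  # investment level reproducing the printed base-year capital stock growth
  iota <- (ec$capital_stock_growth + ec$depreciation) * K[1] / pop[1]
  A[1] <- ec$gdp_pc * pop[1] / (K[1]^ECON_ALPHA * L[1]^(1 - ECON_ALPHA))
  for (t in seq_len(n - 1)) {
    invest <- iota * pop[t] * ws[t] / ws[1]
    K[t + 1] <- step_capital(K[t], invest, ec$depreciation)
    L[t + 1] <- step_employment(L[t], wa[t + 1], ec$labor_force_participation,
                                growth = wa[t + 1] / wa[t])
    A[t + 1] <- A[t] * (1 + g_tfp)
  }
  gdp_pc <- gdp_per_capita(K, L, A, pop)
  e0v <- e0$e0[match(series$year, e0$year)]
  tibble(
    year = series$year,
    capital_pc = K / wa,
    employment = L,
    tfp = A,
    gdp_pc = gdp_pc,
    hdi = hdi_index(e0v, p$mean_school_years_both,
                    (p$expected_school_years_f + p$expected_school_years_m) / 2,
                    gdp_pc, scale = hdi_scale)
  )
}
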