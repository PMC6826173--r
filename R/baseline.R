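# Country baseline: policy, demographic and economic base-year values plus the
# age-sex pyramid. Fractions are stored as fractions ([0,1]); they are rendered
# as percent only in I/O and printed tables.

POLICY_FIELDS <- c(
  "expected_school_years_f", "expected_school_years_m",
  "mean_school_years_f", "mean_school_years_m", "mean_school_years_both",
  "cpr_modern", "cpr_traditional", "postpartum_insusceptibility",
  "sterility_45_49", "gci_public_institutions", "gci_labor_flexibility",
  "gci_financial_efficiency", "gci_ict_use", "imports_pct_gdp"
)

DEMOGRAPHY_FIELDS <- c(
  "tfr", "pct_married", "pct_births_at_risk", "imr", "u5mr", "mmr",
  "eff_modern", "eff_traditional", "e0_female", "e0_gap_female_minus_male"
)

ECONOMY_FIELDS <- c(
  "gdp_pc", "gdp_growth", "capital_formation_pc", "capital_stock_growth",
  "depreciation", "initial_employment_15plus", "employment_growth",
  "labor_force_participation", "primary_edu_cost_pct_gdp_pc",
  "capital_stock_per_15plus"
)

AGE_STARTS <- seq(0, 80, by = 5)

age_group_labels <- function() {
  c(paste(AGE_STARTS[-length(AGE_STARTS)],
          AGE_STARTS[-length(AGE_STARTS)] + 4, sep = "-"), "80+")
}

#' Build an age-sex pyramid
#'
#' Constructs a population pyramid on 5-year age groups (0-4 ... 80+, last
#' group open-ended) from a total population, broad age-band shares and a
#' within-band geometric taper. Within each broad band (0-14, 15-64, 65+)
#' counts decline geometrically with age at rate `taper` per year; band totals
#' match the requested shares exactly. The sex ratio is 1.05 males per female
#' at ages 0-4, declining linearly to 0.80 at 80+.
#'
#' @param total Total population (persons).
#' @param share_0_14,share_65plus Fractions of the total population in ages
#'   0-14 and 65+ (the remainder is 15-64).
#' @param taper Within-band geometric decline rate per year of age.
#' @return A tibble with columns `age_group`, `age_start`, `sex`
#'   ("female"/"male") and `count`.
#' @examples
#' pyr <- make_pyramid(1e6, 0.45, 0.03, taper = 0.03)
#' sum(pyr$count)
#' @export
make_pyramid <- function(total, share_0_14 = 0.467, share_65plus = 0.027,
                         taper = 0.035) {
  stopifnot(total > 0, share_0_14 > 0, share_65plus >= 0,
            share_0_14 + share_65plus < 1, taper >= 0)
  band <- cut(AGE_STARTS, c(-1, 14, 64, Inf), labels = c("young", "work", "old"))
  w <- exp(-taper * AGE_STARTS)
  shares <- c(young = share_0_14, work = 1 - share_0_14 - share_65plus,
              old = share_65plus)
  counts <- numeric(length(AGE_STARTS))
  for (b in levels(band)) {
    idx <- band == b
    counts[idx] <- total * shares[[b]] * w[idx] / sum(w[idx])
  }
  male_ratio <- 1.05 - (1.05 - 0.80) * AGE_STARTS / 80
  female <- counts / (1 + male_ratio)
  tibble(
    age_group = rep(age_group_labels(), 2),
    age_start = rep(AGE_STARTS, 2),
    sex = rep(c("female", "male"), each = length(AGE_STARTS)),
    count = c(female, counts - female)
  )
}

new_baseline <- function(policy, demography, economy,
                         meta = list(country = "custom", base_year = 2010,
                                     end_year = 2050)) {
  structure(
    list(policy = policy, demography = demography, economy = economy,
         meta = meta),
    class = "fp_baseline"
  )
}

#' @export
print.fp_baseline <- function(x, ...) {
  cat("<fp_baseline> ", x$meta$country,
      sprintf(" (base year %d, end year %d)\n", x$meta$base_year, x$meta$end_year))
  cat("  TFR", x$demography$tfr,
      "| mCPR", sprintf("%.1f%%", 100 * x$policy$cpr_modern),
      "| IMR", x$demography$imr, "| U5MR", x$demography$u5mr,
      "| MMR", x$demography$mmr, "\n")
  cat("  population", format(round(sum(x$demography$pyramid$count)), big.mark = ","),
      "| GDP pc", x$economy$gdp_pc, "USD\n")
  invisible(x)
}

#' Tidy a country baseline into a long tibble
#'
#' @param x An `fp_baseline` object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `field`, `value` (pyramid
#'   excluded; see the `pyramid` element for counts).
#' @export
tidy.fp_baseline <- function(x, ...) {
  scalar <- function(comp, fields) {
    tibble(component = comp, field = fields,
           value = vapply(fields, function(f) x[[comp]][[f]], numeric(1)))
  }
  bind_rows(scalar("policy", POLICY_FIELDS),
            scalar("demography", DEMOGRAPHY_FIELDS),
            scalar("economy", ECONOMY_FIELDS))
}

validation_error <- function(invariant, ...) {
  abort(sprintf(invariant, ...), class = "fp_validation_error")
}

#' Validate a country baseline
#'
#' Checks every type invariant (fraction ranges, `cpr_modern +
#' cpr_traditional <= 1`, `imr <= u5mr`, GCI scores in \[1, 7\], non-negative
#' economic quantities, a non-empty pyramid, and the Bongaarts domain
#' condition `u_m e_m + u_t e_t < 1/1.08`). Errors name the violated
#' invariant.
#'
#' @param x An `fp_baseline` object.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `fp_validation_error`.
#' @export
validate_baseline <- function(x) {
  stopifnot(inherits(x, "fp_baseline"))
  p <- x$policy; d <- x$demography; e <- x$economy
  miss <- function(fields, comp) {
    m <- setdiff(fields, names(x[[comp]]))
    if (length(m) > 0)
      validation_error("missing %s field(s): %s", comp, paste(m, collapse = ", "))
  }
  miss(POLICY_FIELDS, "policy")
  miss(c(DEMOGRAPHY_FIELDS, "pyramid"), "demography")
  miss(ECONOMY_FIELDS, "economy")

  chk <- function(ok, invariant) if (!isTRUE(ok)) validation_error(invariant)
  frac <- function(v) is.numeric(v) && v >= 0 && v <= 1

  chk(frac(p$cpr_modern) && frac(p$cpr_traditional),
      "cpr_modern and cpr_traditional must be fractions in [0, 1]")
  chk(p$cpr_modern + p$cpr_traditional <= 1,
      "cpr_modern + cpr_traditional must be <= 1")
  chk(p$postpartum_insusceptibility >= 0,
      "postpartum_insusceptibility (months) must be >= 0")
  chk(frac(p$sterility_45_49), "sterility_45_49 must be a fraction in [0, 1]")
  for (g in c("gci_public_institutions", "gci_labor_flexibility",
              "gci_financial_efficiency", "gci_ict_use"))
    chk(p[[g]] >= 1 && p[[g]] <= 7, paste(g, "must be a GCI score in [1, 7]"))
  chk(p$imports_pct_gdp >= 0, "imports_pct_gdp must be >= 0")
  chk(all(vapply(c("expected_school_years_f", "expected_school_years_m",
                   "mean_school_years_f", "mean_school_years_m",
                   "mean_school_years_both"),
                 function(f) p[[f]] >= 0, logical(1))),
      "school years must be >= 0")

  chk(d$tfr > 0, "tfr must be > 0")
  chk(frac(d$pct_married), "pct_married must be a fraction in [0, 1]")
  chk(frac(d$pct_births_at_risk), "pct_births_at_risk must be a fraction in [0, 1]")
  chk(d$imr >= 0 && d$u5mr >= 0 && d$mmr >= 0, "mortality rates must be >= 0")
  chk(d$imr <= d$u5mr, "imr <= u5mr")
  chk(frac(d$eff_modern) && frac(d$eff_traditional),
      "contraceptive effectiveness must be in [0, 1]")
  chk(d$e0_female > 0, "e0_female must be > 0")
  chk(p$cpr_modern * d$eff_modern + p$cpr_traditional * d$eff_traditional <
        1 / 1.08,
      "u_m*e_m + u_t*e_t must be < 1/1.08 (Bongaarts index domain)")

  chk(all(vapply(ECONOMY_FIELDS, function(f) e[[f]] >= 0, logical(1))),
      "economic baseline values must be non-negative")
  chk(e$depreciation <= 1, "depreciation must be in [0, 1]")

  pyr <- d$pyramid
  chk(is.data.frame(pyr) && nrow(pyr) > 0, "pyramid must be non-empty")
  chk(all(pyr$count >= 0), "pyramid counts must be >= 0")
  chk(sum(pyr$count) > 0, "pyramid must be non-empty")
  chk(setequal(unique(pyr$age_start), AGE_STARTS),
      "pyramid age groups must be contiguous 5-year groups 0-4 ... 80+")
  invisible(x)
}

#' Packaged Benin baseline (base year 2010)
#'
#' The base-year country baseline used throughout the package: education,
#' family-planning and economic policy variables; health and demography values
#' (TFR 4.9, IMR 46, U5MR 75, MMR 340, contraceptive effectiveness 0.95
#' modern / 0.5 traditional, female life expectancy 59.6 years); and economic
#' aggregates (GDP per capita 605 constant-2010 USD, capital stock per adult
#' 11,190 USD, initial employment 4,133,182). The 2010 pyramid is the 2013
#' census total (10,008,749) back-scaled by the 3.5 percent/yr intercensal
#' growth rate and shaped so that ages 0-14 hold 46.7 percent and 65+ hold
#' 2.7 percent of the total with a within-band geometric taper; the taper is
#' later refined by the births calibration in [calibrate_projection()].
#'
#' @param taper Within-band geometric taper of the default pyramid
#'   (per year of age).
#' @return An `fp_baseline` object (components `policy`, `demography`,
#'   `economy`, `meta`).
#' @examples
#' bl <- benin_baseline()
#' bl$policy$cpr_modern
#' @export
benin_baseline <- function(taper = 0.035) {
  total_2013 <- 10008749
  total_2010 <- total_2013 / (1 + 0.035)^3
  policy <- list(
    expected_school_years_f = 9.42,
    expected_school_years_m = 12.68,
    mean_school_years_f = 2.06,
    mean_school_years_m = 4.55,
    mean_school_years_both = 3.31,
    cpr_modern = 0.079,
    cpr_traditional = 0.050,
    postpartum_insusceptibility = 12.3,
    sterility_45_49 = 0.041,
    gci_public_institutions = 2.95,
    gci_labor_flexibility = 3.39,
    gci_financial_efficiency = 2.96,
    gci_ict_use = 3.20,
    imports_pct_gdp = 38.10
  )
  demography <- list(
    tfr = 4.9,
    pct_married = 0.704,
    pct_births_at_risk = 0.523,
    imr = 46,
    u5mr = 75,
    mmr = 340,
    eff_modern = 0.95,
    eff_traditional = 0.5,
    e0_female = 59.6,
    e0_gap_female_minus_male = 2.74,
    pyramid = make_pyramid(total_2010, share_0_14 = 0.467,
                           share_65plus = 0.027, taper = taper)
  )
  economy <- list(
    gdp_pc = 605,
    gdp_growth = 0.037,
    capital_formation_pc = 141,
    capital_stock_growth = 0.005,
    depreciation = 0.04,
    initial_employment_15plus = 4133182,
    employment_growth = 0.034,
    labor_force_participation = 1,
    primary_edu_cost_pct_gdp_pc = 15.02,
    capital_stock_per_15plus = 11190
  )
  x <- new_baseline(policy, demography, economy,
                    meta = list(country = "Benin", base_year = 2010,
                                end_year = 2050))
  validate_baseline(x)
  x
}

# percent-rendered fields in config files (stored internally as fractions)
PERCENT_FIELDS <- c(
  policy = list(c("cpr_modern", "cpr_traditional", "sterility_45_49")),
  demography = list(c("pct_married", "pct_births_at_risk"))
)

to_config_list <- function(x) {
  num <- function(comp, fields) {
    out <- lapply(fields, function(f) {
      v <- x[[comp]][[f]]
      if (f %in% PERCENT_FIELDS[[comp]] %||% character(0)) v <- v * 100
      v
    })
    setNames(out, fields)
  }
  pyr <- x$demography$pyramid
  list(
    country = x$meta$country,
    base_year = x$meta$base_year,
    end_year = x$meta$end_year,
    policy = num("policy", POLICY_FIELDS),
    demography = num("demography", DEMOGRAPHY_FIELDS),
    economy = num("economy", ECONOMY_FIELDS),
    pyramid = list(
      age_start = as.integer(pyr$age_start[pyr$sex == "female"]),
      female = pyr$count[pyr$sex == "female"],
      male = pyr$count[pyr$sex == "male"]
    )
  )
}

#' Save a country baseline to a structured config file
#'
#' Writes a YAML key-value file holding every baseline field (percent-scaled
#' where the printed tables use percent) plus the pyramid counts.
#' `load_baseline(save_baseline(x, path))` returns `x` up to decimal
#' rendering.
#'
#' @param x A valid `fp_baseline`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_baseline <- function(x, path) {
  validate_baseline(x)
  yaml::write_yaml(to_config_list(x), path, precision = 15)
  invisible(path)
}

#' Load a country baseline from a structured config file
#'
#' Reads a YAML baseline written by [save_baseline()] (or by hand), validates
#' every type invariant, and rejects unknown keys.
#'
#' @param path Config file path.
#' @return A validated `fp_baseline`.
#' @export
load_baseline <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  cfg <- yaml::read_yaml(path)
  known_top <- c("country", "base_year", "end_year", "policy", "demography",
                 "economy", "pyramid")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown) > 0)
    validation_error("unknown config key(s): %s", paste(unknown, collapse = ", "))
  read_comp <- function(comp, fields) {
    vals <- cfg[[comp]]
    if (is.null(vals)) validation_error("missing config section: %s", comp)
    unknown <- setdiff(names(vals), fields)
    if (length(unknown) > 0)
      validation_error("unknown %s key(s): %s", comp,
                       paste(unknown, collapse = ", "))
    m <- setdiff(fields, names(vals))
    if (length(m) > 0)
      validation_error("missing %s field(s): %s", comp, paste(m, collapse = ", "))
    out <- lapply(fields, function(f) {
      v <- as.numeric(vals[[f]])
      if (f %in% PERCENT_FIELDS[[comp]] %||% character(0)) v <- v / 100
      v
    })
    setNames(out, fields)
  }
  policy <- read_comp("policy", POLICY_FIELDS)
  demography <- read_comp("demography", DEMOGRAPHY_FIELDS)
  economy <- read_comp("economy", ECONOMY_FIELDS)
  pw <- cfg$pyramid
  if (is.null(pw)) validation_error("missing config section: pyramid")
  demography$pyramid <- tibble(
    age_group = rep(age_group_labels(), 2),
    age_start = rep(as.numeric(pw$age_start), 2),
    sex = rep(c("female", "male"), each = length(pw$age_start)),
    count = c(as.numeric(pw$female), as.numeric(pw$male))
  )
  x <- new_baseline(policy, demography, economy,
                    meta = list(country = cfg$country %||% "custom",
                                base_year = cfg$base_year %||% 2010,
                                end_year = cfg$end_year %||% 2050))
  validate_baseline(x)
  x
}
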