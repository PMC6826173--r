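# Fertility response to contraception through the Bongaarts
# proximate-determinants indices. The projected TFR is the baseline TFR
# scaled by the ratio of the index of contraception to its base-year value;
# because postpartum insusceptibility is constant in every scenario the
# postpartum index cancels from the ratio, and sterility is deliberately held
# out of it (see the methods vignette).

#' Bongaarts index of contraception
#'
#' `Cc = 1 - 1.08 * (u_m * e_m + u_t * e_t)`: the multiplicative reduction of
#' fertility due to contraceptive use among married women, with the standard
#' 1.08 coefficient accounting for use concentrated among fecund women.
#'
#' @param u_m,u_t Modern and traditional contraceptive prevalence (fractions
#'   of married women). Vectorised.
#' @param e_m,e_t Method effectiveness fractions.
#' @return The index, in (0, 1]. Errors if the arguments would drive it to or
#'   below zero.
#' @examples
#' index_contraception(0.079, 0.05, 0.95, 0.5) # 0.891946
#' @export
index_contraception <- function(u_m, u_t, e_m, e_t) {
  stopifnot(all(u_m >= 0), all(u_t >= 0),
            all(e_m >= 0 & e_m <= 1), all(e_t >= 0 & e_t <= 1))
  cc <- 1 - 1.08 * (u_m * e_m + u_t * e_t)
  if (any(cc <= 0))
    abort("index of contraception is <= 0: u_m*e_m + u_t*e_t must be < 1/1.08",
          class = "fp_domain_error")
  cc
}

#' Bongaarts index of postpartum infecundability
#'
#' `Ci = 20 / (18.5 + i)` for a mean postpartum insusceptible period of `i`
#' months; equal to 1 at the normalisation point i = 1.5 months.
#'
#' @param ppi_months Mean months of postpartum insusceptibility
#'   (amenorrhea/abstinence). Vectorised.
#' @return The index.
#' @examples
#' index_postpartum(12.3) # 0.6494
#' @export
index_postpartum <- function(ppi_months) {
  stopifnot(all(ppi_months >= 0))
  20 / (18.5 + ppi_months)
}

#' Project the total fertility rate under a scenario
#'
#' `TFR(t) = TFR0 * Cc(t) / Cc(base year)`, with `Cc` evaluated on the
#' scenario's contraceptive-prevalence trajectories and the baseline
#' effectiveness values. Under the base scenario the ratio is identically 1
#' and the TFR stays at its baseline value.
#'
#' @param baseline An `fp_baseline`.
#' @param trajectories Policy trajectories from [policy_trajectories()].
#' @param years Years at which to evaluate (defaults to all trajectory years).
#' @return A tibble with columns `year`, `cpr_modern`, `cpr_traditional`,
#'   `cc`, `tfr`.
#' @examples
#' bl <- benin_baseline()
#' tr <- policy_trajectories(bl, builtin_scenarios()$optimistic)
#' dplyr::filter(project_tfr(bl, tr), year == 2030)$tfr # 3.476 -> 3.48
#' @export
project_tfr <- function(baseline, trajectories,
                        years = sort(unique(trajectories$year))) {
  d <- baseline$demography
  u_m <- trajectory_value(trajectories, "cpr_modern", years)
  u_t <- trajectory_value(trajectories, "cpr_traditional", years)
  cc <- index_contraception(u_m, u_t, d$eff_modern, d$eff_traditional)
  cc0 <- index_contraception(baseline$policy$cpr_modern,
                             baseline$policy$cpr_traditional,
                             d$eff_modern, d$eff_traditional)
  tibble(year = years, cpr_modern = u_m, cpr_traditional = u_t,
         cc = cc, tfr = d$tfr * cc / cc0)
}
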