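# Abridged life tables via a Brass-logit relational model on a packaged
# standard. The standard is synthetic: it is generated once from a Siler
# (infant + background + senescent) hazard chosen for West-African
# plausibility, not copied from any published family. The Brass alpha
# parameter shifts the standard in logit space to match a requested life
# expectancy after infant and under-five mortality are overridden so that
# 1q0 = IMR/1000 and 5q0 = U5MR/1000.

LT_AGES <- c(0, 1, seq(5, 100, 5))

# Siler hazard parameters of the packaged synthetic standard
SILER <- list(a1 = 0.22, b1 = 1.25, a2 = 0.0045, a3 = 0.00006, b3 = 0.105)

standard_lx <- function(ages = LT_AGES) {
  p <- SILER
  H <- p$a1 / p$b1 * (1 - exp(-p$b1 * ages)) + p$a2 * ages +
    p$a3 / p$b3 * (exp(p$b3 * ages) - 1)
  exp(-H)
}

brass_logit <- function(l) 0.5 * log((1 - l) / l)

# person-years and life expectancy from an abridged lx column on LT_AGES
abridged_columns <- function(lx) {
  n <- diff(LT_AGES)
  k <- length(LT_AGES)
  Lx <- numeric(k - 1)
  # separation factors: a0 = 0.3, 4a1 = 1.3 (high-mortality convention)
  Lx[1] <- lx[2] + 0.3 * (lx[1] - lx[2])
  Lx[2] <- 4 * lx[3] + 1.3 * (lx[2] - lx[3])
  for (i in 3:(k - 1)) Lx[i] <- n[i] / 2 * (lx[i] + lx[i + 1])
  T_last <- lx[k] * 2.5  # open 100+ interval
  Tx <- rev(cumsum(rev(c(Lx, T_last))))
  list(Lx = Lx, Tx = Tx, e0 = Tx[1] / lx[1])
}

relational_lx <- function(alpha, q0, q5) {
  ls <- standard_lx()
  la <- 1 / (1 + exp(2 * (alpha + brass_logit(ls[-1]))))
  lx <- numeric(length(LT_AGES))
  lx[1] <- 1
  lx[2] <- 1 - q0
  lx[3] <- 1 - q5
  # ages 10+ follow the alpha-shifted standard, spliced at age 5
  l5_alpha <- la[2]
  lx[4:length(lx)] <- lx[3] * la[3:length(la)] / l5_alpha
  lx
}

#' Construct an abridged life table matched to e0, IMR and U5MR
#'
#' Builds a Brass-logit relational life table on the packaged synthetic
#' standard: infant and child mortality are set directly from the baseline
#' rates (`1q0 = imr/1000`, `5q0 = u5mr/1000`) and the Brass alpha parameter
#' is solved so that the resulting abridged table reproduces the requested
#' life expectancy at birth. The male target is
#' `e0_female - e0_gap`.
#'
#' @param e0_female Female life expectancy at birth (years).
#' @param e0_gap Female-minus-male life-expectancy difference (years).
#' @param imr Infant mortality rate (deaths per 1,000 live births).
#' @param u5mr Under-five mortality rate (deaths per 1,000 live births).
#' @param sex `"female"` or `"male"`.
#' @return An `fp_life_table`: a tibble with columns `age`, `width`, `lx`,
#'   `Lx`, and attributes `e0` (recomputed from the table), `alpha`, `sex`.
#' @examples
#' lt <- make_life_table(59.6, 2.74, 46, 75, "female")
#' attr(lt, "e0")
#' 1 - lt$lx[lt$age == 5] # 5q0 = 0.075
#' @export
make_life_table <- function(e0_female, e0_gap, imr, u5mr,
                            sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(e0_female > 0, imr >= 0, u5mr >= imr, u5mr < 1000)
  target <- if (sex == "female") e0_female else e0_female - e0_gap
  q0 <- imr / 1000
  q5 <- u5mr / 1000
  f <- function(alpha) abridged_columns(relational_lx(alpha, q0, q5))$e0 - target
  root <- tryCatch(uniroot(f, c(-1.5, 1.5), tol = 1e-10),
                   error = function(e) NULL)
  if (is.null(root))
    abort(sprintf("life-table calibration error: e0 = %.1f unattainable on the packaged standard",
                  target),
          class = "fp_calibration_error")
  alpha <- root$root
  lx <- relational_lx(alpha, q0, q5)
  cols <- abridged_columns(lx)
  out <- tibble(
    age = LT_AGES,
    width = c(diff(LT_AGES), NA),
    lx = lx,
    Lx = c(cols$Lx, NA)
  )
  structure(out, e0 = cols$e0, alpha = alpha, sex = sex,
            class = c("fp_life_table", class(out)))
}

#' Survival schedule for the annual cohort-component step
#'
#' Extracts, from a life table, the per-age-group annual survival
#' probabilities used by [project_population()] (fifth roots of the 5-year
#' person-years ratios) plus the survival of newborns to the end of their
#' birth year. A schedule can also be built directly, e.g. for degenerate
#' no-mortality tests.
#'
#' @param x An `fp_life_table`, or `NULL` when `annual`/`newborn` are given
#'   directly.
#' @param annual Numeric vector of 17 annual survival probabilities
#'   (age groups 0-4 ... 80+).
#' @param newborn Survival of a birth cohort to the end of its birth year.
#' @return An `fp_survival` object (list with `annual`, `newborn`).
#' @export
survival_schedule <- function(x = NULL, annual = NULL, newborn = NULL) {
  if (is.null(x)) {
    stopifnot(length(annual) == length(AGE_STARTS),
              all(annual >= 0 & annual <= 1),
              newborn >= 0, newborn <= 1)
    return(structure(list(annual = annual, newborn = newborn),
                     class = "fp_survival"))
  }
  stopifnot(inherits(x, "fp_life_table"))
  lx <- x$lx
  Lx <- x$Lx[!is.na(x$Lx)]
  # collapse to 5-year groups 0-4, 5-9, ..., 95-99
  L5 <- c(Lx[1] + Lx[2], Lx[3:length(Lx)])
  T_last <- lx[length(lx)] * 2.5
  Tg <- rev(cumsum(rev(c(L5, T_last))))  # T at 0, 5, ..., 100
  n_groups <- length(AGE_STARTS)
  annual <- numeric(n_groups)
  for (i in seq_len(n_groups - 1)) annual[i] <- (L5[i + 1] / L5[i])^(1 / 5)
  i80 <- which(seq(0, 95, 5) == 80)
  annual[n_groups] <- (Tg[i80 + 1] / Tg[i80])^(1 / 5)
  newborn <- lx[2] + 0.3 * (lx[1] - lx[2])  # L(0,1)/l0
  structure(list(annual = pmin(annual, 1), newborn = min(newborn, 1)),
            class = "fp_survival")
}
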