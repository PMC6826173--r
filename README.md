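# fpdividend

Two-part demographic–economic projection of family-planning (FP) policy
scenarios for high-fertility settings, with a packaged Benin baseline
(base year 2010, horizon 2050, reporting window 2015–2030).

## Who this is for

Health-policy analysts and demographers who want to quantify what stronger
contraceptive uptake buys in maternal and child lives saved — and in age
structure, life expectancy, GDP per capita and human development — relative
to a no-change reference, from nothing more than a printed country baseline.

## The model

The chain is: scenario targets → policy trajectories → fertility →
population → deaths and deaths averted → economy.

* **Scenarios.** A scenario maps policy variables to end-year (2050)
  targets; trajectories are linear in calendar year. Built-ins: `base`
  (no change) and three FP hypotheses taking modern contraceptive
  prevalence among married women (mCPR) from 7.9 % to 17.9 % (`low`),
  38.95 % (`moderate`) or 60 % (`optimistic`) by 2050, with traditional
  prevalence 5 % → 2 % and sterility 4.1 % → 3.0 %.
* **Fertility.** The Bongaarts index of contraception
  `Cc = 1 − 1.08 (u_m e_m + u_t e_t)` (effectiveness 0.95 modern, 0.5
  traditional) drives the total fertility rate as a ratio:
  `TFR(t) = TFR0 · Cc(t)/Cc(2010)`, TFR0 = 4.9.
* **Population.** Annual cohort-component projection on 5-year age groups,
  Brass-logit relational life tables matched to e0 = 59.6 (female),
  IMR = 46 and U5MR = 75, closed to migration. The births level and the
  base-pyramid shape are calibrated to the base-path cumulative-births
  identity implied by the infant tables.
* **Health outcomes.** Scenario rate endpoints at 2030 (MMR 340 → 300 /
  265.6 / 207.5; U5MR −10 % low, −42.6 points optimistic) move with
  contraceptive progress; annual deaths are births × rate, cumulated over
  2016–2030, and `averted = base − scenario` to the person.
* **Economy.** Capital accumulation (δ = 4 %), employment tracking the
  adult population, TFP growth normalised to the base 3.7 %/yr GDP growth,
  Cobb–Douglas output anchored at 605 USD per capita, and an HDI-style
  composite calibrated to 0.37 at 2015.

See the methods vignette (`vignettes/fpdividend-methods.Rmd`) for the
assumptions, calibration details and limitations.

## Worked example

```r
library(fpdividend)

fit <- project_dividend(benin_baseline())   # calibrates, runs all 4 scenarios
render_summary(fit)
```

```
Family-planning scenario projection: Benin, window 2015-2030
Scenarios: base, low, moderate, optimistic
  TFR 2030 [base]: 4.90
  TFR 2030 [low]: 4.66
  TFR 2030 [moderate]: 4.07
  TFR 2030 [optimistic]: 3.48
  maternal deaths averted by 2030 [low]: 2,364 (~2,000)
  maternal deaths averted by 2030 [moderate]: 5,430 (~5,000)
  maternal deaths averted by 2030 [optimistic]: 8,946 (~9,000)
  under5 deaths averted by 2030 [low]: 43,569 (~44,000)
  under5 deaths averted by 2030 [moderate]: 138,809 (~139,000)
  under5 deaths averted by 2030 [optimistic]: 221,049 (~221,000)
  infant deaths averted by 2030 [low]: 31,985 (~32,000)
  infant deaths averted by 2030 [moderate]: 73,470 (~73,000)
  infant deaths averted by 2030 [optimistic]: 121,031 (~121,000)
  MMR 2030 [optimistic]: 207.5 (risk of maternal death reduced by 39%)
```

Reading this: under the no-change reference, 4.9 children per woman and an
MMR of 340 persist, and 24,161 maternal deaths accumulate over 2016–2030
(`tidy(fit)` has the full milestone tables). Reaching 33.95 % mCPR by 2030
(the `optimistic` path) cuts the TFR to 3.48, the maternal risk by 39 %,
and averts roughly 9,000 maternal, 221,000 under-five and 121,000 infant
deaths. `glance(fit)` returns the calibration constants and headline
quantities in one row; `autoplot(fit, "averted")` plots the averted series.

Everything is tabular: `fit$series` (per year × scenario: population, TFR,
dependency ratio, e0, GDP pc, HDI, …), `fit$rates`, `fit$outcomes`,
`fit$pyramids` are tibbles that pipe straight into dplyr/ggplot2.

A command-line runner wraps the same pipeline:

```sh
Rscript inst/cli/fpdividend.R --out out/ --seed 1 --summary
```

writing the three milestone outcome tables, rates, trajectories, economy
series and pyramid snapshots as CSV plus a `manifest.json` with checksums
and the calibration constants.

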