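---
title: "Methods: family-planning scenario projection of demographic and economic dividends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-planning scenario projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpdividend)
```

## The model in one page

`fpdividend` implements a two-part demographic–economic projection for
family-planning (FP) policy scenarios in a high-fertility setting, packaged
with a Benin baseline (base year 2010, horizon 2050, reporting window
2015–2030). The chain is:

1. **Scenario engine** — each scenario is a map from policy variables to
   end-year (2050) targets; trajectories are linear in calendar year.
2. **Fertility** — the total fertility rate responds to contraceptive
   prevalence through the Bongaarts index of contraception,
   $C_c = 1 - 1.08\,(u_m e_m + u_t e_t)$, as a ratio applied to the baseline
   TFR: $\mathrm{TFR}(t) = \mathrm{TFR}_0 \cdot C_c(t)/C_c(t_0)$.
3. **Demography** — an annual cohort-component projection on 5-year age
   groups with Brass-logit relational life tables, closed to migration.
4. **Health outcomes** — annual maternal, infant and under-five deaths as
   births × rate (period accounting on the year of birth), cumulated over
   the window; deaths averted are base-minus-scenario by construction.
5. **Economy** — a compact reconstruction: capital accumulation, employment
   tracking the adult population, TFP growth linear in the policy variables,
   Cobb–Douglas output, and an HDI-style composite.

All user-facing functions take and return tibbles;
`project_dividend()` runs the whole chain and returns an object with
`tidy()`, `glance()` and `autoplot()` methods; `run_projection()` writes the
CSV outputs and a manifest.

## Scenarios and trajectories

Four scenarios are built in. The `base` scenario freezes every policy
variable at its 2010 value. The three FP scenarios move modern contraceptive
prevalence among married women (mCPR, 7.9 % in 2010) to an end-2050 level of
17.9 % (`low`, continuing the historical pace), 60 % (`optimistic`, the
FP2020-commitment pace), or their midpoint 38.95 % (`moderate`). All three
move traditional prevalence from 5 % to 2 % and sterility among women 45–49
from 4.1 % to 3.0 %, and leave postpartum insusceptibility (12.3 months) and
every education/economic variable untouched.

Interpolation is linear in calendar year. This is the only rule consistent
with the mid-projection (2030) values the scenarios are defined to reach:
the 2030 mCPR read-outs are exactly the 2010↔2050 midpoints
(12.90 / 23.425 / 33.95 %), as are the traditional-CPR (3.50 %) and
sterility (3.55 %) read-outs. Two remarks on deliberately resolved
ambiguities:

* The moderate end level is defined by its *rule* ("midpoint of low and
  optimistic" = 38.95 %) rather than a truncated 38.9: only the midpoint
  rule reproduces the 2030 read-out of 23.43 (2 dp) that the scenario set is
  anchored on.
* The sterility end level is taken as 3.0 % at 2050, which makes the 2030
  value its midpoint 3.55 %; sterility is carried as a policy variable but
  deliberately does **not** enter the TFR ratio (below).

## Fertility response

Only the index of contraception enters the projection. The postpartum index
$C_i = 20/(18.5+i)$ is implemented (and exported) but cancels from the TFR
ratio because insusceptibility is constant in every scenario. Sterility is
excluded from the ratio as a design choice: the contraception-index ratio
alone reproduces the scenario fertility decline the model is anchored on
(optimistic 2030 TFR 3.48 at 2 dp; adding a sterility factor would shift it
to 3.50). The 1.08 coefficient is the standard published value. The ratio
form needs no total-fecundity constant and is exact for the base scenario
(TFR identically 4.9).

## Population projection

**Time step.** Annual steps on 5-year age groups (0–4 … 80+): each year every
group is survived and one fifth of it ages up. Annual resolution is needed
because the outcome tables cumulate annual deaths to 2020/2025/2030
milestones.

**Life tables.** Abridged tables are built by a Brass-logit relational model
on a packaged standard. The standard is *synthetic*: it is generated from a
Siler hazard (infant, background and senescent components) chosen once for
West-African plausibility — no model-life-table family is shipped. Infant
and child mortality are overridden directly from the baseline rates
($_1q_0 = \mathrm{IMR}/1000$, $_5q_0 = \mathrm{U5MR}/1000$) and the Brass
$\alpha$ is solved by root-finding so the abridged table reproduces the
requested $e_0$ (female 59.6 years; male = female − 2.74). The same child
mortality is used for both sexes (no sex split is given). Separation factors
are $a_0 = 0.3$ and $_4a_1 = 1.3$ (high-mortality convention). Life tables
are held at base-year mortality across years and scenarios; scenario
mortality change enters through the outcome rates (below), which is the
accounting the milestone tables follow. This is a limitation: the population
side slightly understates scenario differences in survivors.

**Fertility schedule.** A fixed age shape peaking at 20–29 (typical of
West-African schedules), rescaled every year so age-specific rates sum to
$\mathrm{TFR}(t)/5$. Births are split 1.05 male per female.

**Base pyramid and calibration.** The 2010 pyramid starts from the 2013
census total (10,008,749) back-scaled by the 3.5 %/yr intercensal growth
rate, with 46.7 % of the population at ages 0–14 and 2.7 % at 65+ and a
geometric within-band taper. Two constants absorb the detail the baseline
does not pin down:

* the **births level** (a scalar on the fertility schedule), and
* the **pyramid shape** (the taper rate),

fitted jointly so the base-scenario cumulative births over 2016–2020 and
2016–2030 equal the values implied by the base-path cumulative *infant*
deaths at the constant base IMR (94,088/0.046 and 326,883/0.046). Only the
infant cells are used, so the maternal cells and the under-five 2025 cell
remain genuine out-of-sample checks of the calibrated births path (the test
suite verifies them at ±0.1 % and ±0.5 % respectively). Calibration is
deterministic root-finding (`uniroot`, inner scale tolerance 10⁻⁹ persons,
outer taper tolerance 10⁻⁷), about 300 projection evaluations of 21 years
each — a few seconds on one core.

**Life expectancy overlay.** Reported female $e_0$ bridges linearly from
59.6 (2010) to 61.5 (2015) — a secular drift confined to the pre-window
years — and from 2015 moves only with under-five mortality:
$e_0(t) = 61.5 + \lambda\,(\mathrm{U5MR}(2015) - \mathrm{U5MR}(t))$ with
$\lambda = 5.3/42.6 \approx 0.124$ years per point, the optimistic-scenario
gain per unit of under-five decline. Continuing the drift after 2015 would
push the base path above the optimistic one, contradicting the anchoring,
so it is stopped at the window start.

## Health outcomes

**Rate trajectories.** Each scenario has 2030 endpoints: MMR falls from 340
to 300 / 265.6 / 207.5 (low / moderate / optimistic); U5MR falls by 10 %
(low) and by 42.6 points (optimistic), with other scenarios interpolated
linearly in their 2030 mCPR between those anchors (this reconstructs the
moderate endpoint, ≈ 49.95). Between 2015 and 2030 rates move with
contraceptive progress,
$\mathrm{rate}(t) = r_0 - (r_0 - r_{2030})\,
\frac{\mathrm{cpr}(t)-\mathrm{cpr}(2015)}{\mathrm{cpr}(2030)-\mathrm{cpr}(2015)}$,
held at $r_0$ before 2015 and at the endpoint after 2030. Endpoints are
applied as *relative* reductions, so a non-Benin baseline gets the same
proportional response.

**Infant endpoints.** No infant-specific endpoints are part of the scenario
definitions. Two reconstructions were considered: IMR proportional to U5MR,
and IMR falling by the same relative amount as MMR. The package uses the
second (capped at the U5MR endpoint so IMR ≤ U5MR always holds): as child
mortality falls, the infant share of under-five deaths rises, so a
proportional-to-U5MR rule overstates the infant decline; the
equal-relative-risk rule is the reconstruction consistent with the infant
milestone tables the engine is validated against.

**Accounting.** Deaths are attributed to the year of birth:
maternal $= B(t)\,\mathrm{MMR}(t)/10^5$, infant
$= B(t)\,\mathrm{IMR}(t)/10^3$, under-five
$= B(t)\,\kappa\,\mathrm{U5MR}(t)/10^3$. The window factor
$\kappa \in (0,1]$ captures the part of a cohort's lifetime under-five risk
the reporting convention counts inside the window; it is calibrated once on
the base-scenario 2030 under-five cell ($\kappa \approx 0.9265$) and
validated on the 2020 and 2025 cells. A cohort-spread alternative (spreading
each cohort's under-five deaths over its first five years) was rejected: it
implies a truncation factor near 0.81, inconsistent with the near-constant
≈ 0.926 the milestone tables exhibit. Cumulative sums start after 2015, so
the 2015 row of every table is empty by convention, and
`averted = base − scenario` holds to the person in emitted tables.

Known reconstruction limit: the milestone tables the engine is anchored on
are not mutually consistent — no common births weighting of the anchored
endpoints reproduces the maternal and under-five tables simultaneously (the
maternal table behaves as if rates decline from 2010, the child tables from
2015). The window-anchored rule above is kept; scenario cells reproduce to
within about ±8 % except the early optimistic maternal milestones
(± ~12 %).

## Economy

The three economic relations are a reconstruction; only base-year
normalisations, the dividend ordering and the HDI endpoints are validated.

* **Capital**: $K_{t+1} = K_t(1-\delta) + I_t$ with $\delta = 4\,\%$.
  Aggregate capital starts at 11,190 USD per adult (15+). Investment per
  capita rises proportionally with the working-age share relative to its
  base value, with its level normalised so the base-year stock growth equals
  the printed 0.5 %/yr. (The baseline's capital-formation-per-capita value
  of 141 is carried in the data model but is mutually inconsistent with the
  depreciation and stock-growth inputs, so it is not the binding constant.)
* **Employment**: scales with the 15+ population from 4,133,182, capped at
  participation × adult population.
* **TFP**: grows at a rate linear in the (scenario-constant) GCI scores,
  mean schooling and import share, normalised so that, at the printed
  base-year capital and employment growth rates, GDP grows at the printed
  3.7 %/yr; with $\alpha = 1/3$ this gives ≈ 1.27 %/yr.
* **Output**: $Y = A K^{1/3} L^{2/3}$, anchored so base-year GDP per capita
  is 605 constant-2010 USD.
* **HDI**: geometric mean of health ($e_0$, goalposts 20–85), education
  (mean years/15 and expected years/18, averaged) and income
  ($\log$ GDP pc, 100–75,000) sub-indices, times one multiplicative
  constant calibrated so the base-2015 value is 0.37 (raw goalposts give
  ≈ 0.42 at those inputs; the constant reconciles the level without
  distorting trends).

The dividend direction — lower dependency at fixed policy variables, weakly
higher GDP per capita — emerges from the population denominator and the
investment response, and is property-tested.

## Synthetic baselines

`random_baseline()` draws complete, valid country baselines uniformly inside
West-African plausibility ranges (TFR 3–8, IMR 20–100 with U5MR 1–2× IMR,
MMR 100–1,000, mCPR 2–35 %, …; see `baseline_ranges()`), enforcing joint
constraints (IMR ≤ U5MR, CPR sum, the Bongaarts domain condition,
employment below the adult population) by construction or rejection. It
emulates the *shape* of a country baseline, not survey sampling: fields are
independent draws, so realistic correlations (e.g. high fertility with high
mortality) are absent, and passing property tests demonstrates engine
robustness and invariant preservation, not predictive validity on real
data. `perturb_baseline()` gives single-field sensitivities for
monotonicity properties.

## Numerical choices and degenerate inputs

* Percentages are stored as fractions internally and rendered as percent in
  config files and printed tables, avoiding 100× errors.
* Root-finding everywhere is `stats::uniroot` on bracketing intervals; an
  unattainable life expectancy on the packaged standard raises a
  calibration error rather than extrapolating.
* Zero TFR, zero mortality, empty pyramids, zero working-age population and
  out-of-domain Bongaarts inputs are all either handled exactly or rejected
  with classed errors naming the violated invariant.
* CSV rounding: cumulative deaths to persons (half-up), rates to 1 dp, TFR
  and CPR to 2 dp. Averted columns are recomputed from the rounded
  cumulative columns so the tables stay internally consistent to the person.
* The pipeline is deterministic given (baseline, scenarios, seed); the seed
  only matters for the synthetic generator.

## Problem sizes

Default runs project 41 years × 17 age groups × 2 sexes for four scenarios;
calibration adds ~300 truncated (21-year) projections. The property suite
uses a 1,000-draw synthetic sweep for invariant checks and a 2-seed
end-to-end sweep; these sizes were chosen as the smallest that exercise
every code path and invariant convincingly.

## Known limitations

* Closed population: migration is zero throughout.
* Scenario mortality improvements do not feed back into projection
  survival (see above).
* The economic component is a deliberately compact reconstruction; its
  coefficients are normalisation constants, not estimates, and
  education/economic policy scenarios, while mechanically supported through
  `scenario_spec()`, are not validated.
* Custom scenarios targeting education or economic variables are flagged by
  name only; no anchors exist for their health-outcome response, which is
  driven entirely by the mCPR trajectory.
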