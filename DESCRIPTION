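Package: fpdividend
Title: Family-Planning Scenario Projection of Demographic and Economic Dividends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-part demographic-economic projection engine for family-planning
    policy scenarios in high-fertility settings, with a packaged Benin baseline
    (base year 2010, horizon 2050, reporting window 2015-2030). Policy-variable
    trajectories are interpolated between base-year values and scenario
    end-year targets; fertility responds to contraceptive prevalence through
    the Bongaarts index of contraception; population is advanced by an annual
    cohort-component projection on Brass-logit relational life tables; births
    and mortality-rate trajectories are converted into cumulative maternal,
    infant and under-five deaths and deaths averted versus the base scenario;
    and a compact economic component (capital formation, employment,
    total-factor productivity, HDI-style composite) tracks the dividend
    direction. Includes a synthetic country-baseline generator for
    property-based testing, tidy accessors, ggplot2 plotting, and a
    command-line runner emitting reproducible CSV outputs with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
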