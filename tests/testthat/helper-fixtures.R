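# Shared fixtures. The calibrated study fit is expensive (root-finding over
# repeated projections), so it is computed once per test run and reused.

study_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- project_dividend(benin_baseline())
    fit
  }
})

# Printed milestone tables (cumulative deaths; rows low/moderate/optimistic/
# base, columns 2020/2025/2030), used as external reference values.
printed_tables <- list(
  maternal = rbind(low = c(6600, 13985, 22142),
                   moderate = c(5781, 11729, 17760),
                   optimistic = c(5052, 9809, 14196),
                   base = c(6954, 14992, 24161)),
  under5 = rbind(low = c(135656, 288109, 457363),
                 moderate = c(120595, 245361, 372029),
                 optimistic = c(106315, 205800, 294932),
                 base = c(141883, 306058, 493792)),
  infant = rbind(low = c(90217, 191796, 304654),
                 moderate = c(80882, 165570, 252668),
                 optimistic = c(72065, 141388, 205949),
                 base = c(94088, 202833, 326883))
)

milestone_years <- c(2020, 2025, 2030)

cum_cell <- function(fit, outcome, scenario, year) {
  tab <- fit$outcomes[[outcome]]
  tab$cumulative_deaths[tab$scenario == scenario & tab$year == year]
}

series_cell <- function(fit, scenario, year, col) {
  s <- fit$series
  s[[col]][s$scenario == scenario & s$year == year]
}
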