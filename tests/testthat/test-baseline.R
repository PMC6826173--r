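test_that("packaged Benin baseline matches the printed base-year values", {
  bl <- benin_baseline()
  expect_s3_class(bl, "fp_baseline")
  expect_equal(bl$policy$cpr_modern, 0.079)
  expect_equal(bl$policy$cpr_traditional, 0.050)
  expect_equal(bl$policy$postpartum_insusceptibility, 12.3)
  expect_equal(bl$policy$sterility_45_49, 0.041)
  expect_equal(bl$policy$expected_school_years_f, 9.42)
  expect_equal(bl$policy$mean_school_years_both, 3.31)
  expect_equal(bl$policy$gci_ict_use, 3.20)
  expect_equal(bl$demography$tfr, 4.9)
  expect_equal(bl$demography$imr, 46)
  expect_equal(bl$demography$u5mr, 75)
  expect_equal(bl$demography$mmr, 340)
  expect_equal(bl$demography$eff_modern, 0.95)
  expect_equal(bl$demography$eff_traditional, 0.5)
  expect_equal(bl$demography$e0_female, 59.6)
  expect_equal(bl$demography$e0_gap_female_minus_male, 2.74)
  expect_equal(bl$economy$gdp_pc, 605)
  expect_equal(bl$economy$initial_employment_15plus, 4133182)
  expect_equal(bl$economy$capital_stock_per_15plus, 11190)
  # passes its own invariants
  expect_invisible(validate_baseline(bl))
  # tidy view covers every scalar field
  td <- tidy(bl)
  expect_equal(nrow(td), 14 + 10 + 10)
})

test_that("pyramid construction honours totals, band shares and aging bands", {
  pyr <- make_pyramid(1e6, share_0_14 = 0.467, share_65plus = 0.027,
                      taper = 0.035)
  expect_equal(sum(pyr$count), 1e6)
  expect_equal(sum(pyr$count[pyr$age_start < 15]) / 1e6, 0.467)
  expect_equal(sum(pyr$count[pyr$age_start >= 65]) / 1e6, 0.027)
  expect_setequal(unique(pyr$sex), c("female", "male"))
  expect_true(all(pyr$count >= 0))
  # geometric taper: within the working band, counts decline with age
  f <- pyr$count[pyr$sex == "female" & pyr$age_start >= 15 & pyr$age_start < 65]
  expect_true(all(diff(f) < 0))
})

test_that("invariant violations are rejected with the invariant named", {
  bl <- benin_baseline()
  bad <- bl
  bad$demography$imr <- 80
  bad$demography$u5mr <- 75
  expect_error(validate_baseline(bad), "imr <= u5mr",
               class = "fp_validation_error")
  bad <- bl
  bad$policy$cpr_modern <- 0.6
  bad$policy$cpr_traditional <- 0.5
  expect_error(validate_baseline(bad), "cpr_modern \\+ cpr_traditional",
               class = "fp_validation_error")
  bad <- bl
  bad$policy$gci_ict_use <- 9
  expect_error(validate_baseline(bad), "GCI", class = "fp_validation_error")
  bad <- bl
  bad$demography$pyramid <- bl$demography$pyramid[0, ]
  expect_error(validate_baseline(bad), "pyramid",
               class = "fp_validation_error")
})

test_that("config save/load round-trips the baseline", {
  bl <- benin_baseline()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_baseline(bl, path)
  bl2 <- load_baseline(path)
  expect_equal(bl2$policy, bl$policy, tolerance = 1e-12)
  expect_equal(bl2$economy, bl$economy, tolerance = 1e-12)
  scalar_fields <- setdiff(names(bl$demography), "pyramid")
  expect_equal(bl2$demography[scalar_fields], bl$demography[scalar_fields],
               tolerance = 1e-12)
  expect_equal(bl2$demography$pyramid$count, bl$demography$pyramid$count,
               tolerance = 1e-12)
  expect_equal(bl2$meta$country, "Benin")
  # rendering idempotence: saving the loaded baseline reproduces the file
  path2 <- withr::local_tempfile(fileext = ".yaml")
  save_baseline(bl2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("config loading rejects unknown keys and names missing fields", {
  bl <- benin_baseline()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_baseline(bl, path)
  cfg <- yaml::read_yaml(path)
  cfg$policy$not_a_field <- 1
  yaml::write_yaml(cfg, path)
  expect_error(load_baseline(path), "not_a_field",
               class = "fp_validation_error")
  cfg$policy$not_a_field <- NULL
  cfg$demography$mmr <- NULL
  yaml::write_yaml(cfg, path)
  expect_error(load_baseline(path), "mmr", class = "fp_validation_error")
  # invariant violations surface at load time too
  cfg <- yaml::read_yaml(path)
  cfg$demography$mmr <- 340
  cfg$demography$imr <- 80
  cfg$demography$u5mr <- 75
  yaml::write_yaml(cfg, path)
  expect_error(load_baseline(path), "imr <= u5mr",
               class = "fp_validation_error")
})

test_that("packaged benin.yaml fixture equals the code constructor", {
  path <- system.file("extdata", "benin.yaml", package = "fpdividend")
  expect_true(nzchar(path))
  bl <- load_baseline(path)
  ref <- benin_baseline()
  expect_equal(bl$policy, ref$policy, tolerance = 1e-12)
  expect_equal(bl$demography$tfr, ref$demography$tfr)
  expect_equal(sum(bl$demography$pyramid$count),
               sum(ref$demography$pyramid$count), tolerance = 1e-9)
})
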