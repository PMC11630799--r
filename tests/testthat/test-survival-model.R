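test_that("log-linear fit recovers D10 from exact curves", {
  # one exact decade drop
  fit <- fit_loglinear(tibble::tibble(dose_gy = c(0, 2500),
                                      surviving_fraction = c(1, 0.1)))
  expect_equal(fit$d10_gy, 2500)
  expect_true(fit$intercept_fixed)

  # exact log-linear curve through two noiseless decades
  fit2 <- fit_loglinear(tibble::tibble(dose_gy = c(0, 1000, 2000),
                                       surviving_fraction = c(1, 1e-2, 1e-4)))
  expect_equal(fit2$d10_gy, 500)
  expect_equal(fit2$r_squared, 1)

  # noiseless recovery is the identity across the D10 range of interest
  for (d10 in 10^seq(1, 5, by = 0.5)) {
    fit <- fit_loglinear(exact_curve(d10))
    expect_equal(fit$d10_gy, d10, tolerance = 1e-9)
  }
})

test_that("free-intercept fit matches the lm() oracle for unnormalised curves", {
  # curve not passing through (0, 1): intercept must be free
  curve <- tibble::tibble(dose_gy = c(100, 500, 900, 1300),
                          surviving_fraction = c(0.7, 0.08, 0.011, 0.0013))
  fit <- fit_loglinear(curve)
  expect_false(fit$intercept_fixed)
  oracle <- stats::lm(log10(surviving_fraction) ~ dose_gy, data = curve)
  expect_equal(fit$slope, unname(stats::coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(stats::coef(oracle)[1]), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(oracle)$r.squared, tolerance = 1e-12)
  expect_equal(fit$d10_gy, -1 / stats::coef(oracle)[2], ignore_attr = TRUE)
})

test_that("non-inactivating and degenerate curves are rejected", {
  expect_error(
    fit_loglinear(tibble::tibble(dose_gy = c(0, 1000),
                                 surviving_fraction = c(0.5, 0.9))),
    "Non-inactivating", class = "radhab_fit_error")
  expect_error(
    fit_loglinear(tibble::tibble(dose_gy = 100, surviving_fraction = 0.5)),
    "at least 2", class = "radhab_data_error")
  expect_error(
    fit_loglinear(tibble::tibble(dose_gy = c(0, 500),
                                 surviving_fraction = c(1, 1))),
    "surviving fraction < 1", class = "radhab_data_error")
  expect_error(
    fit_loglinear(tibble::tibble(dose_gy = c(500, 100),
                                 surviving_fraction = c(0.5, 0.9))),
    "strictly increasing", class = "radhab_data_error")
})

test_that("dose_to_fraction converts D10 to threshold doses", {
  expect_equal(dose_to_fraction(2500, 1e-6), 15000)
  expect_equal(dose_to_fraction(1400, 1e-6), 8400)
  expect_equal(dose_to_fraction(1234, 1), 0)
  # k decades cost exactly k * D10
  for (k in 1:9) {
    expect_equal(dose_to_fraction(700, 10^-k), k * 700)
  }
  expect_error(dose_to_fraction(2500, 0), "target_fraction",
               class = "radhab_validation_error")
  expect_error(dose_to_fraction(2500, 1.5), "target_fraction",
               class = "radhab_validation_error")
})

test_that("time to inactivation reproduces the reference gamma bounds", {
  low_gamma <- dose_scenario("west_rand_low_gamma", 0.02)
  res <- time_to_inactivation(reference_thresholds(), low_gamma,
                              particle_weights(gamma = 1))
  expect_equal(res$time_to_inactivation_yr, c(50000, 420000, 750000))
  expect_equal(res$effective_rate_gy_eq_yr, rep(0.02, 3))
})

test_that("zero dose rate yields the never-inactivated sentinel", {
  res <- time_to_inactivation(reference_thresholds(),
                              dose_scenario("off", 0))
  expect_true(all(is.infinite(res$time_to_inactivation_yr)))
  expect_true(all(res$time_to_inactivation_yr > 0))
  expect_equal(format_survival_table(res)$time_yr_2sf, rep("never", 3))
})

test_that("mixed-scenario time sits between the pure-particle times", {
  thr <- tibble::tibble(organism = "D. radiodurans", threshold_dose_gy = 15000)
  mixed <- time_to_inactivation(thr, dose_scenario("m", 0.3, alpha = 0.5))
  expect_equal(mixed$time_to_inactivation_yr, 15000 / 3.15, tolerance = 1e-12)
  pure_a <- time_to_inactivation(thr, dose_scenario("a", 0.3, alpha = 1))
  pure_g <- time_to_inactivation(thr, dose_scenario("g", 0.3))
  expect_gt(mixed$time_to_inactivation_yr, pure_a$time_to_inactivation_yr)
  expect_lt(mixed$time_to_inactivation_yr, pure_g$time_to_inactivation_yr)
})

test_that("time to inactivation is inversely proportional to dose rate", {
  thr <- tibble::tibble(organism = "x", threshold_dose_gy = 8400)
  base <- time_to_inactivation(thr, dose_scenario("b", 0.02))
  for (k in c(0.5, 2, 15, 1e3, 1e6)) {
    scaled <- time_to_inactivation(thr, dose_scenario("s", 0.02 * k))
    expect_equal(scaled$time_to_inactivation_yr,
                 base$time_to_inactivation_yr / k, tolerance = 1e-12)
  }
})

test_that("survival table covers the full grid with monotone ordering", {
  st <- survival_table(reference_thresholds(), reference_scenarios())
  expect_equal(nrow(st), 18)
  expect_true(attr(st, "assumes_dormant_cells"))

  # within every scenario, times order with threshold dose:
  # E. coli < B. subtilis < D. radiodurans
  by_scenario <- split(st, st$scenario)
  for (tab in by_scenario) {
    ord <- tab[order(tab$threshold_dose_gy), ]
    expect_equal(ord$organism, c("E. coli", "B. subtilis", "D. radiodurans"))
    expect_true(all(diff(ord$time_to_inactivation_yr) > 0))
  }

  # low-dose times exceed high-dose counterparts by the rate ratio 15
  merged <- merge(
    st[grepl("west_rand_low", st$scenario), ],
    st[grepl("vaal_reef_high", st$scenario), ],
    by = "organism", suffixes = c("_low", "_high"))
  merged <- merged[sub("west_rand_low_", "", merged$scenario_low) ==
                     sub("vaal_reef_high_", "", merged$scenario_high), ]
  expect_equal(merged$time_to_inactivation_yr_low /
                 merged$time_to_inactivation_yr_high,
               rep(15, nrow(merged)), tolerance = 1e-12)

  # degenerate 1x1 table equals the scalar computation
  one <- survival_table(reference_thresholds()[1, ],
                        reference_scenarios()[1, ])
  expect_equal(nrow(one), 1)
  expect_equal(one$time_to_inactivation_yr, 50000)
})

test_that("survival table rejects duplicate organisms and empty inputs", {
  dup <- dplyr::bind_rows(reference_thresholds(), reference_thresholds()[1, ])
  expect_error(survival_table(dup, reference_scenarios()),
               "Duplicate organism", class = "radhab_validation_error")
  expect_error(survival_table(reference_thresholds(),
                              reference_scenarios()[0, ]),
               "at least one", class = "radhab_validation_error")
})

test_that("formatted times round to two significant figures", {
  st <- survival_table(reference_thresholds(),
                       dose_scenario("high_mixed", 0.3, alpha = 0.5))
  fmt <- format_survival_table(st)
  expect_equal(fmt$time_yr_2sf, c("320", "2 700", "4 800"))
  # raw values stay at full precision
  expect_equal(st$time_to_inactivation_yr[1], 1000 / 3.15, tolerance = 1e-12)
})

test_that("survival curves read from TSV and fit per organism", {
  path <- withr::local_tempfile(fileext = ".tsv")
  curve <- exact_curve(1400, n_points = 4)
  readr::write_tsv(
    tibble::tibble(organism = "B. subtilis", curve), path)
  tbl <- read_survival_curves(path)
  fit <- fit_loglinear(tbl)
  expect_equal(fit$organism, "B. subtilis")
  expect_equal(dose_to_fraction(fit$d10_gy, 1e-6), 8400, tolerance = 1e-6)
})
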