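test_that("measurement-to-K inversion applies clamping and sensitivity flags", {
  lines <- reference_lines()
  # the intercept maps to exactly zero, unclamped
  k0 <- k_from_measurement(4.9, lines$acsins)
  expect_identical(k0$value, 0)
  expect_length(k0$flags, 0)

  # D_np exactly at the sensitivity floor is still usable (boundary exclusive)
  k1 <- k_from_measurement(1.0, lines$acsins)
  expect_equal(k1$value, (4.9 - 1) / 2045, tolerance = 1e-12)
  expect_false("low_sensitivity_dnp" %in% k1$flags)
  # strictly below the floor is flagged
  k2 <- k_from_measurement(0.99, lines$acsins)
  expect_true("low_sensitivity_dnp" %in% k2$flags)

  # published DLS arithmetic
  k3 <- k_from_measurement(41.03, lines$dls)
  expect_equal(k3$value, 1e-3, tolerance = 1e-12)

  # measurement above the intercept: negative raw K clamped to zero
  k4 <- k_from_measurement(60, lines$acsins)
  expect_identical(k4$value, 0)
  expect_true("clamped_to_zero" %in% k4$flags)
  expect_lt(k4$raw, 0)

  # strongly negative kD implies K above the branching cutoff
  k5 <- k_from_measurement(-100, lines$dls)
  expect_gt(k5$value, 0.01)
  expect_true("above_branching_cutoff" %in% k5$flags)

  # missing measurement: absent-result marker, not an exception
  k6 <- k_from_measurement(NA_real_, lines$dls)
  expect_true(is.na(k6$value))
  expect_true("missing_measurement" %in% k6$flags)
})

test_that("predicted curves follow the law and carry dilution flags", {
  # K = 0: pure monomer baseline at every concentration
  cv <- predict_curve(0, seq(70, 250, by = 10))
  p <- model_params()
  expect_equal(cv$visc_cP, p$A * cv$conc_mg_ml^p$exponent, tolerance = 1e-12)
  expect_true(all(cv$below_entanglement_floor == (cv$conc_mg_ml < 100)))

  # cross-concentration round trips frozen from bisection inversion of
  # printed 150 mg/mL predictions
  k3 <- k_from_viscosity(15.6, 150)
  expect_equal(predict_curve(k3, 159)$visc_cP, 20.0074, tolerance = 1e-4)
  k15 <- k_from_viscosity(21.8, 150)
  expect_equal(predict_curve(k15, 142)$visc_cP, 17.1136, tolerance = 1e-4)

  # a missing K propagates as NA predictions
  kna <- k_from_measurement(NA_real_, reference_lines()$acsins)
  expect_true(all(is.na(predict_curve(kna, c(100, 150))$visc_cP)))
  expect_error(predict_curve(1e-3, c(-50, 150)), "positive")
})

test_that("the 20 cP developability call is boundary-inclusive", {
  expect_identical(classify_viscosity(20.0), "good")
  expect_identical(classify_viscosity(20.1), "bad")
  expect_identical(classify_viscosity(0), "good")
  expect_identical(classify_viscosity(c(19, 21, NA)),
                   c("good", "bad", NA_character_))
  expect_error(classify_viscosity(-1), "non-negative")
})

test_that("performance labels follow the screening definitions", {
  # printed examples: both-low + viscous, one-high + fluid, high + viscous
  expect_identical(performance_label(12.8, 17.5, 34.2), "False positive")
  expect_identical(performance_label(20.0, 24.1, 13.4), "False negative")
  expect_identical(performance_label(10.4, 21.0, 25.9), "TRUE")
  # both predictions and experiment low
  expect_identical(performance_label(10, 12, 15), "TRUE")
  # both predictions and experiment high
  expect_identical(performance_label(25, 23, 30), "TRUE")
  # a missing prediction falls back to the available source
  expect_identical(performance_label(NA, 12, 30), "False positive")
  expect_identical(performance_label(NA, 22, 15), "False negative")
  expect_true(is.na(performance_label(NA, NA, 30)))
  # detection-convention aliases
  expect_identical(standard_label(c("TRUE", "False positive",
                                    "False negative")),
                   c("true", "false_negative", "false_positive"))
})

test_that("every published performance cell is reproduced exactly", {
  vp <- example_panel("validation")
  expect_identical(nrow(vp), 17L)
  lab_exp <- performance_label(vp$acsins_expconc_cP, vp$dls_expconc_cP,
                               vp$experimental_cP)
  expect_identical(lab_exp, vp$performance_expconc)
  lab_150 <- performance_label(vp$acsins_150_cP, vp$dls_150_cP,
                               vp$experimental_cP)
  expect_identical(lab_150, vp$performance_150)

  tp <- example_panel("test")
  expect_identical(nrow(tp), 9L)
  expect_identical(performance_label(tp$acsins_cP, tp$dls_cP,
                                     tp$experimental_cP),
                   tp$performance)
})

test_that("predictions are monotone in the measurements and threshold-consistent", {
  lines <- reference_lines()
  excl <- exclusion_config()
  eta150_from <- function(x, line) {
    predict_curve(k_from_measurement(x, line, excl), 150)$visc_cP
  }
  dnp_grid <- seq(0.5, 6, by = 0.25)
  eta_a <- vapply(dnp_grid, eta150_from, numeric(1), line = lines$acsins)
  expect_true(all(diff(eta_a) <= 0))
  kd_grid <- seq(-80, 70, by = 5)
  eta_d <- vapply(kd_grid, eta150_from, numeric(1), line = lines$dls)
  expect_true(all(diff(eta_d) <= 0))
  # increasing K never flips a bad call back to good
  K_grid <- seq(0, 8e-3, length.out = 100)
  cls <- classify_viscosity(viscosity(K_grid, 150))
  expect_true(all(diff(cls == "bad") >= 0))
})

test_that("cohort evaluation tallies flags, viscous molecules and misses", {
  vp <- example_panel("validation")
  ev <- evaluate_cohort(data.frame(molecule_id = vp$molecule_id,
                                   pred_acsins = vp$acsins_150_cP,
                                   pred_dls = vp$dls_150_cP,
                                   experimental = vp$experimental_cP))
  expect_identical(ev$n_flagged, 3L)
  expect_setequal(ev$flagged_ids, c("V_1", "V_2", "V_15"))
  expect_identical(ev$n_experimentally_viscous, 6L)
  expect_identical(ev$n_missed_viscous, 3L)
  expect_setequal(ev$missed_ids, c("V_7", "V_9", "V_11"))

  # all-zero predictions flag nothing
  ev0 <- evaluate_cohort(data.frame(molecule_id = c("a", "b"),
                                    pred_acsins = 0, pred_dls = 0,
                                    experimental = c(5, 50)))
  expect_identical(ev0$n_flagged, 0L)
  expect_identical(ev0$n_missed_viscous, 1L)

  # empty input yields an empty summary, not an error
  ev_empty <- evaluate_cohort(data.frame(molecule_id = character(),
                                         pred_acsins = numeric(),
                                         pred_dls = numeric(),
                                         experimental = numeric()))
  expect_identical(ev_empty$n, 0L)
  expect_identical(ev_empty$n_flagged, 0L)
})

test_that("screen_cohort assembles per-molecule results and a conservative combined call", {
  cohort <- make_exact_cohort(c(1e-4, 1e-3, 3e-3, 5e-3))
  scr <- screen_cohort(cohort)
  r <- scr$results
  expect_identical(nrow(r), 4L)
  # measurements sit exactly on the lines, so both sources agree
  expect_equal(r$K_acsins, r$K_dls, tolerance = 1e-10)
  expect_equal(r$eta150_acsins, viscosity(c(1e-4, 1e-3, 3e-3, 5e-3), 150),
               tolerance = 1e-8)
  expect_identical(r$class_combined,
                   ifelse(r$eta150_acsins > 20 | r$eta150_dls > 20,
                          "bad", "good"))
  # curves cover both sources and include 150 mg/mL
  expect_true(all(c("acsins", "dls") %in% scr$curves$source))
  expect_true(150 %in% scr$curves$conc_mg_ml)
  # a molecule with only one measurement still gets the other source as NA
  m <- cohort$molecules
  m$kd_ml_per_g[1] <- NA
  scr2 <- screen_cohort(ab_cohort(m, cohort$viscosity))
  expect_true(is.na(scr2$results$eta150_dls[1]))
  expect_identical(scr2$results$class_combined[1],
                   scr2$results$class_acsins[1])
})
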