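test_that("training K fits recover generating constants and flag edge cases", {
  K <- c(1e-4, 5e-4, 1e-3, 5e-3)
  cohort <- make_exact_cohort(K)
  k_table <- fit_training_k(cohort)
  expect_equal(k_table$K_ml_per_mg, K, tolerance = 1e-8)
  expect_true(all(!k_table$non_entangled))
  expect_true(all(k_table$used))

  # below-baseline molecule is flagged non-entangled, not dropped
  mol <- data.frame(molecule_id = c("A", "B", "C"))
  visc <- rbind(
    data.frame(molecule_id = "A", conc_mg_ml = c(110, 150),
               visc_cP = 0.8 * viscosity(0, c(110, 150))),
    data.frame(molecule_id = "B", conc_mg_ml = c(60, 80),
               visc_cP = viscosity(1e-3, c(60, 80))),
    data.frame(molecule_id = "C", conc_mg_ml = 150,
               visc_cP = viscosity(1e-3, 150))
  )
  k_table2 <- fit_training_k(ab_cohort(mol, visc))
  expect_true(k_table2$non_entangled[k_table2$molecule_id == "A"])
  expect_lt(k_table2$K_ml_per_mg[k_table2$molecule_id == "A"], 0)
  # molecule with points only below 100 mg/mL is skipped with a reason
  expect_false(k_table2$used[k_table2$molecule_id == "B"])
  expect_identical(k_table2$reason[k_table2$molecule_id == "B"],
                   "below_entanglement_floor")
  expect_equal(k_table2$K_ml_per_mg[k_table2$molecule_id == "C"], 1e-3,
               tolerance = 1e-8)
})

test_that("HT outlier detection flags only molecules beyond the separator", {
  # molecules exactly on the line-consistency locus are never flagged
  cohort <- make_exact_cohort(c(1e-4, 5e-4, 1e-3, 2e-3))
  lines <- reference_lines()
  # separator halfway between the consistent locus and an HT locus
  sep <- list(slope = 0.08, intercept = 0.4)
  expect_identical(detect_ht_outliers(cohort, sep), character())

  # an injected HT molecule: D_np reports K, kD reports 5K
  K_ht <- 2e-3
  m <- cohort$molecules
  m <- rbind(m, data.frame(
    molecule_id = "HT1",
    dnp_um2_per_s = lines$acsins$intercept - lines$acsins$slope * K_ht,
    kd_ml_per_g = lines$dls$intercept - lines$dls$slope * 5 * K_ht,
    plasmon_shift_nm = NA_real_, split = NA_character_
  ))
  flagged <- detect_ht_outliers(ab_cohort(m), sep)
  expect_identical(flagged, "HT1")

  # unset separator: warning and empty result
  expect_warning(none <- detect_ht_outliers(cohort, NULL), "separator")
  expect_identical(none, character())

  # empty cohort
  empty <- ab_cohort(data.frame(molecule_id = character()))
  expect_identical(detect_ht_outliers(empty, sep), character())
})

test_that("calibration OLS is exact on collinear pairs and honors exclusions", {
  lines <- reference_lines()
  K <- c(1e-4, 3e-4, 6e-4, 1e-3, 1.5e-3)
  pairs <- make_line_pairs(K, lines$acsins)
  fit <- suppressWarnings(fit_calibration_line(pairs, "acsins"))
  expect_equal(fit$intercept, 4.9, tolerance = 1e-8)
  expect_equal(fit$slope, 2045, tolerance = 1e-8)
  expect_identical(fit$n_used, 5L)
  # K at the line's intercept maps back to exactly zero
  expect_equal((fit$intercept - fit$intercept) / fit$slope, 0)

  # dls branching-cutoff rule: the strong binder is excluded from the fit
  # (its measured kD is kept in the plausible range so only the K rule fires)
  K2 <- c(1e-4, 5e-4, 1e-3, 2e-3, 0.02)
  pairs2 <- make_line_pairs(K2, lines$dls)
  pairs2$measurement[5] <- -30
  fit2 <- suppressWarnings(fit_calibration_line(pairs2, "dls"))
  expect_identical(fit2$n_used, 4L)
  expect_identical(fit2$excluded$reason, "above_branching_cutoff")

  # kd plausibility rule
  pairs3 <- make_line_pairs(c(1e-4, 5e-4, 1e-3, 2e-3), lines$dls)
  pairs3$measurement[1] <- 84
  fit3 <- suppressWarnings(fit_calibration_line(pairs3, "dls"))
  expect_identical(fit3$excluded$reason, "kd_out_of_range")

  # acsins rules: sensitivity floor, HT suspicion, non-entangled
  pairs4 <- make_line_pairs(c(1e-4, 5e-4, 1e-3, 2.5e-3, 8e-4, 1.2e-3),
                            lines$acsins)
  pairs4$non_entangled <- c(TRUE, rep(FALSE, 5))
  pairs4$suspected_ht <- c(FALSE, TRUE, rep(FALSE, 4))
  # K = 2.5e-3 puts D_np below 1 um^2/s -> low sensitivity exclusion
  fit4 <- suppressWarnings(fit_calibration_line(pairs4, "acsins"))
  expect_identical(fit4$n_used, 3L)
  expect_setequal(fit4$excluded$reason,
                  c("non_entangled", "suspected_ht", "low_dnp_sensitivity"))
  # ledger partitions the cohort: each molecule appears exactly once
  all_ids <- c(fit4$used_ids, fit4$excluded$molecule_id)
  expect_setequal(all_ids, pairs4$molecule_id)
  expect_identical(anyDuplicated(all_ids), 0L)

  # fewer than 3 survivors is an error carrying the ledger
  expect_error(fit_calibration_line(make_line_pairs(c(1e-4, 2e-4), lines$dls),
                                    "dls"),
               "fewer than 3")
})

test_that("calibration is invariant to molecule ordering", {
  lines <- reference_lines()
  set.seed(11)
  K <- 10^runif(20, -5, -2.2)
  pairs <- make_line_pairs(K, lines$acsins)
  pairs$measurement <- pairs$measurement + rnorm(20, 0, 0.2)
  fit_fwd <- fit_calibration_line(pairs, "acsins")
  fit_rev <- fit_calibration_line(pairs[rev(seq_len(nrow(pairs))), ], "acsins")
  expect_equal(fit_fwd$intercept, fit_rev$intercept, tolerance = 1e-12)
  expect_equal(fit_fwd$slope, fit_rev$slope, tolerance = 1e-12)
})

test_that("noisy calibration recovers the generating slope within 3 standard errors", {
  set.seed(2024)
  lines <- reference_lines()
  K <- 10^runif(60, -5, -2.75)          # within the acsins sensitive range
  pairs <- make_line_pairs(K, lines$acsins)
  pairs$measurement <- pairs$measurement + rnorm(60, 0, 0.3)
  fit <- suppressWarnings(fit_calibration_line(pairs, "acsins"))
  expect_lt(abs(fit$slope - 2045), 3 * fit$slope_se)
})

test_that("end-to-end calibration on a noise-free synthetic cohort reproduces the published lines", {
  cfg <- synthetic_config(n_molecules = 50, seed = 7, dnp_noise_sd = 0,
                          kd_noise_sd = 0, visc_lognoise_sd = 0,
                          concentrations = c(110, 150))
  gen <- generate_cohort(cfg)
  cal <- suppressWarnings(calibrate_cohort(gen$cohort))
  expect_equal(cal$acsins$intercept, 4.9, tolerance = 1e-6)
  expect_equal(cal$acsins$slope, 2045, tolerance = 1e-6)
  expect_equal(cal$dls$intercept, 56.03, tolerance = 1e-6)
  expect_equal(cal$dls$slope, 15000, tolerance = 1e-6)
  # every molecule is accounted for exactly once per assay
  for (src in c("acsins", "dls")) {
    ids <- c(cal[[src]]$used_ids, cal[[src]]$excluded$molecule_id)
    expect_setequal(ids, gen$cohort$molecules$molecule_id)
  }
})

test_that("cohort splitting is seeded, exact and label-complete", {
  cohort <- make_exact_cohort(rep(1e-3, 89))
  sp <- split_cohort(cohort, c(63, 17, 9), seed = 1)
  tab <- table(sp$molecules$split)
  expect_identical(as.integer(tab[c("train", "validation", "test")]),
                   c(63L, 17L, 9L))
  # reproducible under the same seed
  sp2 <- split_cohort(cohort, c(63, 17, 9), seed = 1)
  expect_identical(sp$molecules$split, sp2$molecules$split)
  # degenerate split: everything train
  sp3 <- split_cohort(cohort, c(89, 0, 0), seed = 3)
  expect_true(all(sp3$molecules$split == "train"))
  expect_error(split_cohort(cohort, c(60, 17, 9), seed = 1), "sum")
  expect_error(split_cohort(cohort, c(63, 17, 9)), "seed")
})
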