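test_that("milk solids draws are reproducible, truncated and degenerate-safe", {
  s1 <- sample_milk_solids(500, seed = 42)
  s2 <- sample_milk_solids(500, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0.5))
  # zero SD collapses every draw onto the mean
  cfg <- cohort_config(solids = list(fat = c(mean = 3.37, sd = 0),
                                     protein = c(mean = 3.36, sd = 0),
                                     lactose = c(mean = 4.74, sd = 0),
                                     floor = 0.5))
  s0 <- sample_milk_solids(50, seed = 1, config = cfg)
  expect_true(all(s0$fat_pct == 3.37))
  expect_true(all(s0$lactose_pct == 4.74))
  expect_error(sample_milk_solids(0), "n must be")
})

test_that("zero coupling noise gives a perfectly linear fat relation", {
  cfg <- cohort_config(coupling = list(target_r = -0.66, fat_mean = 3.37,
                                       fat_sd = 0.54, slope = -0.5),
                       delta_eps_noise_sd = 0)
  solids <- sample_milk_solids(200, seed = 3)
  pars <- solids_to_params(solids, "stage1", cfg, seed = 4)
  expect_equal(cor(pars$delta_eps, solids$fat_pct), -1, tolerance = 1e-12)
})

test_that("default coupling recovers the target correlation on latent draws", {
  solids <- sample_milk_solids(5000, seed = 7)
  pars <- solids_to_params(solids, "stage1", seed = 8)
  expect_lt(abs(cor(pars$delta_eps, solids$fat_pct) - (-0.66)), 0.03)
})

test_that("impossible coupling configurations raise calibration errors", {
  bad <- cohort_config(coupling = list(target_r = -0.66, fat_mean = 3.37,
                                       fat_sd = 0.54, slope = -5))
  expect_error(solids_to_params(sample_milk_solids(10, seed = 1), "stage3",
                                bad, seed = 2),
               "calibration error")
  bad_r <- cohort_config(coupling = list(target_r = -1.2, fat_mean = 3.37,
                                         fat_sd = 0.54, slope = NULL))
  expect_error(solids_to_params(sample_milk_solids(10, seed = 1), "stage1",
                                bad_r, seed = 2),
               "calibration error")
})

test_that("instrument noise has the configured relative scale and floors at zero", {
  sp <- evaluate_permittivity(milk_params())
  expect_identical(simulate_instrument_noise(sp, 0), sp)
  # empirical relative SD of one point across replicate draws
  vals <- vapply(1:1000, function(i)
    simulate_instrument_noise(sp, 0.05, seed = i)$eps_real[50], numeric(1))
  expect_lt(abs(sd(vals / sp$eps_real[50]) - 0.05), 0.005)
  # near-zero loss points cannot go negative
  tiny <- milk_spectrum(1:8, rep(5, 8), rep(1e-4, 8))
  noisy <- simulate_instrument_noise(tiny, 0.4, seed = 5)
  expect_true(all(noisy$eps_imag >= 0))
  expect_error(simulate_instrument_noise(sp, 0.6), "rel_sd")
})

test_that("fixture designs reproduce the reference point counts exactly", {
  rnd <- simulate_cohort(design_preset("random_fixture", seed = 5))
  expect_equal(nrow(rnd$table), 117)
  expect_equal(sum(rnd$table$pregnant_outcome), 50)
  expect_equal(sum(!rnd$table$pregnant_outcome), 67)

  preg <- simulate_cohort(design_preset("pregnant_fixture", seed = 5))
  expect_equal(as.integer(table(preg$table$stage)[c("stage1", "stage2",
                                                    "stage3")]),
               c(66L, 8L, 14L))
  expect_equal(length(unique(preg$table$cow_id)), 5)

  nonp <- simulate_cohort(design_preset("nonpregnant_fixture", seed = 5))
  expect_equal(as.integer(table(nonp$table$stage)[c("before", "after")]),
               c(70L, 69L))
  expect_equal(length(unique(nonp$table$cow_id)), 7)
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- simulate_cohort(design_preset("pregnant_fixture", seed = 9))
  b <- simulate_cohort(design_preset("pregnant_fixture", seed = 9))
  expect_identical(a$table, b$table)
  expect_identical(a$spectra[[1]], b$spectra[[1]])
  c <- simulate_cohort(design_preset("pregnant_fixture", seed = 10))
  expect_false(identical(a$table$fat_pct, c$table$fat_pct))
})

test_that("pregnant preset contracts the latent dielectric-strength dispersion", {
  coh <- simulate_cohort(design_preset("pregnant_fixture", seed = 21))
  s <- aggregate(true_delta_eps ~ stage, coh$table, sd)
  expect_gt(s$true_delta_eps[s$stage == "stage1"],
            s$true_delta_eps[s$stage == "stage3"])
})

test_that("longitudinal protocols schedule at the design interval", {
  wk <- simulate_cohort(design_preset("weekly", seed = 2),
                        cohort_config(n_replicates = 1L))
  expect_equal(length(unique(wk$table$cow_id)), 12)
  gaps <- unlist(tapply(wk$table$day, wk$table$cow_id, diff))
  expect_true(all(gaps == 7))
  expect_true(all(wk$table$stage %in%
                    c("stage1", "stage2", "stage3", "before", "after")))
  expect_error(cohort_design("daily", duration_days = 0), "duration")
})

test_that("cohort fits average replicates and report replicate SDs", {
  coh <- simulate_cohort(design_preset("random_fixture", seed = 3))
  expect_equal(length(coh$spectra), 117 * 3)
  sub <- coh
  sub$table <- sub$table[1:6, ]
  keep <- vapply(sub$spectra, function(s)
    s$meta$sample_id %in% sub$table$spectrum_id, logical(1))
  sub$spectra <- sub$spectra[keep]
  fitted <- fit_cohort(sub)
  expect_true(all(is.finite(fitted$table$delta_eps)))
  expect_true(all(fitted$table$fit_converged))
  expect_true(all(fitted$table$rep_sd_delta_eps >= 0))
  # replicate-averaged fits sit close to the latent truth
  expect_lt(max(abs(fitted$table$delta_eps - fitted$table$true_delta_eps)), 1)
})
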