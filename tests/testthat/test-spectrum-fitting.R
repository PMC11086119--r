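test_that("initial guess lands within 20% of the generating Debye values", {
  sp <- evaluate_permittivity(debye_params())          # 5 / 70 / 8 ps
  g <- initial_guess(sp)
  expect_lt(abs(g$eps_inf - 5) / 5, 0.2)
  expect_lt(abs(g$delta_eps - 70) / 70, 0.2)
  expect_lt(abs(g$tau_ps - 8) / 8, 0.2)
  # low-frequency identity recovers a 1 S/m dc term within 20%
  sp2 <- evaluate_permittivity(cc_parameters(eps_inf = 5, delta_eps = 70,
                                             tau_ps = 8, alpha = 1,
                                             sigma_dc = 1))
  g2 <- initial_guess(sp2)
  expect_lt(abs(g2$sigma_dc - 1), 0.2)
})

test_that("flat spectrum triggers an initialization error", {
  flat <- milk_spectrum(1:8, rep(5, 8), rep(0, 8))
  expect_error(initial_guess(flat), "dispersion")
})

test_that("noiseless spectra are recovered to high relative accuracy", {
  truth <- cc_parameters(eps_inf = 5.5, delta_eps = 68, tau_ps = 9,
                         alpha = 0.98, sigma_dc = 0.08)
  fit <- fit_spectrum(evaluate_permittivity(truth))
  for (p in c("eps_inf", "delta_eps", "tau_ps", "alpha", "sigma_dc"))
    expect_lt(abs(fit$params[[p]] - truth[[p]]) / abs(truth[[p]]), 1e-4)
  expect_true(fit$converged)
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("round-trip property: 100 random draws inside bounds recover to 1e-3", {
  set.seed(11)
  lo <- c(1, 1e-6, 1, 0.5, 0)
  hi <- c(10, 120, 50, 1, 3)
  for (i in 1:100) {
    v <- lo + (0.05 + 0.9 * runif(5)) * (hi - lo)
    truth <- cc_parameters(eps_inf = v[1], delta_eps = v[2], tau_ps = v[3],
                           alpha = v[4], sigma_dc = v[5])
    fit <- fit_spectrum(evaluate_permittivity(truth),
                        fit_options(n_starts = 5, seed = i))
    rel <- max(abs(unlist(fit$params[1:5]) - v) / pmax(abs(v), 1e-6))
    expect_lt(rel, 1e-3)
  }
})

test_that("fitter beats a brute-force grid oracle on its own objective", {
  truth <- cc_parameters(eps_inf = 5.5, delta_eps = 68, tau_ps = 9,
                         alpha = 0.9, sigma_dc = 0.6)
  sp <- evaluate_permittivity(truth)
  opts <- fit_options()
  fit <- fit_spectrum(sp, opts)
  # coarse 4-D grid over (delta_eps, tau, alpha, sigma) at the true eps_inf
  grid_obj <- Inf
  for (de in seq(50, 90, by = 5))
    for (tau in seq(5, 15, by = 2))
      for (al in seq(0.7, 1, by = 0.1))
        for (sg in seq(0, 1.5, by = 0.3)) {
          par <- c(eps_inf = 5.5, delta_eps = de, tau_ps = tau, alpha = al,
                   sigma_dc = sg, jonscher_A = 0, jonscher_n = 0.5)
          grid_obj <- min(grid_obj, lactowave:::fit_objective(par, sp, opts))
        }
  expect_lte(fit$objective, grid_obj)
})

test_that("with 5% noise the dielectric strength is recovered within Monte Carlo bands", {
  truth <- milk_params()
  sp0 <- evaluate_permittivity(truth)
  est <- vapply(1:50, function(i) {
    spn <- simulate_instrument_noise(sp0, 0.05, seed = i)
    fit_spectrum(spn, fit_options(n_starts = 2, seed = i))$params$delta_eps
  }, numeric(1))
  expect_lt(abs(mean(est) - truth$delta_eps), 3 * sd(est))
})

test_that("multi-start refinement never reports worse than its own starts", {
  truth <- cc_parameters(eps_inf = 6, delta_eps = 60, tau_ps = 12,
                         alpha = 0.8, sigma_dc = 1.2)
  spn <- simulate_instrument_noise(evaluate_permittivity(truth), 0.05, seed = 4)
  f1 <- fit_spectrum(spn, fit_options(n_starts = 1))
  f5 <- fit_spectrum(spn, fit_options(n_starts = 5))
  expect_lte(f5$objective, f1$objective + 1e-12)
})

test_that("objective landscape is unit-consistent under tau/frequency rescaling", {
  p1 <- cc_parameters(eps_inf = 5, delta_eps = 70, tau_ps = 8, alpha = 0.9,
                      sigma_dc = 0)
  p2 <- cc_parameters(eps_inf = 5, delta_eps = 70, tau_ps = 80, alpha = 0.9,
                      sigma_dc = 0)
  grid <- exp(seq(log(0.5), log(40), length.out = 64))
  sp1 <- evaluate_permittivity(p1, grid)
  sp2 <- evaluate_permittivity(p2, grid / 10)
  expect_equal(sp1$eps_real, sp2$eps_real, tolerance = 1e-12)
  expect_equal(sp1$eps_imag, sp2$eps_imag, tolerance = 1e-12)
  opts <- fit_options()
  v1 <- c(eps_inf = 5, delta_eps = 72, tau_ps = 9, alpha = 0.88,
          sigma_dc = 0, jonscher_A = 0, jonscher_n = 0.5)
  v2 <- v1; v2[["tau_ps"]] <- 90
  expect_equal(lactowave:::fit_objective(v1, sp1, opts),
               lactowave:::fit_objective(v2, sp2, opts), tolerance = 1e-10)
})

test_that("freeing a Jonscher term generated at zero cannot worsen the fit", {
  truth <- milk_params()
  spn <- simulate_instrument_noise(evaluate_permittivity(truth), 0.05, seed = 9)
  frozen <- fit_spectrum(spn, fit_options(freeze_jonscher = TRUE))
  free <- fit_spectrum(spn, fit_options(freeze_jonscher = FALSE))
  expect_lte(free$objective, frozen$objective + 1e-6)
})

test_that("replicate parameter SD follows the n-1 sample formula", {
  mk <- function(de) cc_parameters(eps_inf = 5, delta_eps = de, tau_ps = 8)
  fits <- lapply(c(69, 70, 71), mk)
  expect_equal(replicate_parameter_sd(fits)[["delta_eps"]], 1.0)
  # identical replicates give zero SD; order does not matter
  expect_true(all(replicate_parameter_sd(lapply(rep(70, 3), mk)) == 0))
  expect_equal(replicate_parameter_sd(fits),
               replicate_parameter_sd(rev(fits)))
  expect_error(replicate_parameter_sd(fits[1]), "at least 2")
})

test_that("NaN input and fixed-parameter options are handled", {
  sp <- evaluate_permittivity(milk_params())
  sp$eps_real[3] <- NaN
  expect_error(fit_spectrum(sp), "finite")
  spn <- simulate_instrument_noise(evaluate_permittivity(milk_params()),
                                   0.05, seed = 2)
  fit <- fit_spectrum(spn, fit_options(n_starts = 1, fix = c(eps_inf = 5.5)))
  expect_identical(fit$params$eps_inf, 5.5)
  expect_error(fit_options(fix = c(bogus = 1)), "named")
})
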