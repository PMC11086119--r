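# Bounded complex nonlinear least squares for the milk permittivity model.
# The objective stacks relative residuals of eps_real and eps_imag, matching
# the instrument's relative accuracy specification (5% on both parts).

#' Default fitting options
#'
#' @param freeze_jonscher if `TRUE` (default) the Jonscher tail is fixed at
#'   `A = 0` and only the five Cole--Cole + conductivity parameters are
#'   free; set `FALSE` to fit `A` and `n` as well.
#' @param fix named numeric vector of additional parameters to hold fixed
#'   during optimisation, e.g. `c(eps_inf = 5.5)`.  The 0.5--40 GHz band
#'   ends well below the high-frequency plateau, so `eps_inf` trades off
#'   almost perfectly against `delta_eps` under noise; fixing it at a
#'   literature value is the standard remedy in microwave-band fitting.
#' @param n_starts number of optimisation starts: the data-driven initial
#'   guess plus `n_starts - 1` seeded random perturbations of it (+-30%).
#' @param seed integer seed controlling the start perturbations.
#' @param eps_imag_floor floor applied to the observed loss in the relative
#'   residual denominator, preventing blow-up where the loss crosses zero.
#' @param ftol relative tolerance on the objective decrease.
#' @param max_eval maximum residual evaluations per start.
#' @param lower,upper named bound vectors; defaults bracket water/milk
#'   physics at 25 degC generously.
#' @return a list of options for [fit_spectrum()].
#' @export
fit_options <- function(freeze_jonscher = TRUE, fix = NULL,
                        n_starts = 5L, seed = 1L,
                        eps_imag_floor = 0.05, ftol = 1e-10, max_eval = 2000L,
                        lower = c(eps_inf = 1, delta_eps = 1e-6, tau_ps = 1,
                                  alpha = 0.5, sigma_dc = 0,
                                  jonscher_A = 0, jonscher_n = 1e-3),
                        upper = c(eps_inf = 10, delta_eps = 120, tau_ps = 50,
                                  alpha = 1, sigma_dc = 3,
                                  jonscher_A = 50, jonscher_n = 0.999)) {
  if (!is.null(fix) && (is.null(names(fix)) ||
                        !all(names(fix) %in% cc_parameter_names())))
    stop("fit_options: fix must be a named vector of model parameters",
         call. = FALSE)
  list(freeze_jonscher = isTRUE(freeze_jonscher), fix = fix,
       n_starts = as.integer(n_starts),
       seed = as.integer(seed), eps_imag_floor = eps_imag_floor, ftol = ftol,
       max_eval = as.integer(max_eval), lower = lower, upper = upper)
}

clip_to_bounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Data-driven initial guess for the permittivity model
#'
#' Estimates the relaxation time from the loss-peak position in the upper
#' half of the band, then solves the Debye end-point identities for
#' `delta_eps` and `eps_inf` (the band does not reach the high-frequency
#' plateau, so the raw end values must be extrapolated), and reads the dc
#' conductivity off the lowest-frequency loss point after removing the
#' estimated relaxation contribution.
#'
#' @param spectrum a [milk_spectrum()].
#' @param options a [fit_options()] list (bounds are used for clipping).
#' @return a [cc_parameters()] guess with `alpha = 0.95`, `A = 0`.
#' @export
initial_guess <- function(spectrum, options = fit_options()) {
  validate_spectrum(spectrum)
  f <- spectrum$frequency_ghz
  er <- spectrum$eps_real
  ei <- spectrum$eps_imag
  n <- length(f)

  if (er[1] - er[n] <= 0)
    stop("initial_guess: spectrum shows no dispersion (eps_real does not decrease); cannot initialize delta_eps",
         call. = FALSE)

  # loss peak restricted to the upper half of the band in log-frequency,
  # where the dc tail cannot masquerade as the relaxation peak
  f_mid <- sqrt(f[1] * f[n])
  upper_band <- which(f >= f_mid)
  f_peak <- f[upper_band[which.max(ei[upper_band])]]
  tau_ps <- relaxation_time_from_peak(f_peak)

  # Debye end-point extrapolation:
  #   er[1]  ~ eps_inf + delta_eps        (low-frequency plateau)
  #   er[n]  ~ eps_inf + delta_eps/(1+x), x = (w_hi tau)^2
  x_hi <- (angular_frequency(f[n]) * tau_ps * 1e-12)^2
  delta_eps <- (er[1] - er[n]) * (1 + x_hi) / x_hi
  eps_inf <- er[1] - delta_eps

  # dc conductivity from the lowest point, minus the relaxation loss there
  w_lo <- angular_frequency(f[1])
  wt_lo <- w_lo * tau_ps * 1e-12
  relax_lo <- delta_eps * wt_lo / (1 + wt_lo^2)
  sigma_dc <- max(0, (ei[1] - relax_lo) * w_lo * EPS0)

  lo <- options$lower
  hi <- options$upper
  cc_parameters(
    eps_inf = clip_to_bounds(eps_inf, lo[["eps_inf"]], hi[["eps_inf"]]),
    delta_eps = clip_to_bounds(delta_eps, lo[["delta_eps"]], hi[["delta_eps"]]),
    tau_ps = clip_to_bounds(tau_ps, lo[["tau_ps"]], hi[["tau_ps"]]),
    alpha = 0.95,
    sigma_dc = clip_to_bounds(sigma_dc, lo[["sigma_dc"]], hi[["sigma_dc"]]),
    jonscher_A = 0, jonscher_n = 0.5)
}

# Candidate starts on a coarse (alpha, tau) grid.  Given alpha and tau,
# eps_real at the two band edges is linear in (eps_inf, delta_eps):
#   eps'(w) = eps_inf + delta_eps * Re[1 / (1 + (i w tau)^alpha)],
# so both solve exactly; sigma_dc then follows from the residual loss at
# the lowest frequency.  This covers broad-alpha basins that the
# Debye-based guess misses.
candidate_starts <- function(spectrum, options, free) {
  f <- spectrum$frequency_ghz
  er <- spectrum$eps_real
  ei <- spectrum$eps_imag
  n <- length(f)
  f_mid <- sqrt(f[1] * f[n])
  upper_band <- which(f >= f_mid)
  f_peak <- f[upper_band[which.max(ei[upper_band])]]
  tau0 <- relaxation_time_from_peak(f_peak)
  w_lo <- angular_frequency(f[1])
  cands <- list()
  for (alpha in c(0.6, 0.75, 0.9, 0.98)) {
    for (fac in c(0.5, 1, 2)) {
      tau <- clip_to_bounds(tau0 * fac, options$lower[["tau_ps"]],
                            options$upper[["tau_ps"]])
      g <- Re(1 / (1 + (1i * angular_frequency(c(f[1], f[n])) *
                          tau * 1e-12)^alpha))
      if (abs(g[1] - g[2]) < 1e-9) next
      delta_eps <- (er[1] - er[n]) / (g[1] - g[2])
      eps_inf <- er[1] - delta_eps * g[1]
      cc_lo <- -Im(delta_eps / (1 + (1i * w_lo * tau * 1e-12)^alpha))
      sigma <- max(0, (ei[1] - cc_lo) * w_lo * EPS0)
      v <- c(eps_inf = eps_inf, delta_eps = delta_eps, tau_ps = tau,
             alpha = alpha, sigma_dc = sigma,
             jonscher_A = 0, jonscher_n = 0.5)[free]
      cands[[length(cands) + 1]] <-
        clip_to_bounds(v, options$lower[free], options$upper[free])
    }
  }
  cands
}

# Stacked relative residual vector used by the optimiser and the tests'
# brute-force oracle alike.
fit_residuals <- function(par_vec, spectrum, options) {
  p <- as.list(par_vec)
  eps <- complex_permittivity(p, spectrum$frequency_ghz)
  r1 <- (Re(eps) - spectrum$eps_real) / spectrum$eps_real
  r2 <- (-Im(eps) - spectrum$eps_imag) /
    pmax(spectrum$eps_imag, options$eps_imag_floor)
  c(r1, r2)
}

fit_objective <- function(par_vec, spectrum, options) {
  sum(fit_residuals(par_vec, spectrum, options)^2)
}

params_to_vector <- function(p, free) unlist(p[free])

vector_to_params <- function(vec, fixed) {
  p <- c(as.list(vec), fixed)[cc_parameter_names()]
  class(p) <- "cc_parameters"
  p
}

#' Fit the permittivity model to a measured spectrum
#'
#' Bounded Levenberg--Marquardt minimisation of the stacked relative
#' residual \eqn{[(\varepsilon'_m - \varepsilon'_o)/\varepsilon'_o;\;
#' (\varepsilon''_m - \varepsilon''_o)/\max(\varepsilon''_o, floor)]}
#' over the model parameters, multi-started from the data-driven initial
#' guess plus seeded perturbations; the best converged start wins.
#' Deterministic given the spectrum and options.
#'
#' @param spectrum a [milk_spectrum()].
#' @param options a [fit_options()] list.
#' @return a `fit_result` list: `params` ([cc_parameters()]),
#'   `residual_rms` (root-mean-square relative residual), `objective`
#'   (residual sum of squares), `n_points`, `converged`, `n_starts_used`,
#'   `options_echo`.
#' @examples
#' truth <- cc_parameters(eps_inf = 5, delta_eps = 70, tau_ps = 8,
#'                        alpha = 0.98, sigma_dc = 0.5)
#' sp <- evaluate_permittivity(truth)
#' fit <- fit_spectrum(sp, fit_options(n_starts = 1))
#' fit$params
#' @export
fit_spectrum <- function(spectrum, options = fit_options()) {
  validate_spectrum(spectrum)
  free <- c("eps_inf", "delta_eps", "tau_ps", "alpha", "sigma_dc")
  fixed <- list()
  if (options$freeze_jonscher) {
    fixed <- list(jonscher_A = 0, jonscher_n = 0.5)
  } else {
    free <- c(free, "jonscher_A", "jonscher_n")
  }
  if (!is.null(options$fix)) {
    free <- setdiff(free, names(options$fix))
    fixed <- c(fixed, as.list(options$fix))
    if (!length(free)) stop("fit_spectrum: no free parameters left", call. = FALSE)
  }
  lower <- options$lower[free]
  upper <- options$upper[free]

  guess <- tryCatch(initial_guess(spectrum, options),
                    error = function(e) NULL)
  if (is.null(guess)) {
    mid <- cc_parameters()
    guess <- mid
  }
  start0 <- clip_to_bounds(params_to_vector(guess, free), lower, upper)

  # start 1: data-driven guess; next: best band-edge candidates from a
  # coarse (alpha, tau) grid, ranked by objective; remaining: seeded +-30%
  # perturbations of the guess
  starts <- list(start0)
  if (options$n_starts > 1) {
    cands <- tryCatch(candidate_starts(spectrum, options, free),
                      error = function(e) list())
    if (length(cands)) {
      objs <- vapply(cands, function(v)
        fit_objective(vector_to_params(v, fixed), spectrum, options),
        numeric(1))
      cands <- cands[order(objs)]
      starts <- c(starts, cands[seq_len(min(length(cands),
                                            options$n_starts - 1))])
    }
    n_left <- options$n_starts - length(starts)
    if (n_left > 0) {
      perturbed <- with_seed(options$seed, {
        lapply(seq_len(n_left), function(i) {
          fac <- stats::runif(length(start0), 0.7, 1.3)
          clip_to_bounds(start0 * fac, lower, upper)
        })
      })
      starts <- c(starts, perturbed)
    }
  }

  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = s,
        lower = lower, upper = upper,
        fn = function(par) fit_residuals(vector_to_params(par, fixed),
                                         spectrum, options),
        control = minpack.lm::nls.lm.control(
          ftol = options$ftol, maxfev = options$max_eval, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    obj <- res$deviance
    conv <- res$info %in% 1:4
    any_converged <- any_converged || conv
    if (is.null(best) || obj < best$deviance) best <- res
  }

  # bound-escape polish: bounded LM can converge with a parameter pinned
  # at a bound while a better interior optimum exists; restart from the
  # best point with pinned parameters pulled inside
  if (!is.null(best) && best$deviance > 1e-8) {
    for (pass in 1:2) {
      par <- best$par
      at_bound <- (par - lower) < 1e-8 * (upper - lower) |
                  (upper - par) < 1e-8 * (upper - lower)
      if (!any(at_bound)) break
      par[at_bound] <- lower[at_bound] + 0.5 * (upper - lower)[at_bound]
      res <- tryCatch(
        minpack.lm::nls.lm(
          par = par, lower = lower, upper = upper,
          fn = function(par) fit_residuals(vector_to_params(par, fixed),
                                           spectrum, options),
          control = minpack.lm::nls.lm.control(
            ftol = options$ftol, maxfev = options$max_eval, maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(res) && res$deviance < best$deviance) best <- res else break
    }
  }

  n_pts <- length(spectrum$frequency_ghz)
  if (is.null(best)) {
    return(structure(list(params = guess, residual_rms = NA_real_,
                          objective = NA_real_, n_points = n_pts,
                          converged = FALSE,
                          n_starts_used = length(starts),
                          options_echo = options),
                     class = "fit_result"))
  }
  params <- vector_to_params(best$par, fixed)
  structure(list(params = params,
                 residual_rms = sqrt(best$deviance / (2 * n_pts)),
                 objective = best$deviance,
                 n_points = n_pts,
                 converged = any_converged,
                 n_starts_used = length(starts),
                 options_echo = options),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: converged=%s, rms=%.3g (%d points, %d starts)\n",
              x$converged, x$residual_rms, x$n_points, x$n_starts_used))
  print(x$params)
  invisible(x)
}

#' Replicate standard deviation of fitted parameters
#'
#' Each milk sample is measured several times (at least three in routine
#' practice); this reports the sample SD (n - 1 denominator) of every model
#' parameter across the replicate fits.
#'
#' @param fits list of `fit_result` objects (or of [cc_parameters()]),
#'   length >= 2.
#' @return named numeric vector of per-parameter SDs.
#' @export
replicate_parameter_sd <- function(fits) {
  if (length(fits) < 2)
    stop("replicate_parameter_sd: need at least 2 replicate fits", call. = FALSE)
  rows <- lapply(fits, function(f) {
    p <- if (inherits(f, "fit_result")) f$params else f
    unlist(p[cc_parameter_names()])
  })
  mat <- do.call(rbind, rows)
  apply(mat, 2, stats::sd)
}
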