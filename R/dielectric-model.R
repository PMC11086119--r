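#' lactowave: dielectric pregnancy monitoring of bovine milk
#'
#' Tools to simulate and analyse microwave dielectric spectra (0.5--40 GHz)
#' of raw bovine milk for non-invasive pregnancy monitoring in dairy cows.
#' The permittivity model is a Cole--Cole relaxation of bulk milk water plus
#' a dc-conductivity term and a Jonscher power-law tail.  On top of the
#' model kernel the package provides bounded complex nonlinear
#' least-squares fitting, a synthetic longitudinal cohort generator, a
#' staged variability-reduction analysis, Pearson-correlation and PCA
#' summaries of the fitted parameters, and a self-normalizing neural
#' network classifier of pregnancy status.
#'
#' @keywords internal
"_PACKAGE"

# Vacuum permittivity in F/m.  The module works with the rounded value used
# throughout microwave dielectrics of fluids; all unit conversions funnel
# through angular_frequency().
EPS0 <- 8.85e-12

#' Angular frequency from a frequency in GHz
#'
#' Single point of unit conversion: frequencies are stored in GHz
#' everywhere, relaxation times in ps, conductivity in S/m.
#'
#' @param freq_ghz numeric vector of frequencies in GHz.
#' @return angular frequency omega = 2*pi*f in rad/s.
#' @export
angular_frequency <- function(freq_ghz) 2 * pi * freq_ghz * 1e9

default_frequency_grid <- function(n = 201L, fmin = 0.5, fmax = 40) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Cole--Cole model parameters
#'
#' Parameter vector of the milk permittivity model
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon}{1 + (i\omega\tau)^\alpha} +
#'   \frac{\sigma_{dc}}{i\omega\varepsilon_0} + A (i\omega)^{n-1}}
#' with the loss reported as \eqn{\varepsilon'' = -\mathrm{Im}\,\varepsilon^*}
#' so that both the relaxation and the conductivity losses are positive.
#'
#' @param eps_inf high-frequency permittivity limit (dimensionless, >= 1).
#' @param delta_eps dielectric strength of the bulk-water relaxation (> 0).
#' @param tau_ps relaxation time in picoseconds (> 0).
#' @param alpha symmetric-broadening exponent; `alpha = 1` is the Debye
#'   limit, values below 1 broaden and lower the loss peak (0 < alpha <= 1).
#' @param sigma_dc dc ionic conductivity in S/m (>= 0).
#' @param jonscher_A amplitude of the Jonscher tail `A (i omega)^(n-1)`
#'   (>= 0; 0 disables the term).
#' @param jonscher_n Jonscher exponent, 0 < n < 1.
#' @return an object of class `cc_parameters` (a validated named list).
#' @examples
#' cc_parameters(eps_inf = 5, delta_eps = 70, tau_ps = 8)
#' @export
cc_parameters <- function(eps_inf = 5.5, delta_eps = 68, tau_ps = 9,
                          alpha = 0.985, sigma_dc = 0.9,
                          jonscher_A = 0, jonscher_n = 0.5) {
  p <- list(eps_inf = as.numeric(eps_inf), delta_eps = as.numeric(delta_eps),
            tau_ps = as.numeric(tau_ps), alpha = as.numeric(alpha),
            sigma_dc = as.numeric(sigma_dc), jonscher_A = as.numeric(jonscher_A),
            jonscher_n = as.numeric(jonscher_n))
  class(p) <- "cc_parameters"
  validate_cc_parameters(p)
  p
}

validate_cc_parameters <- function(p) {
  stopifnot(is.list(p))
  vals <- unlist(p[cc_parameter_names()])
  if (any(!is.finite(vals)))
    stop("cc_parameters: all parameters must be finite", call. = FALSE)
  if (p$delta_eps <= 0) stop("cc_parameters: delta_eps must be > 0", call. = FALSE)
  if (p$tau_ps <= 0) stop("cc_parameters: tau_ps must be > 0", call. = FALSE)
  if (p$alpha <= 0 || p$alpha > 1)
    stop("cc_parameters: alpha must lie in (0, 1]", call. = FALSE)
  if (p$sigma_dc < 0) stop("cc_parameters: sigma_dc must be >= 0", call. = FALSE)
  if (p$jonscher_A < 0) stop("cc_parameters: jonscher_A must be >= 0", call. = FALSE)
  if (p$jonscher_A > 0 && (p$jonscher_n <= 0 || p$jonscher_n >= 1))
    stop("cc_parameters: jonscher_n must lie in (0, 1)", call. = FALSE)
  if (p$eps_inf < 1) stop("cc_parameters: eps_inf must be >= 1", call. = FALSE)
  invisible(p)
}

cc_parameter_names <- function() {
  c("eps_inf", "delta_eps", "tau_ps", "alpha", "sigma_dc",
    "jonscher_A", "jonscher_n")
}

#' @export
print.cc_parameters <- function(x, ...) {
  cat("Cole-Cole model parameters\n")
  cat(sprintf("  eps_inf   = %.4g\n  delta_eps = %.4g\n  tau       = %.4g ps\n",
              x$eps_inf, x$delta_eps, x$tau_ps))
  cat(sprintf("  alpha     = %.4g\n  sigma_dc  = %.4g S/m\n", x$alpha, x$sigma_dc))
  if (x$jonscher_A > 0)
    cat(sprintf("  Jonscher  : A = %.4g, n = %.4g\n", x$jonscher_A, x$jonscher_n))
  invisible(x)
}

#' Construct a permittivity spectrum
#'
#' A spectrum couples a strictly increasing frequency grid (GHz) with the
#' real part `eps_real` and the (non-negative) loss `eps_imag` of the
#' complex permittivity, plus free-form measurement metadata.
#'
#' @param frequency_ghz strictly increasing frequencies in GHz, length >= 8.
#' @param eps_real dielectric constant per frequency; > 1 for physical
#'   milk/water spectra.
#' @param eps_imag dielectric loss per frequency, >= 0.
#' @param meta named list of metadata (sample id, replicate, temperature...).
#' @param validate set to `FALSE` to skip physicality checks (used
#'   internally for noisy intermediates).
#' @return an object of class `milk_spectrum`.
#' @export
milk_spectrum <- function(frequency_ghz, eps_real, eps_imag, meta = list(),
                          validate = TRUE) {
  s <- list(frequency_ghz = as.numeric(frequency_ghz),
            eps_real = as.numeric(eps_real),
            eps_imag = as.numeric(eps_imag),
            meta = meta)
  class(s) <- "milk_spectrum"
  if (validate) validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  n <- length(s$frequency_ghz)
  if (n < 8 || length(s$eps_real) != n || length(s$eps_imag) != n)
    stop("milk_spectrum: frequency, eps_real, eps_imag must have equal length >= 8",
         call. = FALSE)
  if (any(!is.finite(s$frequency_ghz)) || any(!is.finite(s$eps_real)) ||
      any(!is.finite(s$eps_imag)))
    stop("milk_spectrum: all values must be finite", call. = FALSE)
  if (any(diff(s$frequency_ghz) <= 0))
    stop("milk_spectrum: frequencies must be strictly increasing", call. = FALSE)
  if (any(s$frequency_ghz <= 0))
    stop("milk_spectrum: frequencies must be positive", call. = FALSE)
  if (any(s$eps_real <= 1))
    stop("milk_spectrum: eps_real must exceed 1 for physical spectra", call. = FALSE)
  if (any(s$eps_imag < 0))
    stop("milk_spectrum: eps_imag must be non-negative", call. = FALSE)
  invisible(s)
}

#' @export
print.milk_spectrum <- function(x, ...) {
  f <- x$frequency_ghz
  cat(sprintf("milk_spectrum: %d points, %.3g-%.3g GHz\n", length(f), min(f), max(f)))
  if (length(x$meta)) {
    kv <- paste(names(x$meta), unlist(lapply(x$meta, format)), sep = "=")
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.milk_spectrum <- function(x, ...) {
  data.frame(frequency_ghz = x$frequency_ghz, eps_real = x$eps_real,
             eps_imag = x$eps_imag)
}

# Complex permittivity, term by term on the principal branch:
# (i w tau)^alpha = (w tau)^alpha exp(i alpha pi / 2).
complex_permittivity <- function(params, freq_ghz) {
  w <- angular_frequency(freq_ghz)
  tau <- params$tau_ps * 1e-12
  eps <- params$eps_inf + params$delta_eps / (1 + (1i * w * tau)^params$alpha)
  if (params$sigma_dc > 0) eps <- eps + params$sigma_dc / (1i * w * EPS0)
  if (params$jonscher_A > 0)
    eps <- eps + params$jonscher_A * (1i * w)^(params$jonscher_n - 1)
  eps
}

#' Evaluate the permittivity model on a frequency grid
#'
#' Computes the Cole--Cole + dc-conductivity + Jonscher model exactly, with
#' \eqn{\omega = 2\pi f} and the principal complex branch, and returns the
#' physics convention `eps_real = Re`, `eps_imag = -Im` so losses are
#' positive.
#'
#' @param params a [cc_parameters()] object.
#' @param freq_ghz positive frequencies in GHz (any length >= 8 for a valid
#'   spectrum object).
#' @param meta metadata list forwarded to the returned spectrum.
#' @return a [milk_spectrum()].
#' @examples
#' sp <- evaluate_permittivity(cc_parameters(eps_inf = 5, delta_eps = 70,
#'                                           tau_ps = 8, alpha = 1,
#'                                           sigma_dc = 0))
#' head(as.data.frame(sp))
#' @export
evaluate_permittivity <- function(params, freq_ghz = default_frequency_grid(),
                                  meta = list()) {
  validate_cc_parameters(params)
  if (any(freq_ghz <= 0) || any(!is.finite(freq_ghz)))
    stop("evaluate_permittivity: frequencies must be positive and finite",
         call. = FALSE)
  eps <- complex_permittivity(params, freq_ghz)
  milk_spectrum(freq_ghz, Re(eps), -Im(eps), meta = meta)
}

#' Relaxation time from the loss-peak frequency
#'
#' For a Debye-like relaxation the loss peak sits at
#' \eqn{f_{max} = 1/(2\pi\tau)}; this inverts that identity.
#'
#' @param f_max_ghz loss-peak frequency in GHz, > 0.
#' @return relaxation time tau in ps.
#' @examples
#' relaxation_time_from_peak(19.894) # ~8 ps
#' @export
relaxation_time_from_peak <- function(f_max_ghz) {
  if (any(f_max_ghz <= 0)) stop("f_max must be positive", call. = FALSE)
  1 / angular_frequency(f_max_ghz) * 1e12
}

#' Split the dielectric loss into its model components
#'
#' Diagnostic view of the loss: the Cole--Cole relaxation, dc-conductivity
#' tail and Jonscher tail contributions to `eps_imag`, which sum to the
#' full model loss at every frequency.
#'
#' @inheritParams evaluate_permittivity
#' @return data.frame with `frequency_ghz`, `relaxation`, `conductivity`,
#'   `jonscher`, `total`.
#' @export
decompose_loss <- function(params, freq_ghz = default_frequency_grid()) {
  validate_cc_parameters(params)
  if (any(freq_ghz <= 0)) stop("frequencies must be positive", call. = FALSE)
  w <- angular_frequency(freq_ghz)
  tau <- params$tau_ps * 1e-12
  relax <- -Im(params$delta_eps / (1 + (1i * w * tau)^params$alpha))
  cond <- params$sigma_dc / (w * EPS0)
  jon <- if (params$jonscher_A > 0)
    -Im(params$jonscher_A * (1i * w)^(params$jonscher_n - 1)) else rep(0, length(w))
  data.frame(frequency_ghz = freq_ghz, relaxation = relax, conductivity = cond,
             jonscher = jon, total = relax + cond + jon)
}
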