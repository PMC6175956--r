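#' 2D FCS autocorrelation model with triplet term
#'
#' G(t) = 1 + (1 + A exp(-t/tau_c)) (1/N_p) (1 / (1 + (t/tau_D)^alpha)):
#' anomalous 2D diffusion of N_p particles with diffusion time tau_D,
#' anomalous exponent alpha and a fixed triplet contribution (amplitude A,
#' correlation time tau_c).
#'
#' @param t Lag times (s, >= 0).
#' @param n_p Mean particle number in the confocal spot (> 0).
#' @param tau_d Diffusion time (s, > 0).
#' @param alpha Anomalous exponent.
#' @param a Triplet amplitude (default 0.05).
#' @param tau_c Triplet correlation time (s, default 5e-6).
#' @return Autocorrelation values.
#' @export
fcs_model <- function(t, n_p, tau_d, alpha = 1, a = 0.05, tau_c = 5e-6) {
  if (n_p <= 0 || tau_d <= 0) stop("n_p and tau_d must be positive")
  1 + (1 + a * exp(-t / tau_c)) * (1 / n_p) * (1 / (1 + (t / tau_d)^alpha))
}

#' Fit the FCS autocorrelation model to a trace
#'
#' Least-squares fit of N_p, tau_D and alpha with the triplet parameters A
#' and tau_c held fixed and alpha bounded (default [0.9, 1]). The returned
#' fit echoes the fixed parameters bit-exactly.
#'
#' @param lag_s Lag times (s, strictly increasing).
#' @param g Autocorrelation values.
#' @param a,tau_c Fixed triplet parameters.
#' @param alpha_bounds Lower/upper bounds for alpha.
#' @return An object of class `fcs_fit` with `n_p`, `tau_d`, `alpha`, the
#'   fixed `a`, `tau_c`, `residual_norm` and `converged`.
#' @export
fit_fcs <- function(lag_s, g, a = 0.05, tau_c = 5e-6,
                    alpha_bounds = c(0.9, 1.0)) {
  if (any(diff(lag_s) <= 0) || any(lag_s <= 0))
    stop("lag times must be positive and strictly increasing")
  amp <- max(g) - 1
  if (amp <= 0) stop("trace has no correlation amplitude")
  n_p0 <- (1 + a) / amp
  tau0 <- lag_s[which.min(abs((g - 1) - amp / 2))]
  dat <- data.frame(t = lag_s, g = g)
  fit <- stats::nls(
    g ~ 1 + (1 + a * exp(-t / tau_c)) * (1 / n_p) * (1 / (1 + (t / tau_d)^alpha)),
    data = dat,
    start = list(n_p = n_p0, tau_d = tau0, alpha = 0.95),
    algorithm = "port",
    lower = c(n_p = 1e-9, tau_d = min(lag_s) / 10, alpha = alpha_bounds[1]),
    upper = c(n_p = Inf, tau_d = max(lag_s) * 10, alpha = alpha_bounds[2]),
    control = stats::nls.control(maxiter = 500, warnOnly = TRUE))
  cf <- stats::coef(fit)
  flagged <- !fit$convInfo$isConv ||
    cf[["tau_d"]] <= min(lag_s) / 5 || cf[["tau_d"]] >= max(lag_s) * 5
  structure(list(n_p = cf[["n_p"]], tau_d = cf[["tau_d"]],
                 alpha = cf[["alpha"]], a = a, tau_c = tau_c,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = !flagged),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: N_p = %.4g, tau_D = %.4g s, alpha = %.3f (A = %g, tau_c = %g s fixed)%s\n",
              x$n_p, x$tau_d, x$alpha, x$a, x$tau_c,
              if (x$converged) "" else "  [flagged]"))
  invisible(x)
}

#' Hydrodynamic radius from a diffusion time
#'
#' D = w^2 / (4 tau_D) for a calibrated beam waist w, then Stokes-Einstein
#' r_H = k_B T / (6 pi eta D).
#'
#' @param tau_d Diffusion time (s), or an `fcs_fit`.
#' @param beam_waist_nm Confocal beam waist (nm).
#' @param temperature_k Temperature (K, default 295).
#' @param viscosity_pa_s Solvent viscosity (Pa s; default water near 295 K).
#' @return List with `d_nm2_s` and `r_h_nm`.
#' @export
hydrodynamic_radius <- function(tau_d, beam_waist_nm, temperature_k = 295,
                                viscosity_pa_s = 9.54e-4) {
  if (inherits(tau_d, "fcs_fit")) tau_d <- tau_d$tau_d
  if (is.null(beam_waist_nm) || beam_waist_nm <= 0)
    stop("beam waist calibration required")
  if (viscosity_pa_s <= 0 || temperature_k <= 0)
    stop("temperature and viscosity must be positive")
  kb <- 1.380649e-23
  d_nm2_s <- beam_waist_nm^2 / (4 * tau_d)
  d_m2_s <- d_nm2_s * 1e-18
  r_m <- kb * temperature_k / (6 * pi * viscosity_pa_s * d_m2_s)
  list(d_nm2_s = d_nm2_s, r_h_nm = r_m * 1e9)
}

#' Beam-waist calibration from a reference species
#'
#' Given the fitted diffusion time of a species of known diffusion
#' coefficient, w = sqrt(4 D tau_D).
#'
#' @param tau_d_ref Fitted diffusion time of the reference (s).
#' @param d_ref_nm2_s Known diffusion coefficient (nm^2/s).
#' @return Beam waist in nm.
#' @export
calibrate_beam_waist <- function(tau_d_ref, d_ref_nm2_s) {
  if (tau_d_ref <= 0 || d_ref_nm2_s <= 0) stop("inputs must be positive")
  sqrt(4 * d_ref_nm2_s * tau_d_ref)
}
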