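# Forward model of FCS autocorrelation curves: a 3D-Gaussian translational
# diffusion term multiplied by a photophysical blinking term derived from the
# three-state scheme, G(tau) = 1 + G_D(tau) * G_T(tau).

#' Confocal detection geometry for FCS
#'
#' @param omega0 Radial 1/e^2 radius of the detection volume, micrometres.
#' @param S Axial-to-radial ratio `omega_z / omega_0` (dimensionless; fixed to
#'   6.8 in the bundled analyses, from volume calibration).
#' @param N_m Mean number of fluorescent molecules in the detection volume.
#' @param tau_D Characteristic diffusion time in seconds; if omitted it is
#'   derived from `D` via `tau_D = omega0^2 / (4 D)`.
#' @param D Diffusion coefficient in um^2/s (optional).
#' @return A `detection_geometry` object.
#' @export
detection_geometry <- function(omega0 = 0.338, S = 6.8, N_m = 2,
                               tau_D = NULL, D = NULL) {
  if (is.null(tau_D)) {
    if (is.null(D)) rlang::abort("Provide either `tau_D` or `D`.")
    tau_D <- omega0^2 / (4 * D)
  }
  if (S <= 0 || N_m <= 0 || tau_D <= 0) {
    rlang::abort("`S`, `N_m`, and `tau_D` must be > 0.")
  }
  structure(list(omega0 = omega0, S = S, N_m = N_m, tau_D = tau_D),
            class = "detection_geometry")
}

new_fcs_curve <- function(tau, G, meta, sd = NULL) {
  out <- tibble::tibble(tau = tau, G = G)
  if (!is.null(sd)) out$sd <- sd
  attr(out, "meta") <- meta
  class(out) <- c("fcs_curve", class(out))
  out
}

#' Translational diffusion term of the FCS curve
#'
#' `G_D(tau) = (1/N_m) (1 + tau/tau_D)^-1 (1 + tau/(S^2 tau_D))^-1/2` for
#' free 3D diffusion through a Gaussian detection volume.
#'
#' @param geometry A [detection_geometry()].
#' @param tau Lag times in seconds, >= 0.
#' @return `G_D(tau)`, zero-baseline (decays to 0).
#' @export
fcs_diffusion <- function(geometry, tau) {
  if (any(tau < 0)) rlang::abort("`tau` must be >= 0.")
  x <- tau / geometry$tau_D
  (1 / geometry$N_m) / (1 + x) / sqrt(1 + x / geometry$S^2)
}

#' Two-state blinking term
#'
#' Closed-form blinking factor for a fluorophore exchanging between the
#' emissive N and one dark photoisomer:
#' `G_T = (1 - P1 + P1 * exp(-tau/tau_iso)) / (1 - P1)`, where `P1` is the
#' stationary dark fraction and `tau_iso` the isomerization relaxation time.
#'
#' @param P1_frac Stationary dark-state fraction, in `[0, 1)`.
#' @param tau_iso Relaxation time in seconds, > 0.
#' @param tau Lag times, seconds.
#' @return `G_T(tau)`, normalized to 1 at infinite lag.
#' @export
fcs_blinking_two_state <- function(P1_frac, tau_iso, tau) {
  if (P1_frac < 0 || P1_frac >= 1) {
    rlang::abort("`P1_frac` must be in [0, 1); at 1 the normalization is singular.")
  }
  if (tau_iso <= 0) rlang::abort("`tau_iso` must be > 0.")
  (1 - P1_frac + P1_frac * exp(-tau / tau_iso)) / (1 - P1_frac)
}

#' Three-state brightness-weighted blinking term
#'
#' General blinking factor of the N <-> P1 <-> P2 scheme with brightness
#' vector `q = (1, 0, Q)`: with stationary populations `p` and propagator
#' `P(tau) = exp(M tau)` of the generator,
#' `G_T(tau) = q' P(tau) (p * q) / (q . p)^2`,
#' evaluated through the eigen-expansion of the generator. Uniform excitation
#' across the detection volume is assumed. `G_T` decays monotonically to 1;
#' `G_T(0) = <q^2> / <q>^2` under the stationary distribution.
#'
#' @param params A [photo_params()].
#' @param wavelength,irradiance Excitation conditions.
#' @param band Emission band label selecting Q (default `"B"`).
#' @param tau Lag times, seconds.
#' @param saturation Passed to [effective_rates()].
#' @return `G_T(tau)`.
#' @export
fcs_blinking_three_state <- function(params, wavelength, irradiance,
                                     band = "B", tau, saturation = FALSE) {
  rates <- effective_rates(params, wavelength, irradiance, saturation)
  Q <- q_for_band(params, band)
  blinking_from_rates(rates, Q, tau)
}

# Internal: blinking term from a rate_set and brightness Q.
blinking_from_rates <- function(rates, Q, tau) {
  q <- c(1, 0, Q)
  if (all(unlist(rates) == 0)) return(rep(1, length(tau)))
  p <- steady_state_vec(rates$k_iso1_eff, rates$k_biso1_eff,
                        rates$k_iso2_eff, rates$k_biso2_eff)
  mean_q <- sum(q * p)
  if (mean_q <= 0) rlang::abort("All emissive states are unpopulated or dark.")
  m <- rate_matrix(rates)
  sol <- kin_solve(m, p * q)
  num <- if (!is.null(sol)) {
    a <- as.numeric(crossprod(q, sol$V)) * sol$coef
    as.numeric(exp(outer(tau, sol$lambda)) %*% a)
  } else {
    vapply(tau, function(ti) {
      pt <- kin_populations_ode(m, p * q / sum(p * q), ti, rtol = 1e-11)
      sum(q * pt) * sum(p * q)
    }, numeric(1))
  }
  num / mean_q^2
}

#' Simulate a full FCS curve
#'
#' `G(tau) = 1 + G_D(tau) * G_T(tau)`: diffusion term times blinking term,
#' with the long-lag baseline at 1 (the baseline convention is recorded in the
#' curve metadata; readers accept baseline-0 data as well).
#'
#' @param params A [photo_params()].
#' @param geometry A [detection_geometry()].
#' @param protocol An [excitation_protocol()] (CW: only wavelength, irradiance
#'   and band are used).
#' @param tau_grid Increasing lag times in seconds.
#' @param saturation Passed to [effective_rates()].
#' @return An `fcs_curve` tibble with columns `tau` and `G`.
#' @export
fcs_curve <- function(params, geometry, protocol,
                      tau_grid = log_grid(1e-8, 1, 200),
                      saturation = FALSE) {
  gd <- fcs_diffusion(geometry, tau_grid)
  gt <- fcs_blinking_three_state(params, protocol$wavelength,
                                 protocol$irradiance, protocol$band,
                                 tau_grid, saturation)
  new_fcs_curve(tau_grid, 1 + gd * gt, meta = list(
    type = "fcs", wavelength = protocol$wavelength,
    irradiance = protocol$irradiance, band = protocol$band,
    baseline = 1, S = geometry$S, N_m = geometry$N_m,
    tau_D = geometry$tau_D, omega0 = geometry$omega0))
}
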