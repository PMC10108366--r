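# Forward model of TRAST (transient-state) pulse-train experiments.
#
# A TRAST curve is the time-averaged fluorescence of a rectangular excitation
# pulse of duration w, normalized at a short reference duration w0, plotted
# against w. Build-up of dark (P1) or differently bright (P2) photoisomers on
# the microsecond-to-millisecond scale makes the curve deviate from 1.

new_trast_curve <- function(w, value, meta) {
  out <- tibble::tibble(w = w, value = value)
  attr(out, "meta") <- meta
  class(out) <- c("trast_curve", class(out))
  out
}

curve_meta <- function(x) attr(x, "meta")

#' Relative emissive signal along a state trajectory
#'
#' The detected fluorescence is proportional to `p_N(t) + Q * p_P2(t)`: N and
#' P2 are the emissive states and P1 is dark. With all molecules in N at t = 0
#' the signal is normalized to 1, so collection efficiency, concentration, and
#' absolute brightness cancel. Values above 1 (possible when `Q > 1` and P2
#' builds up) correspond to inverse relaxation: fluorescence that grows after
#' the onset of excitation.
#'
#' @param trajectory A `state_trajectory` tibble from [populations_vs_time()].
#' @param Q Relative detected brightness of P2 versus N, >= 0.
#' @return A tibble with columns `time` and `F` (relative fluorescence).
#' @export
emissive_signal <- function(trajectory, Q) {
  if (Q < 0) rlang::abort("`Q` must be >= 0.")
  tibble::tibble(time = trajectory$time,
                 F = trajectory$p_N + Q * trajectory$p_P2)
}

#' Mean fluorescence over one rectangular excitation pulse
#'
#' Computes `(1/w) * integral_0^w F(t) dt` with `F(t) = p_N(t) + Q p_P2(t)`,
#' starting from all molecules in N. The integral is evaluated in closed form
#' from the eigen-solution of the generator (analytic integrals of
#' exponentials); when the spectrum is degenerate the ODE path with numerical
#' quadrature is used instead.
#'
#' @param params A [photo_params()].
#' @param protocol An [excitation_protocol()].
#' @param w Pulse duration(s) in seconds, > 0.
#' @param saturation Passed to [effective_rates()].
#' @return Mean relative fluorescence, one value per element of `w`.
#' @export
pulse_average <- function(params, protocol, w, saturation = FALSE) {
  if (any(w <= 0)) rlang::abort("`w` must be > 0.")
  rates <- effective_rates(params, protocol$wavelength, protocol$irradiance,
                           saturation)
  Q <- q_for_band(params, protocol$band)
  m <- rate_matrix(rates)
  kin_mean_signal(m, c(1, 0, 0), c(1, 0, Q), w)
}

#' Simulate a TRAST curve
#'
#' Evaluates the pulse-averaged fluorescence on a grid of pulse durations and
#' normalizes by the value at the reference duration `w0`. Identical pulses
#' are assumed: the duty cycle must be low enough that molecules fully return
#' to N between pulses (checked against the thermal recovery time; a warning
#' is issued otherwise). An explicit pulse-by-pulse train simulator for
#' validating this assumption lives in the synthetic-data generators.
#'
#' @param params A [photo_params()].
#' @param protocol An [excitation_protocol()]; its `w0` is the normalization
#'   pulse duration.
#' @param w_grid Increasing pulse durations in seconds, all >= `w0` is not
#'   required but `w0` must not exceed `min(w_grid)`.
#' @param saturation Passed to [effective_rates()].
#' @return A `trast_curve` tibble with columns `w` and `value`, metadata in
#'   `attr(, "meta")`.
#' @export
trast_curve <- function(params, protocol, w_grid = log_grid(1e-7, 1e-2, 30),
                        saturation = FALSE) {
  w0 <- protocol$w0
  if (w0 > min(w_grid) * (1 + 1e-9)) rlang::abort("`w0` must be <= min(w_grid).")
  check_recovery(params, protocol, max(w_grid))
  s <- pulse_average(params, protocol, c(w0, w_grid), saturation)
  new_trast_curve(w_grid, s[-1] / s[1], meta = list(
    type = "trast", wavelength = protocol$wavelength,
    irradiance = protocol$irradiance, band = protocol$band,
    duty_cycle = protocol$duty_cycle, w0 = w0))
}

check_recovery <- function(params, protocol, w_max) {
  if (params$k_biso1_th > 0) {
    off <- (1 / protocol$duty_cycle - 1) * w_max
    if (off < 10 / params$k_biso1_th) {
      rlang::warn(paste0(
        "Duty cycle may be too high for full thermal recovery between pulses",
        " (off-time < 10 thermal recovery times)."))
    }
  }
  invisible(NULL)
}

#' Logarithmic pulse-duration grid
#'
#' Pulse durations in TRAST acquisitions are spaced logarithmically, typically
#' between 100 ns and 1--10 ms.
#'
#' @param from,to Range in seconds.
#' @param n Number of points.
#' @export
log_grid <- function(from = 1e-7, to = 1e-2, n = 30) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Beam profile for ROI-averaged TRAST curves
#'
#' @param kind `"uniform"` or `"gaussian"`.
#' @param waist 1/e^2 radius of the Gaussian beam, micrometres.
#' @param roi_radius Radius of the analysed region of interest, micrometres.
#' @export
beam_profile <- function(kind = c("uniform", "gaussian"),
                         waist = 15, roi_radius = 15) {
  kind <- match.arg(kind)
  if (waist <= 0 || roi_radius <= 0) {
    rlang::abort("`waist` and `roi_radius` must be > 0.")
  }
  structure(list(kind = kind, waist = waist, roi_radius = roi_radius),
            class = "beam_profile")
}

#' TRAST curve averaged over a wide-field beam profile
#'
#' In wide-field acquisitions the irradiance varies across the region of
#' interest. For a Gaussian beam, `I(r) = I_peak * exp(-2 r^2 / waist^2)`, the
#' unnormalized pulse-averaged signal is integrated over the ROI disc by
#' fixed-order Gauss-Legendre radial quadrature and normalized at `w0`
#' afterwards. A uniform profile reduces exactly to [trast_curve()].
#'
#' @inheritParams trast_curve
#' @param profile A [beam_profile()].
#' @param n_nodes Radial quadrature order (default 32).
#' @return A `trast_curve` tibble.
#' @export
beam_averaged_trast <- function(params, protocol, profile,
                                w_grid = log_grid(1e-7, 1e-2, 30),
                                n_nodes = 32, saturation = FALSE) {
  if (profile$kind == "uniform") {
    return(trast_curve(params, protocol, w_grid, saturation))
  }
  w0 <- protocol$w0
  if (w0 > min(w_grid) * (1 + 1e-9)) rlang::abort("`w0` must be <= min(w_grid).")
  gl <- pracma::gaussLegendre(n_nodes, 0, profile$roi_radius)
  ww <- c(w0, w_grid)
  acc <- numeric(length(ww))
  wsum <- 0
  for (i in seq_len(n_nodes)) {
    r <- gl$x[i]
    irr <- protocol$irradiance * exp(-2 * r^2 / profile$waist^2)
    p_r <- protocol
    p_r$irradiance <- irr
    # weight by the local excitation rate: brighter annuli contribute more
    wgt <- gl$w[i] * r * irr
    acc <- acc + wgt * pulse_average(params, p_r, ww, saturation)
    wsum <- wsum + wgt
  }
  s <- acc / wsum
  new_trast_curve(w_grid, s[-1] / s[1], meta = list(
    type = "trast", wavelength = protocol$wavelength,
    irradiance = protocol$irradiance, band = protocol$band,
    duty_cycle = protocol$duty_cycle, w0 = w0,
    beam = profile$kind, waist = profile$waist,
    roi_radius = profile$roi_radius))
}
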