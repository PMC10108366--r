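# Spectral-TRAST: emission-spectrum stacks recorded with pulse trains of
# different pulse durations w. Build-up of the red-emissive photoisomer P2
# with longer w redshifts the spectra; subtracting normalized spectra exposes
# the photoisomer emission, and integrating bands versus w yields TRAST
# curves per emission window.

new_spectral_stack <- function(df, normalization = "none", meta = list()) {
  attr(df, "meta") <- utils::modifyList(list(normalization = normalization),
                                        meta)
  class(df) <- c("spectral_stack", setdiff(class(df), "spectral_stack"))
  df
}

#' Parametric asymmetric emission basis spectrum
#'
#' A log-normal lineshape in wavelength: unit peak at `peak` nm, dimensionless
#' log-width `width`, and `skew` stretching the red flank relative to the blue
#' one (`skew = 1` is symmetric in log-wavelength). Used to synthesize
#' two-component emission stacks when measured state spectra are not at hand.
#'
#' @param peak Peak wavelength, nm.
#' @param width Log-wavelength standard width (typical 0.02-0.05).
#' @param skew Red-to-blue half-width ratio, > 0.
#' @return A function of wavelength (nm) returning intensities with max 1.
#' @export
emission_basis <- function(peak, width = 0.03, skew = 1.3) {
  if (peak <= 0 || width <= 0 || skew <= 0) {
    rlang::abort("`peak`, `width`, `skew` must be > 0.")
  }
  function(wavelength) {
    z <- log(wavelength / peak)
    s <- ifelse(z < 0, width, width * skew)
    exp(-z^2 / (2 * s^2))
  }
}

#' Synthesize an emission-spectrum stack versus pulse duration
#'
#' For each pulse duration w the spectrum is the population-weighted mixture
#' `S(lambda, w) = s_N(lambda) <p_N>_w + Q_spec s_P2(lambda) <p_P2>_w`, where
#' `<.>_w` denotes the pulse average over a rectangular pulse of duration w
#' and `Q_spec` is the wavelength-integrated brightness of P2 relative to N.
#'
#' @param params A [photo_params()].
#' @param protocol An [excitation_protocol()].
#' @param basis_N,basis_P2 Unit-peak basis spectra (functions of wavelength,
#'   e.g. from [emission_basis()]).
#' @param Q_spec Wavelength-integrated brightness ratio of P2 versus N, >= 0.
#' @param wavelengths Emission wavelength grid, nm, increasing.
#' @param w_grid Pulse durations, seconds, increasing.
#' @param saturation Passed to [effective_rates()].
#' @return A `spectral_stack` tibble with columns `wavelength`, `w`,
#'   `intensity`.
#' @export
simulate_spectral_stack <- function(params, protocol,
                                    basis_N = emission_basis(790),
                                    basis_P2 = emission_basis(820),
                                    Q_spec = 1,
                                    wavelengths = seq(700, 900, by = 2),
                                    w_grid = log_grid(1e-7, 1e-3, 12),
                                    saturation = FALSE) {
  if (Q_spec < 0) rlang::abort("`Q_spec` must be >= 0.")
  rates <- effective_rates(params, protocol$wavelength, protocol$irradiance,
                           saturation)
  m <- rate_matrix(rates)
  pN_w <- kin_mean_signal(m, c(1, 0, 0), c(1, 0, 0), w_grid)
  pP2_w <- kin_mean_signal(m, c(1, 0, 0), c(0, 0, 1), w_grid)
  sN <- basis_N(wavelengths)
  sP2 <- basis_P2(wavelengths)
  df <- tidyr::expand_grid(w = w_grid, wavelength = wavelengths)
  df$intensity <- rep(pN_w, each = length(wavelengths)) * rep(sN, length(w_grid)) +
    Q_spec * rep(pP2_w, each = length(wavelengths)) * rep(sP2, length(w_grid))
  new_spectral_stack(df[, c("wavelength", "w", "intensity")],
                     normalization = "none",
                     meta = list(wavelength_exc = protocol$wavelength,
                                 irradiance = protocol$irradiance,
                                 duty_cycle = protocol$duty_cycle))
}

#' Normalize a spectral stack
#'
#' `mode = "peak"` scales each pulse-duration column to unit maximum
#' (shape-only comparison across w); `mode = "ref_w"` scales the whole stack
#' by the maximum of the spectrum at `w_ref` (preserving relative intensities
#' across w). Both modes are idempotent.
#'
#' @param stack A `spectral_stack`.
#' @param mode `"peak"` or `"ref_w"`.
#' @param w_ref Reference pulse duration for `mode = "ref_w"`.
#' @return A normalized `spectral_stack`.
#' @export
normalize_stack <- function(stack, mode = c("peak", "ref_w"), w_ref = NULL) {
  mode <- match.arg(mode)
  meta <- attr(stack, "meta")
  df <- tibble::as_tibble(stack)
  if (mode == "peak") {
    df <- df |>
      dplyr::group_by(.data$w) |>
      dplyr::mutate(intensity = {
        mx <- max(.data$intensity)
        if (mx <= 0) rlang::abort("All-zero spectrum cannot be normalized.")
        .data$intensity / mx
      }) |>
      dplyr::ungroup()
    norm <- "peak"
  } else {
    if (is.null(w_ref)) rlang::abort("`w_ref` is required for mode 'ref_w'.")
    wv <- stack_w_lookup(df, w_ref)
    mx <- max(df$intensity[df$w == wv])
    if (mx <= 0) rlang::abort("All-zero reference spectrum cannot be normalized.")
    df$intensity <- df$intensity / mx
    norm <- "ref_w"
    meta$w_ref <- wv
  }
  meta$normalization <- NULL
  new_spectral_stack(df, normalization = norm, meta = meta)
}

stack_w_lookup <- function(df, w) {
  ws <- unique(df$w)
  hit <- which(abs(ws - w) <= 1e-9 * pmax(ws, w))
  if (length(hit) == 0) {
    rlang::abort(sprintf("Pulse duration %g s is not in the stack.", w))
  }
  ws[hit[1]]
}

#' Photoisomer difference spectrum
#'
#' Subtracts the peak-normalized spectrum at a short pulse duration (pure-N
#' shape) from the one at a long duration, exposing the approximate emission
#' spectrum of the red-emissive photoisomer. The stack is peak-normalized
#' first if it is not already. The difference can be negative near the N peak
#' and is returned unclipped unless `clip = TRUE`.
#'
#' @param stack A `spectral_stack`.
#' @param w_long,w_short Pulse durations present in the stack, seconds.
#' @param clip Clip negative values at 0.
#' @return A tibble with columns `wavelength` and `delta`.
#' @export
difference_spectrum <- function(stack, w_long, w_short, clip = FALSE) {
  if (!identical(attr(stack, "meta")$normalization, "peak")) {
    stack <- normalize_stack(stack, "peak")
  }
  df <- tibble::as_tibble(stack)
  wl <- stack_w_lookup(df, w_long)
  ws <- stack_w_lookup(df, w_short)
  long <- df[df$w == wl, ]
  short <- df[df$w == ws, ]
  delta <- long$intensity - short$intensity[match(long$wavelength,
                                                 short$wavelength)]
  if (clip) delta <- pmax(delta, 0)
  tibble::tibble(wavelength = long$wavelength, delta = delta)
}

#' TRAST curves integrated over emission bands
#'
#' Integrates the stack intensity over one or more wavelength windows
#' (trapezoidal rule), then normalizes each band's signal at the reference
#' pulse duration `w0`. Requires an unnormalized or `ref_w`-normalized stack:
#' per-column peak normalization would erase the very w-dependence TRAST
#' measures.
#'
#' @param stack A `spectral_stack`.
#' @param bands A named list of `c(lo, hi)` wavelength windows in nm.
#' @param w0 Normalization pulse duration (must be in the stack).
#' @return A tibble with columns `band`, `w`, `value`; each band's value is 1
#'   at `w0`.
#' @export
band_integrated_trast <- function(stack, bands, w0) {
  if (identical(attr(stack, "meta")$normalization, "peak")) {
    rlang::abort("Band integration needs an unnormalized or ref_w-normalized stack.")
  }
  df <- tibble::as_tibble(stack)
  w0v <- stack_w_lookup(df, w0)
  rng <- range(df$wavelength)
  purrr::imap_dfr(bands, function(b, label) {
    if (b[1] >= b[2] || b[2] < rng[1] || b[1] > rng[2]) {
      rlang::abort(sprintf("Band [%g, %g] nm is empty within the stack range.",
                           b[1], b[2]))
    }
    band_df <- df |>
      dplyr::filter(.data$wavelength >= b[1], .data$wavelength <= b[2]) |>
      dplyr::group_by(.data$w) |>
      dplyr::summarise(signal = pracma::trapz(.data$wavelength, .data$intensity),
                       .groups = "drop")
    ref <- band_df$signal[band_df$w == w0v]
    tibble::tibble(band = label, w = band_df$w, value = band_df$signal / ref)
  })
}
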