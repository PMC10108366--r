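#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# CODATA 2018 constants
.h_planck <- 6.62607015e-34   # J s
.c_light  <- 2.99792458e8     # m/s
.n_avogadro <- 6.02214076e23  # 1/mol

#' Convert irradiance to photon flux
#'
#' All excitation-driven rates in the kinetic model are products of a cross
#' section (cm^2) and a photon flux (photons cm^-2 s^-1). Irradiance is stored
#' in W/cm^2 and converted here, at a single point of use, via the photon
#' energy h*c/lambda.
#'
#' @param irradiance Irradiance in W/cm^2 (scalar or vector), >= 0.
#' @param wavelength Excitation wavelength in nm, > 0.
#' @return Photon flux in photons cm^-2 s^-1.
#' @examples
#' photon_flux(3900, 638)   # ~1.25e22
#' @export
photon_flux <- function(irradiance, wavelength) {
  if (any(irradiance < 0)) abort("`irradiance` must be >= 0 W/cm^2.")
  if (any(wavelength <= 0)) abort("`wavelength` must be positive (nm).")
  irradiance * (wavelength * 1e-9) / (.h_planck * .c_light)
}

#' Convert a molar extinction coefficient to an absorption cross section
#'
#' sigma = 1000 * ln(10) * epsilon / N_A, with epsilon in L mol^-1 cm^-1 and
#' sigma in cm^2. This is how the peak ground-state excitation cross section
#' of the all-trans state is obtained from a manufacturer-quoted extinction
#' coefficient.
#'
#' @param epsilon Molar (decadic) extinction coefficient, L mol^-1 cm^-1, >= 0.
#' @return Cross section in cm^2.
#' @examples
#' extinction_to_cross_section(240600)  # ~9.2e-16 cm^2
#' @export
extinction_to_cross_section <- function(epsilon) {
  if (any(epsilon < 0)) abort("`epsilon` must be >= 0.")
  1000 * log(10) * epsilon / .n_avogadro
}

#' Photophysical parameter set for a three-state photoisomerization model
#'
#' Bundles the dye-level constants of the kinetic scheme N <-> P1 <-> P2:
#' the excited-state isomerization rate `k_iso1` (N* -> P1), per-wavelength
#' cross sections, thermal back-isomerization rates, excited-state lifetimes,
#' and the relative detected brightness `Q` of P2 versus N per emission band.
#'
#' Cross-section arguments are named numeric vectors keyed by the excitation
#' wavelength in nm (e.g. `c("638" = 1.56e-16)`), so one parameter set can
#' describe measurements at several excitation wavelengths.
#'
#' @param k_iso1 Isomerization rate from the excited singlet of N to P1, s^-1.
#' @param sigma_N Ground-state excitation cross section(s) of N, cm^2, named
#'   by wavelength (nm).
#' @param sigma_biso1 P1 -> N back-isomerization cross section(s), cm^2.
#' @param sigma_iso2 P1 -> P2 isomerization cross section(s), cm^2.
#' @param sigma_biso2 P2 -> P1 back-isomerization cross section(s), cm^2.
#' @param k_biso1_th Thermal P1 -> N rate, s^-1.
#' @param k_biso2_th Thermal P2 -> P1 rate, s^-1.
#' @param tau_f Excited-state lifetime of N in seconds; 1/tau_f comprises all
#'   deactivation from N*, including isomerization, so k10_N = 1/tau_f - k_iso1
#'   must be positive.
#' @param tau_f2 Optional excited-state lifetime of P2, seconds.
#' @param Q_by_band Named numeric vector of relative P2-vs-N brightness per
#'   emission band label (e.g. `c(B = 0, R = 0.56)`).
#' @return An object of class `photo_params` (a named list).
#' @seealso [scy7_params()] for the bundled fitted values, [effective_rates()].
#' @export
photo_params <- function(k_iso1,
                         sigma_N,
                         sigma_biso1,
                         sigma_iso2,
                         sigma_biso2,
                         k_biso1_th = 0,
                         k_biso2_th = 0,
                         tau_f,
                         tau_f2 = NA_real_,
                         Q_by_band = c(B = 0)) {
  p <- list(
    k_iso1 = k_iso1,
    sigma_N = sigma_N,
    sigma_biso1 = sigma_biso1,
    sigma_iso2 = sigma_iso2,
    sigma_biso2 = sigma_biso2,
    k_biso1_th = k_biso1_th,
    k_biso2_th = k_biso2_th,
    tau_f = tau_f,
    tau_f2 = tau_f2,
    Q_by_band = Q_by_band
  )
  validate_photo_params(p)
  structure(p, class = "photo_params")
}

validate_photo_params <- function(p) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  for (nm in c("k_iso1", "sigma_N", "sigma_biso1", "sigma_iso2",
               "sigma_biso2", "k_biso1_th", "k_biso2_th", "tau_f")) {
    if (!num_ok(p[[nm]]) || any(p[[nm]] < 0)) {
      abort(paste0("`", nm, "` must be finite and >= 0."))
    }
  }
  if (p$tau_f <= 0) abort("`tau_f` must be > 0.")
  if (p$k_iso1 >= 1 / p$tau_f) {
    abort("`k_iso1` must be < 1/tau_f so that k10_N = 1/tau_f - k_iso1 > 0.")
  }
  if (any(p$Q_by_band < 0)) abort("Q values must be >= 0.")
  invisible(p)
}

#' @export
print.photo_params <- function(x, ...) {
  cat("<photo_params>\n")
  cat(sprintf("  k_iso1      %.4g s^-1   (tau_f = %.3g ns, k10_N = %.4g s^-1)\n",
              x$k_iso1, x$tau_f * 1e9, 1 / x$tau_f - x$k_iso1))
  for (nm in c("sigma_N", "sigma_biso1", "sigma_iso2", "sigma_biso2")) {
    v <- x[[nm]]
    cat(sprintf("  %-11s %s cm^2\n", nm,
                paste(sprintf("%s nm: %.3g", names(v), v), collapse = ", ")))
  }
  cat(sprintf("  k_biso1_th  %.4g s^-1, k_biso2_th %.4g s^-1\n",
              x$k_biso1_th, x$k_biso2_th))
  cat(sprintf("  Q           %s\n",
              paste(sprintf("%s: %.3g", names(x$Q_by_band), x$Q_by_band),
                    collapse = ", ")))
  invisible(x)
}

sigma_at <- function(map, wavelength, what) {
  key <- as.character(round(wavelength))
  if (!key %in% names(map)) {
    abort(paste0("No ", what, " entry for wavelength ", key,
                 " nm; available: ", paste(names(map), collapse = ", "), "."))
  }
  unname(map[[key]])
}

#' Excitation protocol for pulse-train (TRAST) or CW experiments
#'
#' @param wavelength Excitation wavelength, nm.
#' @param irradiance Peak irradiance at the sample, W/cm^2.
#' @param duty_cycle Fraction of time the excitation is on within the pulse
#'   train (0 < eta <= 1); low values let the dye recover to N between pulses.
#' @param w0 Normalization pulse duration in seconds, short enough that no
#'   dark-state build-up occurs (default 100 ns).
#' @param t_ill Total illuminated time per pulse train, seconds (acquisition
#'   bookkeeping only).
#' @param band Emission band label, matched against `Q_by_band`.
#' @return An object of class `excitation_protocol`.
#' @export
excitation_protocol <- function(wavelength, irradiance,
                                duty_cycle = 0.01, w0 = 1e-7,
                                t_ill = 1e-3, band = "B") {
  if (duty_cycle <= 0 || duty_cycle > 1) abort("`duty_cycle` must be in (0, 1].")
  if (irradiance < 0) abort("`irradiance` must be >= 0.")
  if (w0 <= 0) abort("`w0` must be > 0.")
  structure(list(wavelength = wavelength, irradiance = irradiance,
                 duty_cycle = duty_cycle, w0 = w0, t_ill = t_ill, band = band),
            class = "excitation_protocol")
}

#' @export
print.excitation_protocol <- function(x, ...) {
  cat(sprintf("<excitation_protocol> %g nm, %g W/cm^2, duty %g, w0 %g s, band %s\n",
              x$wavelength, x$irradiance, x$duty_cycle, x$w0, x$band))
  invisible(x)
}

q_for_band <- function(params, band) {
  if (!band %in% names(params$Q_by_band)) {
    abort(paste0("No Q entry for emission band '", band, "'."))
  }
  unname(params$Q_by_band[[band]])
}

# ---- parameter file serialization -------------------------------------------

#' Read or write a photophysical parameter file
#'
#' Parameter sets serialize to a plain-text key/value format. Scalar fields are
#' written as `name = value # unit`; per-wavelength cross sections as
#' `name@638 = value`, and per-band brightness as `Q@R = value`. A file may
#' hold several named parameter sets introduced by `[set: label]` lines.
#'
#' @param path File path.
#' @return `read_params()` returns a named list of `photo_params` (or a single
#'   `photo_params` if the file holds one unlabelled set).
#' @seealso [scy7_params()]
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  current <- "default"
  kv <- list()
  flush_set <- function(sets, label, kv) {
    if (length(kv) > 0) sets[[label]] <- kv
    sets
  }
  for (ln in lines) {
    if (grepl("^\\[set:", ln)) {
      sets <- flush_set(sets, current, kv)
      current <- trimws(sub("^\\[set:(.*)\\]$", "\\1", ln))
      kv <- list()
    } else {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort(paste0("Malformed parameter line: ", ln))
      kv[[trimws(parts[1])]] <- as.numeric(trimws(parts[2]))
    }
  }
  sets <- flush_set(sets, current, kv)
  out <- lapply(sets, kv_to_params)
  if (length(out) == 1 && names(out) == "default") out[[1]] else out
}

kv_to_params <- function(kv) {
  keys <- names(kv)
  scalar <- function(nm, default = NULL) {
    if (nm %in% keys) kv[[nm]] else default %||%
      abort(paste0("Missing parameter `", nm, "`."))
  }
  mapped <- function(nm) {
    hit <- grepl(paste0("^", nm, "@"), keys)
    v <- unlist(kv[hit])
    names(v) <- sub(paste0("^", nm, "@"), "", keys[hit])
    v
  }
  photo_params(
    k_iso1 = scalar("k_iso1"),
    sigma_N = mapped("sigma_N"),
    sigma_biso1 = mapped("sigma_biso1"),
    sigma_iso2 = mapped("sigma_iso2"),
    sigma_biso2 = mapped("sigma_biso2"),
    k_biso1_th = scalar("k_biso1_th", 0),
    k_biso2_th = scalar("k_biso2_th", 0),
    tau_f = scalar("tau_f"),
    tau_f2 = scalar("tau_f2", NA_real_),
    Q_by_band = mapped("Q")
  )
}

#' @rdname read_params
#' @param params A `photo_params` object or named list of them.
#' @export
write_params <- function(params, path) {
  one <- function(label, p) {
    out <- character()
    if (!is.null(label)) out <- c(out, paste0("[set: ", label, "]"))
    fmt <- function(nm, v, unit) sprintf("%s = %.12g  # %s", nm, v, unit)
    out <- c(out, fmt("k_iso1", p$k_iso1, "s^-1"))
    for (nm in c("sigma_N", "sigma_biso1", "sigma_iso2", "sigma_biso2")) {
      v <- p[[nm]]
      out <- c(out, vapply(names(v), function(k)
        fmt(paste0(nm, "@", k), v[[k]], "cm^2"), character(1)))
    }
    out <- c(out,
             fmt("k_biso1_th", p$k_biso1_th, "s^-1"),
             fmt("k_biso2_th", p$k_biso2_th, "s^-1"),
             fmt("tau_f", p$tau_f, "s"))
    if (!is.na(p$tau_f2)) out <- c(out, fmt("tau_f2", p$tau_f2, "s"))
    qv <- p$Q_by_band
    out <- c(out, vapply(names(qv), function(k)
      fmt(paste0("Q@", k), qv[[k]], "dimensionless"), character(1)))
    out
  }
  if (inherits(params, "photo_params")) {
    writeLines(one(NULL, params), path)
  } else {
    lines <- unlist(purrr::imap(params, function(p, label) c(one(label, p), "")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Fitted SCy7 parameter sets
#'
#' Returns the published fitted parameter values for the cyanine dye SCy7 in
#' PBS, bundled with the package as `scy7_fitted.params`. Three sets are
#' available, one per measurement modality and excitation wavelength:
#' `"fcs638"` (FCS at 638 nm, thermal rates and Q fixed to 0 in that fit),
#' `"trast638"` (TRAST at 638 nm, two emission bands), and `"trast785"`
#' (TRAST at 785 nm, with the cross sections of P1 scaled by F = 14 relative
#' to 638 nm). The excited-state lifetime of N is 0.52 ns throughout.
#'
#' @param set One of `"fcs638"`, `"trast638"`, `"trast785"`.
#' @return A `photo_params` object.
#' @examples
#' scy7_params("fcs638")
#' @export
scy7_params <- function(set = c("fcs638", "trast638", "trast785")) {
  set <- match.arg(set)
  path <- system.file("extdata", "scy7_fitted.params", package = "phototrast")
  read_params(path)[[set]]
}
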