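# Kinetic core of the three-state photoisomerization scheme
#
#   N  <->  P1  <->  P2
#
# N (emissive all-trans) exchanges with the dark mono-cis P1 and P1 with the
# red-emissive photoisomer P2. Transitions are described by effective,
# excitation-dependent first-order rates; the scheme is solved analytically by
# eigendecomposition of the 3x3 generator, with an adaptive ODE integration as
# the fallback (and as the in-package oracle for tests).

#' Effective isomerization rates under given excitation conditions
#'
#' Converts dye constants plus excitation wavelength and irradiance into the
#' four effective first-order rates of the three-state scheme:
#' * `k_iso1_eff  = k_iso1 * f_exc` with the excited-state fraction
#'   `f_exc = sigma_N*phi / k10_N` (pre-saturation, the default) or
#'   `f_exc = sigma_N*phi / (sigma_N*phi + 1/tau_f)` (`saturation = TRUE`),
#'   where `k10_N = 1/tau_f - k_iso1` and `phi` is the photon flux;
#' * `k_biso1_eff = sigma_biso1*phi + k_biso1_th`;
#' * `k_iso2_eff  = sigma_iso2*phi`;
#' * `k_biso2_eff = sigma_biso2*phi + k_biso2_th`.
#'
#' The saturating form matters only near MW/cm^2 irradiances where the
#' excited-state population of N levels off; at the irradiances typical of
#' pulse-train (kW/cm^2) and correlation (100s of kW/cm^2) measurements both
#' forms agree.
#'
#' @param params A [photo_params()] object.
#' @param wavelength Excitation wavelength in nm; must be present in the
#'   cross-section maps of `params`.
#' @param irradiance Irradiance in W/cm^2.
#' @param saturation Use the saturating excited-state fraction for N.
#' @return A `rate_set` object with fields `k_iso1_eff`, `k_biso1_eff`,
#'   `k_iso2_eff`, `k_biso2_eff` (s^-1).
#' @export
effective_rates <- function(params, wavelength, irradiance, saturation = FALSE) {
  phi <- photon_flux(irradiance, wavelength)
  k10_N <- 1 / params$tau_f - params$k_iso1
  sN <- sigma_at(params$sigma_N, wavelength, "sigma_N")
  f_exc <- if (saturation) {
    sN * phi / (sN * phi + 1 / params$tau_f)
  } else {
    sN * phi / k10_N
  }
  rate_set(
    k_iso1_eff = params$k_iso1 * f_exc,
    k_biso1_eff = sigma_at(params$sigma_biso1, wavelength, "sigma_biso1") * phi +
      params$k_biso1_th,
    k_iso2_eff = sigma_at(params$sigma_iso2, wavelength, "sigma_iso2") * phi,
    k_biso2_eff = sigma_at(params$sigma_biso2, wavelength, "sigma_biso2") * phi +
      params$k_biso2_th
  )
}

#' Construct a set of effective rates directly
#'
#' @param k_iso1_eff,k_biso1_eff,k_iso2_eff,k_biso2_eff Effective first-order
#'   rates in s^-1, all >= 0.
#' @return A `rate_set` object.
#' @export
rate_set <- function(k_iso1_eff, k_biso1_eff, k_iso2_eff, k_biso2_eff) {
  r <- list(k_iso1_eff = k_iso1_eff, k_biso1_eff = k_biso1_eff,
            k_iso2_eff = k_iso2_eff, k_biso2_eff = k_biso2_eff)
  if (any(!is.finite(unlist(r))) || any(unlist(r) < 0)) {
    rlang::abort("All effective rates must be finite and >= 0.")
  }
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(paste0("<rate_set> k_iso1' = %.4g, k_biso1' = %.4g, ",
                     "k_iso2' = %.4g, k_biso2' = %.4g s^-1\n"),
              x$k_iso1_eff, x$k_biso1_eff, x$k_iso2_eff, x$k_biso2_eff))
  invisible(x)
}

#' Generator matrix of the three-state scheme
#'
#' Returns the 3x3 rate matrix M acting on the population column vector
#' p = (N, P1, P2), i.e. dp/dt = M p. Columns sum to zero (probability
#' conservation) and off-diagonal entries are the non-negative transition
#' rates of the N <-> P1 <-> P2 chain.
#'
#' @param rates A [rate_set()].
#' @return A 3x3 numeric matrix with dimnames `c("N","P1","P2")`.
#' @export
rate_matrix <- function(rates) {
  k12 <- rates$k_iso1_eff   # N  -> P1
  k21 <- rates$k_biso1_eff  # P1 -> N
  k23 <- rates$k_iso2_eff   # P1 -> P2
  k32 <- rates$k_biso2_eff  # P2 -> P1
  m <- matrix(c(-k12,        k21,          0,
                 k12, -(k21 + k23),      k32,
                   0,         k23,      -k32),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("N", "P1", "P2"), c("N", "P1", "P2")))
  m
}

#' Stationary populations under constant excitation
#'
#' For the linear chain the stationary distribution follows from detailed
#' balance: `p_P1/p_N = k_iso1'/k_biso1'` and `p_P2/p_P1 = k_iso2'/k_biso2'`.
#' Below saturation and with negligible thermal rates all four effective rates
#' are proportional to the irradiance, so these ratios -- and hence the
#' steady state -- are irradiance-independent.
#'
#' @param rates A [rate_set()].
#' @return A one-row tibble with columns `p_N`, `p_P1`, `p_P2` summing to 1.
#' @export
steady_state <- function(rates) {
  p <- steady_state_vec(rates$k_iso1_eff, rates$k_biso1_eff,
                        rates$k_iso2_eff, rates$k_biso2_eff)
  tibble::tibble(p_N = p[1], p_P1 = p[2], p_P2 = p[3])
}

# bare-numeric stationary distribution, used in fitting hot paths
steady_state_vec <- function(k12, k21, k23, k32) {
  if (k12 == 0 && k21 == 0 && k23 == 0 && k32 == 0) {
    rlang::abort("All rates are zero: stationary state is not unique.")
  }
  if ((k21 == 0 && k12 > 0) || (k32 == 0 && k23 > 0)) {
    # forward flux without the matching return path: the chain is absorbing
    # and no excitation-recovery steady state exists
    rlang::abort("Degenerate chain: forward rates without a return path to N.")
  }
  r1 <- if (k21 > 0) k12 / k21 else 0
  r2 <- if (k32 > 0) k23 / k32 else 0
  p <- c(1, r1, r1 * r2)
  p / sum(p)
}

# ---- internal analytic solver -----------------------------------------------

# Eigen-solve dp/dt = M p with initial condition p0.
# Returns list(mode = "eigen", lambda, V, coef) or NULL when the spectrum is
# numerically degenerate / non-real, in which case callers fall back to ODE
# integration.
kin_solve <- function(m, p0) {
  if (all(m == 0)) {
    return(list(mode = "eigen", lambda = c(0, 0, 0), V = diag(3),
                coef = as.numeric(p0)))
  }
  e <- eigen(m)
  lam <- e$values; V <- e$vectors
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 1e-9 * max(abs(lam))) return(NULL)
    lam <- Re(lam); V <- Re(V)
  }
  scale <- max(abs(lam))
  # snap the stationary eigenvalue to exactly zero
  i0 <- which.min(abs(lam))
  if (abs(lam[i0]) > 1e-6 * scale) return(NULL)
  lam[i0] <- 0
  # distinct-eigenvalue guard (relative gap below 1e-9 -> ODE fallback)
  if (any(abs(diff(sort(lam))) < 1e-9 * scale)) return(NULL)
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  # cheap 1-norm condition estimate in place of a full kappa()
  if (max(colSums(abs(V))) * max(colSums(abs(Vinv))) > 1e10) return(NULL)
  list(mode = "eigen", lambda = lam, V = V,
       coef = as.numeric(Vinv %*% as.numeric(p0)))
}

kin_populations_eigen <- function(sol, times) {
  ew <- exp(outer(sol$lambda, times))          # 3 x T
  p <- sol$V %*% (sol$coef * ew)               # 3 x T
  t(p)
}

kin_populations_ode <- function(m, p0, times, rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) list(as.numeric(m %*% y))
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  out <- deSolve::lsoda(y = as.numeric(p0), times = tt, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  res <- unname(out[, 2:4, drop = FALSE])
  if (prepend) res <- res[-1, , drop = FALSE]
  res
}

# Time-averaged signal (1/w) int_0^w q . p(t) dt for each pulse width w.
# Analytic in the eigen basis; ODE quadrature otherwise.
kin_mean_signal <- function(m, p0, q, w) {
  sol <- kin_solve(m, p0)
  if (!is.null(sol)) {
    a <- as.numeric(crossprod(q, sol$V)) * sol$coef   # per-mode amplitudes
    g <- function(x) ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)
    vapply(w, function(wi) sum(a * g(sol$lambda * wi)), numeric(1))
  } else {
    kin_mean_signal_ode(m, p0, q, w)
  }
}

kin_mean_signal_ode <- function(m, p0, q, w) {
  deriv <- function(t, y, parms) {
    dp <- as.numeric(m %*% y[1:3])
    list(c(dp, sum(q * y[1:3])))
  }
  tt <- sort(unique(c(0, w)))
  out <- deSolve::lsoda(y = c(as.numeric(p0), 0), times = tt, func = deriv,
                        parms = NULL, rtol = 1e-11, atol = 1e-13)
  cum <- stats::approx(out[, 1], out[, 5], xout = w)$y
  ifelse(w == 0, sum(q * p0), cum / w)
}

#' Populations of N, P1, P2 versus time after onset of excitation
#'
#' Solves dp/dt = M p by eigendecomposition of the generator; if the spectrum
#' is numerically degenerate (relative eigenvalue gap below 1e-9) the solution
#' falls back to adaptive ODE integration (`deSolve::lsoda`, rtol 1e-10).
#' By default all molecules start in N, the situation at the onset of an
#' excitation pulse after full dark recovery.
#'
#' @param rates A [rate_set()].
#' @param times Non-negative, increasing time grid in seconds.
#' @param initial Initial populations `c(p_N, p_P1, p_P2)`, summing to 1.
#' @param method `"auto"` (eigen with ODE fallback), `"eigen"`, or `"ode"`
#'   (force the integrator; used as an independent oracle in tests).
#' @return A tibble of class `state_trajectory` with columns `time`, `p_N`,
#'   `p_P1`, `p_P2`; the generating `rate_set` is attached as attribute
#'   `rates`.
#' @export
populations_vs_time <- function(rates, times, initial = c(1, 0, 0),
                                method = c("auto", "eigen", "ode")) {
  method <- match.arg(method)
  if (any(diff(times) <= 0) || any(times < 0)) {
    rlang::abort("`times` must be non-negative and strictly increasing.")
  }
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    rlang::abort("`initial` must be non-negative populations summing to 1.")
  }
  m <- rate_matrix(rates)
  p <- switch(method,
    auto = {
      sol <- kin_solve(m, initial)
      if (is.null(sol)) kin_populations_ode(m, initial, times)
      else kin_populations_eigen(sol, times)
    },
    eigen = {
      sol <- kin_solve(m, initial)
      if (is.null(sol)) rlang::abort("Eigen solution unavailable (degenerate spectrum).")
      kin_populations_eigen(sol, times)
    },
    ode = kin_populations_ode(m, initial, times)
  )
  out <- tibble::tibble(time = times, p_N = p[, 1], p_P1 = p[, 2], p_P2 = p[, 3])
  attr(out, "rates") <- rates
  class(out) <- c("state_trajectory", class(out))
  out
}

#' Relaxation spectrum of the generator
#'
#' Eigenvalues and projection amplitudes of the 3x3 generator. Exactly one
#' eigenvalue is zero (stationarity); for this reversible chain the other two
#' are real and negative, and their magnitudes are the relaxation rates seen
#' in correlation and pulse-train measurements.
#'
#' @param rates A [rate_set()].
#' @return A list of class `relaxation_spectrum` with `values` (sorted by
#'   magnitude, first exactly 0), right eigenvector matrix `vectors`, and
#'   `inv_vectors` such that the populations at time t for initial condition
#'   p0 are `vectors %*% (exp(values * t) * (inv_vectors %*% p0))`.
#' @export
relaxation_eigenvalues <- function(rates) {
  m <- rate_matrix(rates)
  sol <- kin_solve(m, c(1, 0, 0))
  if (is.null(sol)) {
    e <- eigen(m)
    lam <- Re(e$values); V <- Re(e$vectors)
    lam[which.min(abs(lam))] <- 0
  } else {
    lam <- sol$lambda; V <- sol$V
  }
  ord <- order(abs(lam))
  Vinv <- tryCatch(solve(V), error = function(e) NULL)  # defective: no basis
  structure(list(values = lam[ord],
                 vectors = V[, ord, drop = FALSE],
                 inv_vectors = if (!is.null(Vinv)) Vinv[ord, , drop = FALSE]),
            class = "relaxation_spectrum")
}

#' @export
print.relaxation_spectrum <- function(x, ...) {
  cat("<relaxation_spectrum> eigenvalues:",
      paste(sprintf("%.4g", x$values), collapse = ", "), "s^-1\n")
  invisible(x)
}

#' Reduce the three-state scheme to an effective two-state model
#'
#' When the P1 <-> P2 exchange is much faster than the N <-> P1 exchange, P1
#' and P2 act on the slow timescale as a single lumped photoisomer in local
#' equilibrium. The lumped state has population `p_P1 + p_P2` and detected
#' brightness `Q_lump = Q * r2 / (1 + r2)` with `r2 = k_iso2'/k_biso2'`, i.e.
#' the P2-weighted average brightness. With `Q = 0` this is the classic
#' two-state trans/cis blinking model with a dark photoisomer.
#'
#' @param params A [photo_params()].
#' @param wavelength,irradiance Excitation conditions.
#' @param band Emission band label selecting Q.
#' @param saturation Passed to [effective_rates()].
#' @param sep_threshold Minimum ratio of fast to slow relaxation rate; below
#'   it a warning is issued (the reduction is still returned).
#' @return A list of class `two_state_params` with elements `k_on` (N to lump),
#'   `k_off` (lump to N), `tau_iso = 1/(k_on + k_off)`, `p_dark` (stationary
#'   lumped population), `Q_lump`, and `separation` (eigenvalue ratio).
#' @export
reduce_two_state <- function(params, wavelength, irradiance, band = "B",
                             saturation = FALSE, sep_threshold = 10) {
  rates <- effective_rates(params, wavelength, irradiance, saturation)
  Q <- q_for_band(params, band)
  spec <- relaxation_eigenvalues(rates)
  lam <- abs(spec$values[2:3])
  separation <- if (lam[1] > 0) lam[2] / lam[1] else Inf
  if (is.finite(separation) && separation < sep_threshold) {
    rlang::warn(sprintf(
      "P1-P2 exchange is only %.2g-fold faster than N-P1 relaxation; the two-state reduction may be inaccurate.",
      separation))
  }
  r2 <- if (rates$k_biso2_eff > 0) rates$k_iso2_eff / rates$k_biso2_eff else
    if (rates$k_iso2_eff == 0) 0 else Inf
  if (!is.finite(r2)) rlang::abort("P2 is absorbing: cannot lump P1 and P2.")
  q_lump <- Q * r2 / (1 + r2)
  k_on <- rates$k_iso1_eff
  k_off <- rates$k_biso1_eff / (1 + r2)
  ss <- steady_state(rates)
  structure(list(k_on = k_on, k_off = k_off,
                 tau_iso = 1 / (k_on + k_off),
                 p_dark = ss$p_P1 + ss$p_P2,
                 Q_lump = q_lump, separation = separation),
            class = "two_state_params")
}
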