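# Global nonlinear least-squares fitting of sets of TRAST and FCS curves.
#
# A fit specification assigns every model parameter one role:
#   fixed       held at a value,
#   global      one shared value across all curves,
#   local       one value per curve (e.g. N_m and tau_D in FCS),
#   scaled      a fixed base value times a free global factor (the
#               cross-wavelength scaling of the P1 cross sections).
# Rates and cross sections are fitted in log space so positivity is enforced
# by the transform rather than by penalties. Optimization is multi-start
# Levenberg-Marquardt on the concatenated residuals of all curves.

#' Declare parameter roles for a global fit
#'
#' @param ... Parameter declarations from [par_fixed()], [par_global()],
#'   [par_local()], [par_scaled()].
#' @return A `fit_spec` tibble with one row per parameter.
#' @examples
#' fit_spec(par_fixed("Q_B", 0), par_global("k_iso1", 1e7, 1e4, 1e9))
#' @export
fit_spec <- function(...) {
  rows <- dplyr::bind_rows(...)
  if (anyDuplicated(rows$name)) {
    rlang::abort("Each parameter may be declared only once.")
  }
  bad <- rows$role == "scaled" & !(rows$factor %in% rows$name)
  if (any(bad)) {
    rlang::abort("Scaled parameters must reference a declared factor parameter.")
  }
  class(rows) <- c("fit_spec", class(rows))
  rows
}

spec_row <- function(name, role, init = NA_real_, lower = NA_real_,
                     upper = NA_real_, transform = "log",
                     base_value = NA_real_, factor = NA_character_) {
  tibble::tibble(name = name, role = role, init = init, lower = lower,
                 upper = upper, transform = transform,
                 base_value = base_value, factor = factor)
}

#' @rdname fit_spec
#' @param name Parameter name as used by the model (`k_iso1`, `sigma_biso1`,
#'   `sigma_iso2`, `sigma_biso2`, `k_th1`, `k_th2`, `Q_<band>`, `N_m`,
#'   `tau_D`, or a factor such as `F`).
#' @param value Fixed value.
#' @export
par_fixed <- function(name, value) spec_row(name, "fixed", init = value)

#' @rdname fit_spec
#' @param init Initial value (first multi-start point).
#' @param lower,upper Positive bounds (log-transformed parameters) or plain
#'   bounds (linear).
#' @param transform `"log"` (default) or `"linear"`.
#' @export
par_global <- function(name, init, lower, upper, transform = "log") {
  spec_row(name, "global", init, lower, upper, transform)
}

#' @rdname fit_spec
#' @export
par_local <- function(name, init, lower, upper, transform = "log") {
  spec_row(name, "local", init, lower, upper, transform)
}

#' @rdname fit_spec
#' @param base_value Fixed base value the factor multiplies.
#' @param factor Name of the (global) factor parameter.
#' @export
par_scaled <- function(name, base_value, factor) {
  spec_row(name, "scaled", base_value = base_value, factor = factor)
}

# ---- optimizer plumbing -----------------------------------------------------

to_opt <- function(x, transform) ifelse(transform == "log", log(x), x)
from_opt <- function(x, transform) ifelse(transform == "log", exp(x), x)

build_free_table <- function(spec, n_curves) {
  free <- spec[spec$role %in% c("global", "local"), ]
  if (nrow(free) == 0) rlang::abort("The fit spec declares no free parameters.")
  rows <- purrr::pmap_dfr(free, function(name, role, init, lower, upper,
                                         transform, ...) {
    if (role == "local") {
      tibble::tibble(par = sprintf("%s[%d]", name, seq_len(n_curves)),
                     name = name, curve = seq_len(n_curves),
                     init = init, lower = lower, upper = upper,
                     transform = transform)
    } else {
      tibble::tibble(par = name, name = name, curve = NA_integer_,
                     init = init, lower = lower, upper = upper,
                     transform = transform)
    }
  })
  if (any(!is.finite(rows$init)) || any(rows$lower <= 0 & rows$transform == "log")) {
    rlang::abort("Free parameters need finite inits and positive bounds on the log scale.")
  }
  rows
}

resolve_theta <- function(par_opt, free_tab, spec, curve_i) {
  vals <- from_opt(par_opt, free_tab$transform)
  theta <- list()
  for (j in seq_len(nrow(free_tab))) {
    if (is.na(free_tab$curve[j]) || free_tab$curve[j] == curve_i) {
      theta[[free_tab$name[j]]] <- vals[j]
    }
  }
  fixed <- spec[spec$role == "fixed", ]
  for (j in seq_len(nrow(fixed))) theta[[fixed$name[j]]] <- fixed$init[j]
  scaled <- spec[spec$role == "scaled", ]
  for (j in seq_len(nrow(scaled))) {
    theta[[scaled$name[j]]] <- scaled$base_value[j] * theta[[scaled$factor[j]]]
  }
  theta
}

# Multi-start Levenberg-Marquardt over concatenated curve residuals.
global_fit_engine <- function(curves, spec, model_fn, constants,
                              n_starts, seed, maxiter = 200) {
  n_curves <- length(curves)
  free_tab <- build_free_table(spec, n_curves)
  p0 <- to_opt(free_tab$init, free_tab$transform)
  lo <- to_opt(free_tab$lower, free_tab$transform)
  hi <- to_opt(free_tab$upper, free_tab$transform)

  xs <- lapply(curves, function(cv) cv[[1]])
  ys <- lapply(curves, function(cv) cv[[2]])
  wts <- lapply(curves, function(cv) {
    if ("sd" %in% names(cv)) 1 / cv$sd else rep(1, nrow(cv))
  })
  metas <- lapply(curves, curve_meta)
  n_points <- sum(lengths(ys))

  resid_fn <- function(par) {
    out <- vector("list", n_curves)
    for (i in seq_len(n_curves)) {
      theta <- resolve_theta(par, free_tab, spec, i)
      pred <- tryCatch(model_fn(theta, metas[[i]], xs[[i]], constants),
                       error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) {
        return(rep(1e6, n_points))
      }
      out[[i]] <- (pred - ys[[i]]) * wts[[i]]
    }
    unlist(out, use.names = FALSE)
  }

  starts <- matrix(p0, nrow = 1)
  if (n_starts > 1) {
    draws <- with_seed(seed, {
      matrix(stats::runif((n_starts - 1) * length(p0), min = rep(lo, each = n_starts - 1),
                          max = rep(hi, each = n_starts - 1)),
             nrow = n_starts - 1)
    })
    starts <- rbind(starts, draws)
  }

  best <- NULL
  start_rss <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lo, upper = hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ans) || ans$info %in% c(0, 9)) next
    start_rss[s] <- ans$deviance
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (is.null(best)) {
    rlang::abort("No multi-start run converged; inspect bounds and data.")
  }

  vals <- from_opt(best$par, free_tab$transform)
  dof <- n_points - length(best$par)
  sigma2 <- best$deviance / max(dof, 1)
  cov_t <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov_t)) {
    se_t <- sqrt(pmax(diag(cov_t), 0))
    corr <- tryCatch(stats::cov2cor(cov_t), error = function(e) NULL)
  } else {
    se_t <- rep(NA_real_, length(vals))
    corr <- NULL
  }
  se <- ifelse(free_tab$transform == "log", se_t * vals, se_t)
  if (!is.null(corr)) dimnames(corr) <- list(free_tab$par, free_tab$par)

  estimates <- tibble::tibble(term = free_tab$par, name = free_tab$name,
                              curve = free_tab$curve, estimate = vals, se = se)
  # append resolved scaled parameters for convenience
  scaled <- spec[spec$role == "scaled", ]
  if (nrow(scaled) > 0) {
    fvals <- estimates$estimate[match(scaled$factor, estimates$term)]
    fses <- estimates$se[match(scaled$factor, estimates$term)]
    estimates <- dplyr::bind_rows(estimates, tibble::tibble(
      term = scaled$name, name = scaled$name, curve = NA_integer_,
      estimate = scaled$base_value * fvals, se = scaled$base_value * fses))
  }

  fitted <- lapply(seq_len(n_curves), function(i) {
    theta <- resolve_theta(best$par, free_tab, spec, i)
    model_fn(theta, metas[[i]], xs[[i]], constants)
  })
  residuals <- purrr::map2(ys, fitted, `-`)

  structure(list(
    estimates = estimates, correlation = corr,
    rss = best$deviance, dof = dof, n_points = n_points,
    n_curves = n_curves, n_starts = n_starts,
    start_rss = start_rss, seed = seed,
    fitted = fitted, residuals = residuals,
    spec = spec, info = best$info, converged = TRUE
  ), class = "photo_fit")
}

#' @export
print.photo_fit <- function(x, ...) {
  cat(sprintf("<photo_fit> %d curves, %d points, rss = %.4g (dof %d), %d starts\n",
              x$n_curves, x$n_points, x$rss, x$dof, x$n_starts))
  glob <- x$estimates[is.na(x$estimates$curve), ]
  for (j in seq_len(nrow(glob))) {
    cat(sprintf("  %-14s %.4g", glob$term[j], glob$estimate[j]))
    if (is.finite(glob$se[j])) cat(sprintf("  (se %.2g)", glob$se[j]))
    cat("\n")
  }
  qc <- q_correlation(x)
  if (!is.null(qc)) {
    cat(sprintf("  strongest Q cross-correlation: %s (r = %.2f)\n",
                names(qc), qc))
  }
  invisible(x)
}

# Cross-covariance between the brightness Q and the parameters governing the
# P2 occupancy is a known degeneracy of the model; surface it prominently.
q_correlation <- function(fit) {
  if (is.null(fit$correlation)) return(NULL)
  qpars <- grep("^Q_", rownames(fit$correlation), value = TRUE)
  if (length(qpars) == 0) return(NULL)
  sub <- fit$correlation[qpars, setdiff(colnames(fit$correlation), qpars),
                         drop = FALSE]
  if (length(sub) == 0) return(NULL)
  i <- which.max(abs(sub))
  val <- sub[i]
  names(val) <- paste0(qpars[(i - 1) %% length(qpars) + 1], " ~ ",
                       colnames(sub)[(i - 1) %/% length(qpars) + 1])
  val
}

# ---- model functions --------------------------------------------------------

theta_rates <- function(theta, meta, constants) {
  wl <- meta$wavelength
  phi <- photon_flux(meta$irradiance, wl)
  sigma_N <- sigma_at(constants$sigma_N, wl, "sigma_N")
  k10 <- 1 / constants$tau_f - theta$k_iso1
  if (k10 <= 0) rlang::abort("k_iso1 exceeds 1/tau_f.")
  list(
    k12 = theta$k_iso1 * sigma_N * phi / k10,
    k21 = theta$sigma_biso1 * phi + theta$k_th1,
    k23 = theta$sigma_iso2 * phi,
    k32 = theta$sigma_biso2 * phi + theta$k_th2
  )
}

trast_model_fn <- function(theta, meta, w, constants) {
  k <- theta_rates(theta, meta, constants)
  m <- rate_matrix(rate_set(k$k12, k$k21, k$k23, k$k32))
  Q <- theta[[paste0("Q_", meta$band)]]
  if (is.null(Q)) rlang::abort(paste0("No Q parameter for band ", meta$band, "."))
  s <- kin_mean_signal(m, c(1, 0, 0), c(1, 0, Q), c(meta$w0, w))
  s[-1] / s[1]
}

fcs_model_fn <- function(theta, meta, tau, constants) {
  k <- theta_rates(theta, meta, constants)
  rs <- rate_set(k$k12, k$k21, k$k23, k$k32)
  Q <- theta[[paste0("Q_", meta$band)]]
  if (is.null(Q)) rlang::abort(paste0("No Q parameter for band ", meta$band, "."))
  gt <- blinking_from_rates(rs, Q, tau)
  x <- tau / theta$tau_D
  gd <- (1 / theta$N_m) / (1 + x) / sqrt(1 + x / constants$S^2)
  baseline <- meta$baseline %||% 1
  baseline + gd * gt
}

# ---- user-facing fits -------------------------------------------------------

#' Globally fit the three-state model to a set of TRAST curves
#'
#' Fits the kinetic parameters to normalized TRAST curves across irradiances,
#' excitation wavelengths, and emission bands. Residuals are unweighted (the
#' curves are normalized). The ground-state cross section of N and the
#' excited-state lifetime of N are supplied as known constants, mirroring the
#' convention of fixing `sigma_N` from the absorption spectrum and `tau_f`
#' from TCSPC.
#'
#' @param curves List of `trast_curve` tibbles (see [trast_curve()],
#'   [preprocess_trast()], [read_curve()]).
#' @param spec A [fit_spec()]; see [fit_spec_trast638()] /
#'   [fit_spec_trast785()] for the standard configurations.
#' @param constants List with `sigma_N` (named cm^2 map by wavelength) and
#'   `tau_f` (seconds).
#' @param n_starts Number of multi-start initializations (first start = spec
#'   inits, the rest drawn log-uniform within bounds).
#' @param seed Seed for the multi-start draws.
#' @return A `photo_fit` object; see [tidy.photo_fit()], [glance.photo_fit()].
#' @export
global_fit_trast <- function(curves, spec,
                             constants = list(sigma_N = c("638" = 1.56e-16,
                                                          "785" = 2.48e-16),
                                              tau_f = 0.52e-9),
                             n_starts = 16, seed = 1) {
  global_fit_engine(curves, spec, trast_model_fn, constants, n_starts, seed)
}

#' Globally fit the three-state model to a set of FCS curves
#'
#' The blinking parameters are shared across curves while `N_m` and `tau_D`
#' are fitted per curve; the axial ratio S is a fixed constant (6.8 by
#' default, from volume calibration). Curves carrying an `sd` column are
#' fitted with `1/sd` weights.
#'
#' @param curves List of `fcs_curve` tibbles.
#' @param spec A [fit_spec()]; see [fit_spec_fcs()].
#' @param constants List with `sigma_N`, `tau_f`, and `S`.
#' @inheritParams global_fit_trast
#' @return A `photo_fit` object.
#' @export
global_fit_fcs <- function(curves, spec,
                           constants = list(sigma_N = c("638" = 1.56e-16),
                                            tau_f = 0.52e-9, S = 6.8),
                           n_starts = 16, seed = 1) {
  global_fit_engine(curves, spec, fcs_model_fn, constants, n_starts, seed)
}

# ---- standard fit configurations -------------------------------------------

#' Standard global-fit configurations
#'
#' These constructors encode the three fitting configurations used for SCy7:
#'
#' * `fit_spec_fcs()`: 638 nm FCS -- `k_iso1`, `sigma_biso1`, `sigma_iso2`,
#'   `sigma_biso2` global; `Q` and both thermal rates fixed to 0 (B-band
#'   emission is from N only and thermal terms are negligible at FCS
#'   irradiances); `N_m` and `tau_D` per curve.
#' * `fit_spec_trast638()`: two-band TRAST at 638 nm -- rates, cross sections
#'   and thermal rates global; `Q_B` fixed to 0; `Q_R` global.
#' * `fit_spec_trast785(base)`: TRAST at 785 nm -- `k_iso1` and thermal rates
#'   fixed to the 638 nm values in `base`; `sigma_biso1` and `sigma_iso2`
#'   tied to their 638 nm values through one free scaling factor `F`;
#'   `sigma_biso2` global; `Q_R` global.
#'
#' @param bands Emission band labels present in the curves (trast638).
#' @param base Named list/vector with the 638 nm reference values `k_iso1`,
#'   `sigma_biso1`, `sigma_iso2`, `k_th1`, `k_th2` (e.g. estimates from a
#'   638 nm fit).
#' @return A [fit_spec()].
#' @export
fit_spec_fcs <- function() {
  fit_spec(
    par_global("k_iso1", 1e7, 1e4, 1e9),
    par_global("sigma_biso1", 1e-18, 1e-21, 1e-14),
    par_global("sigma_iso2", 1e-17, 1e-21, 1e-14),
    par_global("sigma_biso2", 1e-17, 1e-21, 1e-14),
    par_fixed("k_th1", 0),
    par_fixed("k_th2", 0),
    par_fixed("Q_B", 0),
    par_local("N_m", 1, 1e-2, 1e4),
    par_local("tau_D", 1e-4, 1e-6, 1)
  )
}

#' @rdname fit_spec_fcs
#' @export
fit_spec_trast638 <- function(bands = c("B", "R")) {
  rows <- list(
    par_global("k_iso1", 1e7, 1e4, 1e9),
    par_global("sigma_biso1", 1e-18, 1e-21, 1e-14),
    par_global("sigma_iso2", 1e-17, 1e-21, 1e-14),
    par_global("sigma_biso2", 1e-17, 1e-21, 1e-14),
    par_global("k_th1", 1e4, 1e2, 1e7),
    par_global("k_th2", 1e4, 1e2, 1e7)
  )
  for (b in bands) {
    rows <- c(rows, list(
      if (b == "B") par_fixed("Q_B", 0)
      else par_global(paste0("Q_", b), 1, 1e-3, 1e2)
    ))
  }
  do.call(fit_spec, rows)
}

#' @rdname fit_spec_fcs
#' @export
fit_spec_trast785 <- function(base, bands = "R") {
  rows <- list(
    par_fixed("k_iso1", base$k_iso1),
    par_fixed("k_th1", base$k_th1),
    par_fixed("k_th2", base$k_th2),
    par_global("F", 5, 0.05, 1e3),
    par_scaled("sigma_biso1", base$sigma_biso1, "F"),
    par_scaled("sigma_iso2", base$sigma_iso2, "F"),
    par_global("sigma_biso2", 1e-17, 1e-21, 1e-14)
  )
  for (b in bands) {
    rows <- c(rows, list(par_global(paste0("Q_", b), 1, 1e-3, 1e2)))
  }
  do.call(fit_spec, rows)
}

# ---- phenomenological single-exponential relaxation fits --------------------

#' Fit a single-exponential relaxation model to TRAST curves
#'
#' Fits the pulse-averaged one-exponential relaxation
#' `value(w) = 1 - A * (1 - (tau/w) * (1 - exp(-w/tau)))`
#' with signed amplitude `A` and relaxation time `tau` as the only free
#' parameters (`model = "plain_exp"` selects the un-averaged form
#' `1 - A * (1 - exp(-w/tau))` instead). A negative `A` encodes inverse
#' relaxation: fluorescence growing with pulse duration. With
#' `global_tau = TRUE` a list of curves is fitted with per-curve amplitudes
#' and one shared relaxation time.
#'
#' @param curves A single `trast_curve` or a list of them.
#' @param model Pulse-averaged (default) or plain exponential form.
#' @param global_tau Share tau across curves (requires a list of curves).
#' @return A tibble with one row per curve: `curve`, `A`, `tau`, their
#'   standard errors, and `flat` (amplitude within three standard errors of
#'   zero, or errors unavailable -- the relaxation time is then unbounded).
#' @export
fit_single_relaxation <- function(curves, model = c("pulse_avg", "plain_exp"),
                                  global_tau = FALSE) {
  model <- match.arg(model)
  if (inherits(curves, "trast_curve")) curves <- list(curves)
  n <- length(curves)
  shape <- function(w, tau) {
    if (model == "pulse_avg") {
      x <- w / tau
      ifelse(abs(x) < 1e-8, x / 2, 1 - (1 - exp(-x)) / x)
    } else {
      1 - exp(-w / tau)
    }
  }
  ws <- lapply(curves, function(cv) cv$w)
  ys <- lapply(curves, function(cv) cv$value)
  n_tau <- if (global_tau) 1 else n
  # par = (A_1..A_n, log tau_1..log tau_n_tau)
  resid_fn <- function(par) {
    a <- par[seq_len(n)]
    ltau <- par[n + seq_len(n_tau)]
    unlist(lapply(seq_len(n), function(i) {
      tau <- exp(if (global_tau) ltau[1] else ltau[i])
      (1 - a[i] * shape(ws[[i]], tau)) - ys[[i]]
    }), use.names = FALSE)
  }
  a0 <- vapply(ys, function(y) 1 - y[length(y)], numeric(1))
  tau0 <- vapply(seq_len(n), function(i) {
    y <- ys[[i]]; w <- ws[[i]]
    half <- 1 - a0[i] / 2
    idx <- if (a0[i] >= 0) which(y <= half) else which(y >= half)
    if (length(idx) > 0) w[idx[1]] else stats::median(w)
  }, numeric(1))
  if (global_tau) tau0 <- stats::median(tau0)
  a_init <- ifelse(abs(a0) < 1e-6, 1e-6, a0)
  par0 <- c(a_init, log(tau0))
  ans <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-13, ptol = 1e-13))
  a <- ans$par[seq_len(n)]
  tau <- exp(ans$par[n + seq_len(n_tau)])
  dof <- sum(lengths(ys)) - length(par0)
  sigma2 <- ans$deviance / max(dof, 1)
  cov <- tryCatch(sigma2 * solve(ans$hessian), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_, length(par0))
  se_a <- se[seq_len(n)]
  se_tau <- se[n + seq_len(n_tau)] * tau
  tibble::tibble(
    curve = seq_len(n),
    A = a, se_A = se_a,
    tau = if (global_tau) rep(tau, n) else tau,
    se_tau = if (global_tau) rep(se_tau, n) else se_tau,
    flat = !is.finite(se_a) | abs(a) < 3 * se_a
  )
}

# ---- preprocessing ----------------------------------------------------------

#' Preprocess a raw TRAST acquisition
#'
#' Subtracts the static ambient background, fits a smooth bleaching trend
#' (linear or exponential in acquisition order) to the interleaved reference
#' frames -- all recorded at the short normalization pulse duration, where no
#' dark-state build-up occurs -- divides the trend out, and normalizes the
#' curve by the corrected reference level. Total bleaching correction beyond
#' 10% triggers a warning, as does an apparently increasing reference trend.
#'
#' @param raw A `trast_raw` acquisition from [gen_trast_experiment()] or
#'   a list with elements `curve` (tibble `w`, `counts`, `order`),
#'   `references` (tibble `order`, `counts`), and `meta`.
#' @param background Static background counts per frame.
#' @param trend `"exponential"` (default) or `"linear"` bleaching model.
#' @return A normalized `trast_curve` tibble.
#' @export
preprocess_trast <- function(raw, background = 0,
                             trend = c("exponential", "linear")) {
  trend <- match.arg(trend)
  cv <- raw$curve
  ref <- raw$references
  sig <- cv$counts - background
  ref_sig <- ref$counts - background
  if (any(sig <= 0) || any(ref_sig <= 0)) {
    rlang::abort("Background subtraction leaves non-positive signal.")
  }
  # bleaching trend from the reference frames
  if (trend == "exponential") {
    fit <- stats::lm(log(ref_sig) ~ ref$order)
    slope <- stats::coef(fit)[2]
    bleach <- function(ord) exp(slope * ord)
    level0 <- exp(stats::coef(fit)[1])
  } else {
    fit <- stats::lm(ref_sig ~ ref$order)
    co <- stats::coef(fit)
    bleach <- function(ord) 1 + co[2] / co[1] * ord
    level0 <- co[1]
  }
  slope_se <- summary(fit)$coefficients[2, 2]
  if (stats::coef(fit)[2] > 2 * slope_se) {
    rlang::warn("Reference intensity increases with acquisition order; bleaching trend is non-monotone beyond noise.")
  }
  corr <- bleach(cv$order)
  span <- 1 - min(corr) / max(corr)
  if (span > 0.10) {
    rlang::warn(sprintf("Bleaching correction spans %.0f%% (> 10%%).", 100 * span))
  }
  value <- (sig / corr) / level0
  ord <- order(cv$w)
  meta <- raw$meta
  new_trast_curve(cv$w[ord], value[ord], meta = utils::modifyList(
    meta %||% list(), list(type = "trast", preprocessed = TRUE,
                           bleach_span = span)))
}
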