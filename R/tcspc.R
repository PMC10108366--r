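# TCSPC decay models and fits. Mono- or bi-exponential decays, optional
# instrument-response convolution, Poisson-weighted least squares with support
# for fixing individual lifetimes (e.g. fixing the N-state lifetime while
# fitting a second, shorter component attributed to the red photoisomer).

#' Build a TCSPC decay histogram container
#'
#' @param bin_times Uniform bin centre times, seconds, increasing.
#' @param counts Non-negative integer counts per bin.
#' @param irf Optional instrument response sampled on the same bins
#'   (normalized internally to unit sum).
#' @return A `decay_histogram` tibble with columns `time`, `counts` (and
#'   `irf`).
#' @export
decay_histogram <- function(bin_times, counts, irf = NULL) {
  if (any(counts < 0)) rlang::abort("`counts` must be >= 0.")
  dt <- diff(bin_times)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) {
    rlang::abort("`bin_times` must be uniform.")
  }
  out <- tibble::tibble(time = bin_times, counts = counts)
  if (!is.null(irf)) out$irf <- irf / sum(irf)
  class(out) <- c("decay_histogram", class(out))
  out
}

#' Expected counts of a multi-exponential decay
#'
#' `E(t) = sum_i a_i exp(-t/tau_i)` evaluated at the bin times, linearly
#' convolved with the instrument response when one is supplied, plus a
#' constant background per bin.
#'
#' @param amplitudes Component amplitudes (counts at t = 0), >= 0.
#' @param lifetimes Component lifetimes in seconds, > 0.
#' @param bin_times Uniform bin times, seconds.
#' @param irf Optional response on the same bins (any scale; normalized to
#'   unit sum, so the convolution preserves total amplitude).
#' @param background Constant background counts per bin.
#' @return Expected counts per bin.
#' @export
decay_expectation <- function(amplitudes, lifetimes, bin_times, irf = NULL,
                              background = 0) {
  if (length(amplitudes) != length(lifetimes)) {
    rlang::abort("`amplitudes` and `lifetimes` must have equal length.")
  }
  if (any(lifetimes <= 0)) rlang::abort("`lifetimes` must be > 0.")
  if (any(amplitudes < 0)) rlang::abort("`amplitudes` must be >= 0.")
  t0 <- bin_times - bin_times[1]
  decay <- colSums(amplitudes * exp(-outer(1 / lifetimes, t0)))
  if (!is.null(irf)) {
    k <- irf / sum(irf)
    n <- length(decay)
    full <- stats::convolve(decay, rev(k), type = "open")
    # FFT-based convolution can ring slightly negative; counts cannot
    decay <- pmax(full[seq_len(n)], 0)
  }
  decay + background
}

#' Fit an exponential decay model to a TCSPC histogram
#'
#' Weighted nonlinear least squares with Poisson weights
#' (`1/sqrt(max(counts, 1))`), via Levenberg-Marquardt. Any subset of
#' lifetimes can be fixed (e.g. the first to a known reference lifetime).
#' For two-component fits a mono-exponential fit is run alongside and the
#' reduced chi-square ratio mono/bi decides whether the second component is
#' supported (`threshold`, default 1.2); an unsupported second component is
#' flagged in the result.
#'
#' @param hist A [decay_histogram()]; its `irf` column, when present, is
#'   convolved into the model.
#' @param n_components 1 or 2.
#' @param fixed_lifetimes Named or positional numeric vector; `NA` entries are
#'   fitted, non-`NA` entries are held fixed (seconds).
#' @param background Fit a constant background (default `TRUE`).
#' @param min_counts Minimum total counts demanded before fitting.
#' @param threshold Reduced chi-square ratio below which the bi-exponential
#'   model is considered unsupported.
#' @return A `decay_fit` object: amplitudes, lifetimes, background,
#'   `rel_amplitude` (a2/(a1+a2)), reduced chi-square, fitted values,
#'   residuals, and for `n_components = 2` the mono/bi comparison.
#' @export
fit_decay <- function(hist, n_components = 1, fixed_lifetimes = NULL,
                      background = TRUE, min_counts = 1e4, threshold = 1.2) {
  stopifnot(n_components %in% c(1, 2))
  if (sum(hist$counts) < min_counts) {
    rlang::abort(sprintf("Histogram has %.0f counts; at least %g required.",
                         sum(hist$counts), min_counts))
  }
  fit <- fit_decay_one(hist, n_components, fixed_lifetimes, background)
  if (n_components == 2) {
    fx1 <- if (!is.null(fixed_lifetimes) && !is.na(fixed_lifetimes[1])) {
      fixed_lifetimes[1]
    } else NULL
    mono <- fit_decay_one(hist, 1, fx1, background)
    fit$chisq_mono <- mono$chisq_red
    fit$chisq_ratio <- mono$chisq_red / fit$chisq_red
    fit$second_component_supported <- fit$chisq_ratio >= threshold
  }
  fit
}

fit_decay_one <- function(hist, n_components, fixed_lifetimes, background) {
  counts <- hist$counts
  tt <- hist$time
  irf <- if ("irf" %in% names(hist)) hist$irf else NULL
  wts <- 1 / sqrt(pmax(counts, 1))
  fixed <- rep(NA_real_, n_components)
  if (!is.null(fixed_lifetimes)) {
    fixed[seq_along(fixed_lifetimes)] <- fixed_lifetimes
  }
  free_tau <- which(is.na(fixed))

  # moment-based initial guesses
  tot <- sum(counts)
  bg0 <- if (background) max(stats::median(utils::tail(counts, 20)), 1e-3) else 0
  sig <- pmax(counts - bg0, 0)
  tbar <- sum((tt - tt[1]) * sig) / max(sum(sig), 1)
  tau0 <- rep(max(tbar, diff(tt)[1]), n_components)
  if (n_components == 2) tau0 <- tau0 * c(1.5, 0.5)
  tau0[!is.na(fixed)] <- fixed[!is.na(fixed)]
  a0 <- rep(max(sig[1], 1) / n_components, n_components)

  par0 <- c(log(a0), log(tau0[free_tau]))
  if (background) par0 <- c(par0, log(max(bg0, 1e-3)))

  unpack <- function(par) {
    a <- exp(par[seq_len(n_components)])
    tau <- fixed
    tau[free_tau] <- exp(par[n_components + seq_along(free_tau)])
    bg <- if (background) exp(par[length(par)]) else 0
    list(a = a, tau = tau, bg = bg)
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    if (any(!is.finite(p$a)) || any(!is.finite(p$tau)) || any(p$tau <= 0)) {
      return(rep(1e6, length(counts)))
    }
    r <- (counts - decay_expectation(p$a, p$tau, tt, irf, p$bg)) * wts
    if (any(!is.finite(r))) rep(1e6, length(counts)) else r
  }
  ans <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (ans$info %in% c(0, 9)) {
    rlang::abort(paste0("Decay fit did not converge: ", ans$message))
  }
  p <- unpack(ans$par)
  mu <- decay_expectation(p$a, p$tau, tt, irf, p$bg)
  dof <- length(counts) - length(par0)
  structure(list(
    amplitudes = p$a, lifetimes = p$tau, background = p$bg,
    rel_amplitude = if (n_components == 2) p$a[2] / sum(p$a) else NA_real_,
    mean_lifetime = sum(p$a * p$tau) / sum(p$a),
    chisq_red = sum(((counts - mu) * wts)^2) / dof,
    fitted = mu, residuals = counts - mu, n_components = n_components,
    fixed_lifetimes = fixed, converged = TRUE, info = ans$info
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d component(s); chisq_red = %.3f\n",
              x$n_components, x$chisq_red))
  for (i in seq_along(x$lifetimes)) {
    cat(sprintf("  tau%d = %.4g ns (a = %.4g%s)\n", i, x$lifetimes[i] * 1e9,
                x$amplitudes[i],
                if (!is.na(x$fixed_lifetimes[i])) ", fixed" else ""))
  }
  if (!is.na(x$rel_amplitude)) {
    cat(sprintf("  relative amplitude a2/(a1+a2) = %.3f\n", x$rel_amplitude))
  }
  if (!is.null(x$second_component_supported)) {
    cat(sprintf("  mono/bi chisq ratio = %.3f (%s)\n", x$chisq_ratio,
                if (x$second_component_supported) "second component supported"
                else "second component NOT supported"))
  }
  invisible(x)
}
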