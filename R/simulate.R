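# Seeded synthetic-data generators emulating the experimental inputs with
# known ground truth: TRAST pulse-train acquisitions with Poisson counting and
# bleaching drift, FCS curves with lag-scaled noise, a Gillespie trajectory
# oracle for the blinking term, Poisson TCSPC histograms, and emission
# spectrum stacks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a raw TRAST pulse-train acquisition
#'
#' Generates Poisson photon counts for a stack of pulse trains with
#' logarithmically spaced pulse durations measured in randomized order, plus
#' interleaved reference frames at the normalization duration `w0` tracking
#' permanent bleaching. Bleaching is a multiplicative exponential decay over
#' acquisition order reaching `bleach_fraction` at the end of the run.
#'
#' @param params A [photo_params()] (ground truth).
#' @param protocol An [excitation_protocol()].
#' @param w_grid Pulse durations, seconds.
#' @param counts_per_point Expected counts for a frame at unit relative
#'   signal (sets the Poisson noise level).
#' @param bleach_fraction Total bleaching over the acquisition, <= 0.15.
#' @param n_references Number of interleaved reference frames.
#' @param seed Integer seed; recorded in the output.
#' @return A `trast_raw` list: `curve` (tibble `w`, `counts`, `order`),
#'   `references` (tibble `order`, `counts`), `meta`, and `truth` (the
#'   generating parameters and seed).
#' @export
gen_trast_experiment <- function(params, protocol,
                                 w_grid = log_grid(1e-7, 1e-2, 30),
                                 counts_per_point = 1e6,
                                 bleach_fraction = 0,
                                 n_references = 10,
                                 seed = 1) {
  if (bleach_fraction > 0.15 || bleach_fraction < 0) {
    rlang::abort("`bleach_fraction` must be in [0, 0.15].")
  }
  mean_sig <- pulse_average(params, protocol, c(protocol$w0, w_grid))
  n_w <- length(w_grid)
  n_tot <- n_w + n_references
  with_seed(seed, {
    w_order <- sample.int(n_w)                 # randomized acquisition order
    ref_slots <- round(seq(1, n_tot, length.out = n_references))
    orders <- setdiff(seq_len(n_tot), ref_slots)
    bleach <- function(ord) {
      if (bleach_fraction == 0) rep(1, length(ord))
      else exp(log(1 - bleach_fraction) * (ord - 1) / (n_tot - 1))
    }
    mu_curve <- counts_per_point * mean_sig[-1][w_order] * bleach(orders)
    mu_ref <- counts_per_point * mean_sig[1] * bleach(ref_slots)
    curve <- tibble::tibble(w = w_grid[w_order],
                            counts = stats::rpois(n_w, mu_curve),
                            order = orders)
    refs <- tibble::tibble(order = ref_slots,
                           counts = stats::rpois(n_references, mu_ref))
    structure(list(
      curve = curve, references = refs,
      meta = list(type = "trast", wavelength = protocol$wavelength,
                  irradiance = protocol$irradiance, band = protocol$band,
                  duty_cycle = protocol$duty_cycle, w0 = protocol$w0,
                  seed = seed),
      truth = list(params = params, protocol = protocol,
                   counts_per_point = counts_per_point,
                   bleach_fraction = bleach_fraction, seed = seed)
    ), class = "trast_raw")
  })
}

#' Simulate noisy FCS curves at several irradiances
#'
#' Model curves from [fcs_curve()] with additive Gaussian noise whose standard
#' deviation scales with the local correlation value,
#' `sd(tau) = rel_sigma * G(tau)` -- a pragmatic stand-in for the
#' measurement-time and count-rate dependence of correlator noise. The noise
#' sd is stored in an `sd` column, so fits weight by `1/sd`.
#'
#' @param params A [photo_params()] (ground truth).
#' @param geometry A [detection_geometry()].
#' @param irradiances Vector of irradiances, W/cm^2.
#' @param wavelength Excitation wavelength, nm.
#' @param band Emission band label.
#' @param tau_grid Log-spaced lag grid, seconds.
#' @param rel_sigma Relative noise level (0.01 = 1%).
#' @param seed Integer seed.
#' @return A list of `fcs_curve` tibbles with columns `tau`, `G`, `sd`.
#' @export
gen_fcs_curves <- function(params, geometry, irradiances, wavelength = 638,
                           band = "B", tau_grid = log_grid(1e-8, 1, 200),
                           rel_sigma = 0.01, seed = 1) {
  with_seed(seed, {
    lapply(irradiances, function(irr) {
      proto <- excitation_protocol(wavelength, irr, band = band)
      cv <- fcs_curve(params, geometry, proto, tau_grid)
      sd <- rel_sigma * cv$G
      g <- cv$G + stats::rnorm(length(sd), 0, sd)
      meta <- attr(cv, "meta")
      meta$seed <- seed
      new_fcs_curve(cv$tau, g, meta, sd = sd)
    })
  })
}

#' Gillespie trajectory of the three-state chain
#'
#' Simulates a continuous-time Markov chain over \{N, P1, P2\} with the given
#' effective rates, returning the jump path and a brightness trace binned on
#' a regular grid with brightness vector `q = (1, 0, Q)`. The binned trace's
#' autocorrelation is an independent stochastic estimate of the blinking term
#' `G_T`.
#'
#' @param rates A [rate_set()].
#' @param duration Total simulated time, seconds (should exceed the slowest
#'   relaxation many times over).
#' @param Q Brightness of P2 relative to N.
#' @param bin Bin width for the brightness trace, seconds.
#' @param seed Integer seed.
#' @param initial Initial state (1 = N, 2 = P1, 3 = P2).
#' @return A list with `path` (tibble `time`, `state`, `dwell`), `trace`
#'   (numeric brightness per bin), `bin`, and `seed`.
#' @export
gen_state_trajectory_ctmc <- function(rates, duration, Q = 0, bin = NULL,
                                      seed = 1, initial = 1L) {
  k12 <- rates$k_iso1_eff; k21 <- rates$k_biso1_eff
  k23 <- rates$k_iso2_eff; k32 <- rates$k_biso2_eff
  exit <- c(k12, k21 + k23, k32)
  if (is.null(bin)) {
    lam <- abs(relaxation_eigenvalues(rates)$values)
    fast <- max(lam)
    bin <- if (fast > 0) 0.1 / fast else duration / 1000
  }
  # keep the binned trace to a tractable length
  bin <- max(bin, duration / 2e6)
  with_seed(seed, {
    t_now <- 0
    s <- initial
    # preallocate generously; grow if needed
    cap <- max(1000L, ceiling(duration * max(exit) * 1.5) + 100L)
    times <- numeric(cap); states <- integer(cap)
    n <- 0L
    while (t_now < duration) {
      n <- n + 1L
      if (n > length(times)) {
        times <- c(times, numeric(length(times)))
        states <- c(states, integer(length(states)))
      }
      times[n] <- t_now
      states[n] <- s
      if (exit[s] == 0) break
      dt <- stats::rexp(1, exit[s])
      t_now <- t_now + dt
      s <- switch(s,
        2L,
        if (stats::runif(1) < k21 / (k21 + k23)) 1L else 3L,
        2L)
    }
    times <- times[seq_len(n)]; states <- states[seq_len(n)]
    dwell <- c(diff(times), duration - times[n])
    q <- c(1, 0, Q)
    edges <- seq(0, duration, by = bin)
    n_bins <- length(edges) - 1
    # time-weighted brightness per bin
    trace <- numeric(n_bins)
    starts <- times
    ends <- pmin(times + dwell, duration)
    for (i in seq_len(n)) {
      if (q[states[i]] == 0) next
      b0 <- max(1L, min(n_bins, findInterval(starts[i], edges)))
      b1 <- max(1L, min(n_bins, findInterval(ends[i], edges, left.open = TRUE)))
      if (b0 == b1) {
        trace[b0] <- trace[b0] + (ends[i] - starts[i]) * q[states[i]]
      } else {
        trace[b0] <- trace[b0] + (edges[b0 + 1] - starts[i]) * q[states[i]]
        trace[b1] <- trace[b1] + (ends[i] - edges[b1]) * q[states[i]]
        if (b1 > b0 + 1) {
          mid <- (b0 + 1):(b1 - 1)
          trace[mid] <- trace[mid] + bin * q[states[i]]
        }
      }
    }
    trace <- trace / bin
    list(path = tibble::tibble(time = times, state = states, dwell = dwell),
         trace = trace, bin = bin, seed = seed)
  })
}

#' Empirical blinking correlation from a CTMC brightness trace
#'
#' Estimates `G_T(k * bin) = <x(t) x(t + k*bin)> / <x>^2` from the binned
#' brightness trace of [gen_state_trajectory_ctmc()].
#'
#' @param trace Binned brightness trace.
#' @param max_lag Maximum lag in bins.
#' @return A tibble with columns `lag` (bins) and `G` .
#' @export
trace_correlation <- function(trace, max_lag = 100) {
  n <- length(trace)
  mx <- mean(trace)
  if (mx == 0) rlang::abort("Trace has zero mean brightness.")
  ks <- 0:max_lag
  g <- vapply(ks, function(k) {
    mean(trace[seq_len(n - k)] * trace[(1 + k):n]) / mx^2
  }, numeric(1))
  tibble::tibble(lag = ks, G = g)
}

#' Simulate a TCSPC decay histogram
#'
#' Poisson counts drawn from a multi-exponential decay expectation, with an
#' optional Gaussian instrument response of given FWHM convolved in.
#'
#' @param amplitudes Relative component amplitudes.
#' @param lifetimes Component lifetimes, seconds.
#' @param total_counts Expected total number of photons.
#' @param bin_width Bin width, seconds (default 4 ps).
#' @param n_bins Number of bins.
#' @param irf_fwhm Gaussian IRF full width at half maximum, seconds; `NULL`
#'   for a delta response.
#' @param background_fraction Fraction of counts from a flat background.
#' @param seed Integer seed.
#' @return A [decay_histogram()] (with `irf` column when an IRF is used).
#' @export
gen_tcspc <- function(amplitudes, lifetimes, total_counts = 1e6,
                      bin_width = 4e-12, n_bins = 1250, irf_fwhm = NULL,
                      background_fraction = 0, seed = 1) {
  if (total_counts < 1) rlang::abort("`total_counts` must be >= 1.")
  tt <- (seq_len(n_bins) - 0.5) * bin_width
  irf <- NULL
  if (!is.null(irf_fwhm)) {
    s <- irf_fwhm / (2 * sqrt(2 * log(2)))
    centre <- 10 * s
    irf <- stats::dnorm(tt, mean = centre, sd = s)
    irf <- irf / sum(irf)
  }
  shape <- decay_expectation(amplitudes, lifetimes, tt, irf, 0)
  mu_signal <- shape / sum(shape) * total_counts * (1 - background_fraction)
  mu <- mu_signal + total_counts * background_fraction / n_bins
  with_seed(seed, {
    decay_histogram(tt, stats::rpois(n_bins, mu), irf = irf)
  })
}

#' Simulate a noisy spectral-TRAST stack
#'
#' [simulate_spectral_stack()] plus the chosen noise model.
#'
#' @inheritParams simulate_spectral_stack
#' @param noise `"gaussian_relative"` (sd = `noise_level` times the stack
#'   maximum) or `"poisson"` (counts with `counts_scale` expected counts at
#'   the stack maximum); `"none"` for the exact synthesis.
#' @param noise_level Relative Gaussian noise level.
#' @param counts_scale Expected counts at the stack maximum (Poisson mode).
#' @param seed Integer seed.
#' @return A `spectral_stack` tibble.
#' @export
gen_spectral_stack <- function(params, protocol,
                               basis_N = emission_basis(790),
                               basis_P2 = emission_basis(820),
                               Q_spec = 1,
                               wavelengths = seq(700, 900, by = 2),
                               w_grid = log_grid(1e-7, 1e-3, 12),
                               noise = c("none", "gaussian_relative", "poisson"),
                               noise_level = 0.01, counts_scale = 1e5,
                               seed = 1) {
  noise <- match.arg(noise)
  stack <- simulate_spectral_stack(params, protocol, basis_N, basis_P2,
                                   Q_spec, wavelengths, w_grid)
  if (noise == "none") return(stack)
  meta <- attr(stack, "meta")
  meta$seed <- seed
  df <- tibble::as_tibble(stack)
  with_seed(seed, {
    if (noise == "gaussian_relative") {
      df$intensity <- df$intensity +
        stats::rnorm(nrow(df), 0, noise_level * max(df$intensity))
    } else {
      scale <- counts_scale / max(df$intensity)
      df$intensity <- stats::rpois(nrow(df), df$intensity * scale) / scale
    }
    new_spectral_stack(df, normalization = "none", meta = meta)
  })
}
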