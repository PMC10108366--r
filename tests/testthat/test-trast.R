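# TRAST forward model: emissive signal, pulse averages, normalized curves,
# beam-profile averaging.

test_that("emissive signal is anchored at 1 and follows p_N + Q*p_P2", {
  p <- scy7_params("trast638")
  r <- effective_rates(p, 638, 3900)
  tr <- populations_vs_time(r, log_grid(1e-9, 1e-2, 30))
  f0 <- emissive_signal(tr, 0)
  expect_equal(f0$F, tr$p_N)
  # equally bright states with no P1 occupation conserve the signal
  tr_flat <- tr
  tr_flat$p_P1 <- 0
  tr_flat$p_P2 <- 1 - tr_flat$p_N
  expect_equal(emissive_signal(tr_flat, 1)$F, rep(1, nrow(tr)))
  # Q > 1 with rising P2 exceeds 1 (inverse relaxation)
  p785 <- scy7_params("trast785")
  tr785 <- populations_vs_time(effective_rates(p785, 785, 6500),
                               log_grid(1e-7, 1e-2, 30))
  expect_gt(max(emissive_signal(tr785, 4.6)$F), 1)
})

test_that("pulse averages interpolate between F(0) = 1 and the stationary signal", {
  p <- scy7_params("trast638")
  proto <- excitation_protocol(638, 3900, band = "B")
  expect_equal(pulse_average(p, proto, 1e-12), 1, tolerance = 1e-6)
  r <- effective_rates(p, 638, 3900)
  lam_slow <- abs(relaxation_eigenvalues(r)$values[2])
  ss <- steady_state(r)
  expect_equal(pulse_average(p, proto, 1e4 / lam_slow), ss$p_N,
               tolerance = 1e-3)
})

test_that("analytic pulse average equals trapezoid quadrature of the ODE oracle", {
  p <- scy7_params("trast638")
  proto <- excitation_protocol(638, 3900, band = "B")
  for (w in c(1e-5, 1e-4, 1e-3)) {
    tt <- seq(0, w, length.out = 20001)
    r <- effective_rates(p, 638, 3900)
    tr <- populations_vs_time(r, tt[-1], method = "ode")
    quad <- pracma::trapz(tt, c(1, tr$p_N)) / w
    expect_equal(pulse_average(p, proto, w), quad, tolerance = 1e-6)
  }
})

test_that("TRAST curves are normalized at w0 and flat without isomerization", {
  p_flat <- photo_params(k_iso1 = 0, sigma_N = c("638" = 1.56e-16),
                         sigma_biso1 = c("638" = 1e-18),
                         sigma_iso2 = c("638" = 1e-17),
                         sigma_biso2 = c("638" = 1e-17),
                         tau_f = 0.52e-9)
  proto <- excitation_protocol(638, 3900, band = "B")
  cv <- trast_curve(p_flat, proto)
  expect_equal(cv$value, rep(1, nrow(cv)), tolerance = 1e-12)
  # normalization anchor: value at w = w0 is 1 by construction
  p <- scy7_params("trast638")
  cv2 <- trast_curve(p, proto, w_grid = c(proto$w0, log_grid(1e-6, 1e-2, 10)))
  expect_equal(cv2$value[1], 1, tolerance = 1e-12)
})

test_that("inverse relaxation appears for Q > 1 with fast P1-P2 conversion", {
  p785 <- scy7_params("trast785")
  cv <- trast_curve(p785, excitation_protocol(785, 6500, band = "R"))
  expect_true(all(diff(cv$value) >= -1e-12))
  expect_gt(max(cv$value), 1)
})

test_that("relaxation gets faster and deeper with irradiance in the B band", {
  p <- scy7_params("trast638")
  irr <- c(600, 3900)
  fits <- lapply(irr, function(i) {
    cv <- trast_curve(p, excitation_protocol(638, i, band = "B"),
                      w_grid = log_grid(1e-7, 1e-2, 40))
    fit_single_relaxation(cv)
  })
  expect_gt(fits[[2]]$A, fits[[1]]$A)        # amplitude grows with irradiance
  expect_lt(fits[[2]]$tau, fits[[1]]$tau)    # relaxation time shrinks
})

test_that("long-pulse curves take the sign of the stationary signal deficit", {
  # with two emissive states the transient can cross 1 (N decays before P2
  # builds up), so only the long-pulse limit carries a guaranteed sign; with
  # a dark photoisomer only (Q = 0) the whole curve stays on one side of 1
  set.seed(21)
  for (i in 1:20) {
    q <- stats::runif(1, 0, 5)
    v <- exp(stats::runif(2, log(1e3), log(1e7)))
    p <- photo_params(k_iso1 = 1e7, sigma_N = c("638" = 1.56e-16),
                      sigma_biso1 = c("638" = 1e-18),
                      sigma_iso2 = c("638" = 1e-17),
                      sigma_biso2 = c("638" = 1e-17),
                      k_biso1_th = v[1], k_biso2_th = v[2],
                      tau_f = 0.52e-9, Q_by_band = c(X = q, D = 0))
    proto <- excitation_protocol(638, stats::runif(1, 500, 5e3), band = "X")
    r <- effective_rates(p, proto$wavelength, proto$irradiance)
    ss <- steady_state(r)
    f_inf <- ss$p_N + q * ss$p_P2
    w_long <- 1e4 / max(abs(relaxation_eigenvalues(r)$values[2]), 1)
    cv <- trast_curve(p, proto, w_grid = c(proto$w0, w_long))
    dev_long <- cv$value[2] - 1
    if (abs(f_inf - 1) > 1e-3) {
      expect_equal(sign(dev_long), sign(f_inf - 1))
    }
    proto_d <- proto; proto_d$band <- "D"
    dev_dark <- trast_curve(p, proto_d)$value - 1
    expect_true(all(dev_dark <= 1e-12))
  }
})

test_that("two-state closed form is recovered when P2 is unreachable", {
  # sigma_iso2 = 0: exact single-exponential pulse-averaged relaxation
  p <- photo_params(k_iso1 = 1.4e7, sigma_N = c("638" = 1.56e-16),
                    sigma_biso1 = c("638" = 1.2e-18),
                    sigma_iso2 = c("638" = 0),
                    sigma_biso2 = c("638" = 2e-17),
                    k_biso1_th = 3.4e4, k_biso2_th = 1.1e4,
                    tau_f = 0.52e-9, Q_by_band = c(B = 0, R = 7))
  for (band in c("B", "R")) {
    proto <- excitation_protocol(638, 2600, band = band)
    r <- effective_rates(p, 638, 2600)
    k12 <- r$k_iso1_eff; k21 <- r$k_biso1_eff
    tau <- 1 / (k12 + k21)
    A <- k12 / (k12 + k21)
    w <- log_grid(1e-7, 1e-2, 25)
    shape <- 1 - A * (1 - (tau / w) * (1 - exp(-w / tau)))
    w0v <- proto$w0
    shape0 <- 1 - A * (1 - (tau / w0v) * (1 - exp(-w0v / tau)))
    cv <- trast_curve(p, proto, w_grid = w)
    expect_equal(cv$value, shape / shape0, tolerance = 1e-8)
  }
})

test_that("beam averaging reduces to the uniform curve and converges in quadrature", {
  p <- scy7_params("trast638")
  proto <- excitation_protocol(638, 2900, band = "B")
  w <- log_grid(1e-7, 1e-2, 15)
  uni <- beam_averaged_trast(p, proto, beam_profile("uniform"), w_grid = w)
  expect_equal(uni$value, trast_curve(p, proto, w_grid = w)$value,
               tolerance = 1e-12)
  gau <- beam_averaged_trast(p, proto, beam_profile("gaussian", waist = 15,
                                                    roi_radius = 15), w_grid = w)
  gau_fine <- beam_averaged_trast(p, proto,
                                  beam_profile("gaussian", waist = 15,
                                               roi_radius = 15),
                                  w_grid = w, n_nodes = 320)
  expect_lt(max(rel_err(gau$value, gau_fine$value)), 1e-5)
  # averaging over weaker annuli shallows the curve relative to peak irradiance
  expect_gt(min(gau$value), min(trast_curve(p, proto, w_grid = w)$value))
  # tiny ROI converges to the on-axis uniform curve
  tiny <- beam_averaged_trast(p, proto,
                              beam_profile("gaussian", waist = 15,
                                           roi_radius = 0.05), w_grid = w)
  expect_equal(tiny$value, trast_curve(p, proto, w_grid = w)$value,
               tolerance = 1e-4)
})
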