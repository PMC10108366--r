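# Kinetic core: unit conversions, effective rates, generator, steady state,
# time-dependent populations, relaxation spectrum, two-state reduction.

test_that("photon flux conversion matches direct evaluation of I*lambda/(h*c)", {
  expect_identical(photon_flux(0, 638), 0)
  expect_equal(photon_flux(3900, 638), 3900 * 638e-9 / HC, tolerance = 1e-12)
  expect_equal(photon_flux(3900, 638), 1.2526e22, tolerance = 1e-4)
  expect_equal(photon_flux(1000, 785), 1000 * 785e-9 / HC, tolerance = 1e-12)
  expect_equal(photon_flux(1000, 785), 3.9518e21, tolerance = 1e-4)
  expect_error(photon_flux(-1, 638), "irradiance")
  expect_error(photon_flux(1, 0), "wavelength")
})

test_that("extinction-to-cross-section conversion reproduces the published peak value", {
  # 240,600 L/mol/cm is the manufacturer extinction coefficient; the published
  # peak cross section is 9.2e-16 cm^2
  expect_equal(extinction_to_cross_section(240600), 9.2e-16, tolerance = 0.01)
  expect_identical(extinction_to_cross_section(0), 0)
  # inverse check: epsilon giving exactly 1e-16 cm^2
  eps <- 1e-16 * NA_CONST / (1000 * log(10))
  expect_equal(eps, 2.6153e4, tolerance = 1e-4)
  expect_equal(extinction_to_cross_section(eps), 1e-16, tolerance = 1e-12)
})

test_that("effective rates follow the printed rate definitions", {
  p <- scy7_params("fcs638")
  # zero irradiance: only thermal terms survive
  p_th <- photo_params(k_iso1 = 1e7, sigma_N = c("638" = 1e-16),
                       sigma_biso1 = c("638" = 1e-18),
                       sigma_iso2 = c("638" = 1e-17),
                       sigma_biso2 = c("638" = 1e-17),
                       k_biso1_th = 3.4e4, k_biso2_th = 1.1e4,
                       tau_f = 0.52e-9)
  r0 <- effective_rates(p_th, 638, 0)
  expect_identical(r0$k_iso1_eff, 0)
  expect_identical(r0$k_iso2_eff, 0)
  expect_equal(r0$k_biso1_eff, 3.4e4)
  expect_equal(r0$k_biso2_eff, 1.1e4)
  # hand evaluation at 100 kW/cm^2, 638 nm, FCS parameter column
  phi <- 1e5 * 638e-9 / HC
  k10 <- 1 / 0.52e-9 - 12.5e6
  r <- effective_rates(p, 638, 100e3)
  expect_equal(r$k_iso1_eff, 12.5e6 * 1.56e-16 * phi / k10, tolerance = 1e-12)
  expect_equal(r$k_iso1_eff, 3.28e5, tolerance = 2e-3)
  expect_equal(r$k_biso1_eff, 1.1e-18 * phi, tolerance = 1e-12)
  expect_equal(r$k_biso1_eff, 3.53e5, tolerance = 2e-3)
  # saturating form deviates at MW/cm^2 but agrees at TRAST irradiances
  r_sat_lo <- effective_rates(p, 638, 1e3, saturation = TRUE)
  r_lin_lo <- effective_rates(p, 638, 1e3)
  expect_equal(r_sat_lo$k_iso1_eff, r_lin_lo$k_iso1_eff, tolerance = 0.01)
  r_sat_hi <- effective_rates(p, 638, 1e6, saturation = TRUE)
  r_lin_hi <- effective_rates(p, 638, 1e6)
  expect_lt(r_sat_hi$k_iso1_eff, r_lin_hi$k_iso1_eff)
  expect_error(effective_rates(p, 700, 1e3), "700")
})

test_that("the generator conserves probability and matches the balance equations", {
  m <- rate_matrix(rate_set(1, 1, 1, 1))
  expect_equal(unname(diag(m)), c(-1, -2, -1))
  expect_equal(unname(colSums(m)), c(0, 0, 0))
  expect_true(all(m[row(m) != col(m)] >= 0))
  expect_equal(rate_matrix(rate_set(0, 0, 0, 0)), matrix(0, 3, 3,
    dimnames = list(c("N", "P1", "P2"), c("N", "P1", "P2"))))
  for (rs in random_rate_sets(25, seed = 11)) {
    expect_equal(max(abs(colSums(rate_matrix(rs)))), 0)
  }
})

test_that("steady state follows the detailed-balance chain closed form", {
  # symmetric rates
  expect_equal(as.numeric(steady_state(rate_set(1, 1, 1, 1))),
               rep(1 / 3, 3), tolerance = 1e-12)
  # no excitation: everything returns to N
  p <- scy7_params("trast638")
  r0 <- effective_rates(p, 638, 0)
  expect_equal(as.numeric(steady_state(r0)), c(1, 0, 0), tolerance = 1e-12)
  # FCS parameter column at 638 nm: dark fraction ~75%
  pf <- scy7_params("fcs638")
  ss <- steady_state(effective_rates(pf, 638, 100e3))
  # independent closed-form arithmetic
  phi <- 1e5 * 638e-9 / HC
  r1 <- 12.5e6 * 1.56e-16 * phi / (1 / 0.52e-9 - 12.5e6) / (1.1e-18 * phi)
  r2 <- 3.0e-17 / 1.3e-17
  expect_equal(ss$p_N, 1 / (1 + r1 + r1 * r2), tolerance = 1e-9)
  expect_equal(ss$p_N, 0.246, tolerance = 2e-3)
  expect_equal(ss$p_P1, 0.228, tolerance = 2e-3)
  expect_equal(ss$p_P2, 0.526, tolerance = 2e-3)
  # irradiance invariance below saturation with zero thermal rates
  ss2 <- steady_state(effective_rates(pf, 638, 700e3))
  expect_equal(as.numeric(ss), as.numeric(ss2), tolerance = 1e-9)
  # closed form equals the generator null space
  for (rs in random_rate_sets(100, seed = 3)) {
    p_cf <- as.numeric(steady_state(rs))
    ns <- rate_matrix(rs) %*% p_cf
    expect_lt(max(abs(ns)), 1e-8 * max(unlist(rs)))
  }
  expect_error(steady_state(rate_set(0, 0, 0, 0)), "zero")
  expect_error(steady_state(rate_set(1, 0, 1, 0)), "Degenerate|return")
})

test_that("excited-state saturation shifts the steady state back towards N", {
  # thermal-only back-isomerization: the dark build-up saturates with the
  # excited-state fraction, so p_N is non-increasing in irradiance
  p_th <- photo_params(k_iso1 = 1e7, sigma_N = c("638" = 1.56e-16),
                       sigma_biso1 = c("638" = 0), sigma_iso2 = c("638" = 0),
                       sigma_biso2 = c("638" = 1e-17),
                       k_biso1_th = 3.4e4, tau_f = 0.52e-9)
  irr <- 10^seq(3, 6.5, length.out = 12)
  pn <- vapply(irr, function(i) {
    steady_state(effective_rates(p_th, 638, i, saturation = TRUE))$p_N
  }, numeric(1))
  expect_true(all(diff(pn) <= 1e-12))
  # with excitation-driven back rates (which do not saturate), saturation of
  # the N excitation instead pushes the population back towards N at MW/cm^2
  p <- scy7_params("fcs638")
  pn_sat <- steady_state(effective_rates(p, 638, 1e6, saturation = TRUE))$p_N
  pn_lin <- steady_state(effective_rates(p, 638, 1e6))$p_N
  expect_gt(pn_sat, pn_lin)
})

test_that("eigen solution of the populations agrees with the ODE oracle", {
  # deterministic evolution, conservation, initial condition, asymptotics
  p <- scy7_params("trast638")
  r <- effective_rates(p, 638, 3900)
  times <- log_grid(1e-8, 1e-2, 40)
  tr <- populations_vs_time(r, times)
  expect_equal(rowSums(as.matrix(tr[, 2:4])), rep(1, nrow(tr)),
               tolerance = 1e-12)
  tr0 <- populations_vs_time(r, c(1e-12, 1))
  expect_equal(as.numeric(tr0[1, 2:4]), c(1, 0, 0), tolerance = 1e-3)
  # t -> infinity reaches the stationary distribution
  lam_slow <- abs(relaxation_eigenvalues(r)$values[2])
  tr_inf <- populations_vs_time(r, 30 / lam_slow)
  expect_equal(as.numeric(tr_inf[1, 2:4]), as.numeric(steady_state(r)),
               tolerance = 1e-9)
  # oracle equivalence across random rate sets
  for (rs in random_rate_sets(100, seed = 5, lo = 1e2, hi = 1e7)) {
    tt <- log_grid(1e-8, 1e-1, 12)
    a <- populations_vs_time(rs, tt, method = "auto")
    b <- populations_vs_time(rs, tt, method = "ode")
    expect_lt(max(abs(as.matrix(a[, 2:4]) - as.matrix(b[, 2:4]))), 1e-8)
  }
})

test_that("the relaxation spectrum has one zero and real negative eigenvalues", {
  sp <- relaxation_eigenvalues(rate_set(1, 1, 1, 1))
  expect_equal(sp$values, c(0, -1, -3), tolerance = 1e-12)
  expect_equal(relaxation_eigenvalues(rate_set(0, 0, 0, 0))$values, c(0, 0, 0))
  # two-state limit: the single nonzero eigenvalue is -(k_iso1' + k_biso1'),
  # i.e. the classic isomerization relaxation rate 1/tau_iso (the decoupled
  # P2 contributes a second zero mode)
  sp2 <- relaxation_eigenvalues(rate_set(3e4, 5e4, 0, 0))
  expect_equal(max(abs(sp2$values)), 8e4, tolerance = 1e-9)
  expect_equal(sort(abs(sp2$values))[1:2], c(0, 0), tolerance = 1e-12)
  for (rs in random_rate_sets(50, seed = 9)) {
    v <- relaxation_eigenvalues(rs)$values
    expect_identical(v[1], 0)
    expect_true(all(v[2:3] < 0))
    expect_true(all(Im(v) == 0))
    # amplitudes reproduce the trajectory when recombined
    sp <- relaxation_eigenvalues(rs)
    t1 <- 0.5 / max(abs(v))
    rec <- sp$vectors %*% (exp(sp$values * t1) * (sp$inv_vectors %*% c(1, 0, 0)))
    direct <- as.numeric(populations_vs_time(rs, t1)[1, 2:4])
    expect_equal(as.numeric(rec), direct, tolerance = 1e-8)
  }
})

test_that("two-state reduction lumps P1 and P2 at local equilibrium", {
  p <- scy7_params("fcs638")
  red <- reduce_two_state(p, 638, 200e3)
  r <- effective_rates(p, 638, 200e3)
  r2 <- r$k_iso2_eff / r$k_biso2_eff
  expect_equal(r2, 3.0e-17 / 1.3e-17, tolerance = 1e-9)
  expect_equal(red$Q_lump, 0 * r2 / (1 + r2))  # B-band Q = 0: dark lump
  ss <- steady_state(r)
  expect_equal(red$p_dark, ss$p_P1 + ss$p_P2, tolerance = 1e-9)
  # Q > 0 lump brightness equals the P2-weighted equilibrium average
  p785 <- scy7_params("trast785")
  red785 <- reduce_two_state(p785, 785, 5e3, band = "R")
  r785 <- effective_rates(p785, 785, 5e3)
  r2b <- r785$k_iso2_eff / r785$k_biso2_eff
  expect_equal(red785$Q_lump, 4.6 * r2b / (1 + r2b), tolerance = 1e-12)
  # sigma_iso2 = 0: lump is P1 only and dark
  p_no2 <- photo_params(k_iso1 = 1e7, sigma_N = c("638" = 1e-16),
                        sigma_biso1 = c("638" = 1e-18),
                        sigma_iso2 = c("638" = 0),
                        sigma_biso2 = c("638" = 1e-17),
                        tau_f = 0.5e-9, Q_by_band = c(B = 2))
  red0 <- suppressWarnings(reduce_two_state(p_no2, 638, 1e4))
  expect_identical(red0$Q_lump, 0)
  # poor timescale separation warns but still returns
  expect_warning(reduce_two_state(p_no2, 638, 1e4), "two-state reduction")
})

test_that("parameter validation rejects inconsistent photophysics", {
  expect_error(photo_params(k_iso1 = 3e9, sigma_N = c("638" = 1e-16),
                            sigma_biso1 = c("638" = 0), sigma_iso2 = c("638" = 0),
                            sigma_biso2 = c("638" = 0), tau_f = 0.52e-9),
               "k10_N")
  expect_error(rate_set(-1, 0, 0, 0), "rates")
})
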