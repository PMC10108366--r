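# Global fitting engine: spec roles, noise-free identifiability, scaled
# parameters, preprocessing, single-exponential relaxation fits,
# reproducibility.

test_that("fit specs validate roles and scaled references", {
  expect_error(fit_spec(par_fixed("Q_B", 0), par_fixed("Q_B", 1)), "once")
  expect_error(fit_spec(par_scaled("sigma_biso1", 1e-18, "F")), "factor")
  sp <- fit_spec_trast638()
  expect_setequal(sp$name[sp$role == "global"],
                  c("k_iso1", "sigma_biso1", "sigma_iso2", "sigma_biso2",
                    "k_th1", "k_th2", "Q_R"))
  expect_equal(sp$init[sp$name == "Q_B"], 0)
})

test_that("noise-free two-band TRAST curves are inverted to the generating parameters", {
  truth <- scy7_params("trast638")
  irr <- c(600, 1400, 2900, 3900)
  combos <- tidyr::expand_grid(irradiance = irr, band = c("B", "R"))
  curves <- purrr::pmap(combos, function(irradiance, band) {
    trast_curve(truth, excitation_protocol(638, irradiance, band = band))
  })
  fit <- global_fit_trast(curves, fit_spec_trast638(),
                          constants = list(sigma_N = truth$sigma_N,
                                           tau_f = truth$tau_f),
                          n_starts = 1, seed = 1)
  est <- tidy(fit)
  expected <- c(k_iso1 = 1.4e7, sigma_biso1 = 1.2e-18, sigma_iso2 = 2e-17,
                sigma_biso2 = 2e-17, k_th1 = 3.4e4, k_th2 = 1.1e4, Q_R = 0.56)
  for (nm in names(expected)) {
    expect_lt(rel_err(est$estimate[est$term == nm], expected[[nm]]), 1e-3)
  }
  expect_lt(fit$rss, 1e-12)
})

test_that("the recovered scaling factor equals the generating cross-section ratio", {
  truth <- scy7_params("trast785")
  b <- list(k_iso1 = 1.4e7, sigma_biso1 = 1.2e-18, sigma_iso2 = 2e-17,
            k_th1 = 3.4e4, k_th2 = 1.1e4)
  curves <- lapply(c(1700, 3300, 6500), function(irr) {
    trast_curve(truth, excitation_protocol(785, irr, band = "R"))
  })
  fit <- global_fit_trast(curves, fit_spec_trast785(b),
                          constants = list(sigma_N = truth$sigma_N,
                                           tau_f = truth$tau_f),
                          n_starts = 8, seed = 3)
  est <- tidy(fit)
  expect_lt(rel_err(est$estimate[est$term == "F"],
                    unname(truth$sigma_biso1["785"]) / b$sigma_biso1), 1e-3)
  expect_lt(rel_err(est$estimate[est$term == "Q_R"], 4.6), 1e-3)
  # resolved scaled parameters are reported alongside the factor
  expect_equal(est$estimate[est$term == "sigma_iso2"],
               est$estimate[est$term == "F"] * b$sigma_iso2, tolerance = 1e-12)
})

test_that("FCS fits collapse to the nested two-state truth", {
  # two-state generating model (P2 unreachable): the three-state fit must
  # drive sigma_iso2 to its lower bound and recover the two-state rates
  truth <- photo_params(k_iso1 = 1.25e7, sigma_N = c("638" = 1.56e-16),
                        sigma_biso1 = c("638" = 1.1e-18),
                        sigma_iso2 = c("638" = 0),
                        sigma_biso2 = c("638" = 1.3e-17),
                        tau_f = 0.52e-9)
  geom <- detection_geometry(N_m = 2, tau_D = 9.5e-5)
  curves <- gen_fcs_curves(truth, geom, c(100, 400) * 1e3, rel_sigma = 0.002,
                           seed = 5)
  fit <- global_fit_fcs(curves, fit_spec_fcs(),
                        constants = list(sigma_N = truth$sigma_N,
                                         tau_f = truth$tau_f, S = 6.8),
                        n_starts = 1, seed = 1)
  est <- tidy(fit)
  expect_lt(rel_err(est$estimate[est$term == "k_iso1"], 1.25e7), 0.05)
  expect_lt(rel_err(est$estimate[est$term == "sigma_biso1"], 1.1e-18), 0.05)
  # the P2 channel is driven to irrelevance: whatever point of the
  # (sigma_iso2, sigma_biso2) ridge the fit lands on, the recovered model's
  # stationary P2 population and blinking term match the two-state truth
  th <- est$estimate
  names(th) <- est$term
  rs_fit <- rate_set(th["k_iso1"] * 1.56e-16 * photon_flux(1e5, 638) /
                       (1 / 0.52e-9 - th["k_iso1"]),
                     th["sigma_biso1"] * photon_flux(1e5, 638),
                     th["sigma_iso2"] * photon_flux(1e5, 638),
                     th["sigma_biso2"] * photon_flux(1e5, 638))
  expect_lt(steady_state(rs_fit)$p_P2, 0.05)
  tau <- log_grid(1e-8, 1e-2, 30)
  gt_fit <- phototrast:::blinking_from_rates(rs_fit, 0, tau)
  gt_true <- fcs_blinking_three_state(truth, 638, 1e5, "B", tau)
  expect_lt(max(abs(gt_fit - gt_true)), 0.02 * (gt_true[1] - 1))
  # per-curve diffusion parameters are recovered too
  expect_equal(est$estimate[est$name == "N_m"], rep(2, 2), tolerance = 0.02)
  expect_equal(est$estimate[est$name == "tau_D"], rep(9.5e-5, 2),
               tolerance = 0.02)
})

test_that("Q cross-covariance with the P2 occupancy parameters is surfaced", {
  truth <- scy7_params("trast785")
  curves <- lapply(c(1700, 6500), function(irr) {
    cv <- trast_curve(truth, excitation_protocol(785, irr, band = "R"))
    cv$value <- cv$value * (1 + stats::rnorm(nrow(cv), 0, 1e-3))
    cv
  })
  b <- list(k_iso1 = 1.4e7, sigma_biso1 = 1.2e-18, sigma_iso2 = 2e-17,
            k_th1 = 3.4e4, k_th2 = 1.1e4)
  set.seed(2)
  fit <- global_fit_trast(curves, fit_spec_trast785(b),
                          constants = list(sigma_N = truth$sigma_N,
                                           tau_f = truth$tau_f),
                          n_starts = 8, seed = 2)
  qc <- phototrast:::q_correlation(fit)
  expect_false(is.null(qc))
  expect_gt(abs(qc), 0.5)
})

test_that("bleaching correction round-trips an 8% linear drift within 0.5%", {
  truth <- scy7_params("trast638")
  proto <- excitation_protocol(638, 2900, band = "B")
  clean <- trast_curve(truth, proto)
  raw <- gen_trast_experiment(truth, proto, counts_per_point = 1e7,
                              bleach_fraction = 0.08, seed = 77)
  corrected <- suppressWarnings(preprocess_trast(raw))
  expect_equal(corrected$w, clean$w)
  expect_lt(max(rel_err(corrected$value, clean$value)), 0.005)
  # zero background + flat references leave the curve unchanged up to noise
  raw0 <- gen_trast_experiment(truth, proto, counts_per_point = 1e8,
                               bleach_fraction = 0, seed = 78)
  flat <- suppressWarnings(preprocess_trast(raw0))
  expect_lt(max(rel_err(flat$value, clean$value)), 0.002)
  # background equal to the signal is rejected
  raw_bad <- raw0
  expect_error(preprocess_trast(raw_bad,
                                background = min(raw_bad$curve$counts)),
               "non-positive")
})

test_that("single-relaxation fits recover amplitude and time, including inverse sign", {
  # two-state synthetic curve with known closed form
  p <- photo_params(k_iso1 = 1.4e7, sigma_N = c("638" = 1.56e-16),
                    sigma_biso1 = c("638" = 1.2e-18),
                    sigma_iso2 = c("638" = 0), sigma_biso2 = c("638" = 0),
                    k_biso1_th = 3.4e4, tau_f = 0.52e-9)
  proto <- excitation_protocol(638, 2900, band = "B")
  r <- effective_rates(p, 638, 2900)
  A_true <- r$k_iso1_eff / (r$k_iso1_eff + r$k_biso1_eff)
  tau_true <- 1 / (r$k_iso1_eff + r$k_biso1_eff)
  cv <- trast_curve(p, proto, w_grid = log_grid(1e-7, 1e-2, 40))
  set.seed(9)
  cv$value <- cv$value + stats::rnorm(nrow(cv), 0, 0.005)
  fit <- fit_single_relaxation(cv)
  expect_lt(rel_err(fit$A, A_true), 0.02)
  expect_lt(rel_err(fit$tau, tau_true), 0.05)
  expect_false(fit$flat)
  # flat curve: amplitude consistent with zero
  flat_cv <- cv
  set.seed(10)
  flat_cv$value <- 1 + stats::rnorm(nrow(cv), 0, 0.002)
  fit_flat <- fit_single_relaxation(flat_cv)
  expect_true(abs(fit_flat$A) < 0.01)
  expect_true(fit_flat$flat)
  # inverse relaxation: negative amplitude
  p785 <- scy7_params("trast785")
  inv <- trast_curve(p785, excitation_protocol(785, 6500, band = "R"))
  expect_lt(fit_single_relaxation(inv)$A, 0)
  # global-tau mode shares one relaxation time across curves
  curves <- lapply(c(2000, 2900), function(irr) {
    trast_curve(p, excitation_protocol(638, irr, band = "B"))
  })
  gfit <- fit_single_relaxation(curves, global_tau = TRUE)
  expect_equal(gfit$tau[1], gfit$tau[2])
  expect_equal(nrow(gfit), 2)
})

test_that("identical seed, spec, and data give bitwise-identical estimates", {
  rec1 <- suppressWarnings(recover_parameters("trast638", replicates = 1,
                                              seed = 5, n_starts = 2,
                                              irradiances = c(1000, 3900),
                                              w_grid = log_grid(1e-7, 1e-2, 15)))
  rec2 <- suppressWarnings(recover_parameters("trast638", replicates = 1,
                                              seed = 5, n_starts = 2,
                                              irradiances = c(1000, 3900),
                                              w_grid = log_grid(1e-7, 1e-2, 15)))
  expect_identical(rec1$estimate, rec2$estimate)
})
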