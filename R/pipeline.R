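# Pipeline entry points: simulate -> fit -> recover, driven by plain config
# lists (or YAML files). These tie the generators and fitting engine together
# and are what the bundled command-line script dispatches to.

#' Parameter-recovery experiments for the standard fitting configurations
#'
#' Runs the full simulate-and-refit loop for one of the three standard
#' experiments, using the supplied ground-truth parameters:
#'
#' * `"fcs638"`: FCS curves at four irradiances (default 100-800 kW/cm^2,
#'   638 nm, B band, 1% lag-scaled noise), refitted with [fit_spec_fcs()].
#' * `"trast638"`: TRAST pulse-train acquisitions at the seven standard
#'   638 nm irradiances (0.6-3.9 kW/cm^2) in both emission bands with
#'   Poisson counting noise, preprocessed and refitted with
#'   [fit_spec_trast638()].
#' * `"trast785"`: TRAST acquisitions at the six standard 785 nm irradiances
#'   (1.7-6.5 kW/cm^2), R band, refitted with [fit_spec_trast785()] using
#'   638 nm-derived values in `base`.
#'
#' Each replicate uses seed `seed * 1000 + replicate`, so the whole experiment
#' is reproducible from one integer.
#'
#' @param experiment One of `"fcs638"`, `"trast638"`, `"trast785"`.
#' @param truth Ground-truth [photo_params()] (defaults to the bundled fitted
#'   values for the chosen experiment).
#' @param replicates Number of simulate-and-fit replicates.
#' @param seed Base seed.
#' @param n_starts Multi-start count per fit. Defaults per experiment: 4 for
#'   `"fcs638"` and `"trast638"`, 12 for `"trast785"`, whose likelihood has a
#'   local minimum at the fast-exchange (lumped P1/P2) limit that more starts
#'   are needed to escape. The fit functions themselves default to 16 for
#'   blind fits.
#' @param irradiances Override the irradiance set, W/cm^2.
#' @param counts_per_point Expected counts per TRAST point.
#' @param rel_sigma Relative FCS noise level.
#' @param geometry FCS detection geometry.
#' @param base 638 nm-derived reference values for `"trast785"` (defaults to
#'   the bundled TRAST(638) values).
#' @param w_grid Pulse-duration grid for TRAST experiments.
#' @return A tibble with one row per replicate and recovered parameter:
#'   `replicate`, `term`, `estimate`, `truth`.
#' @export
recover_parameters <- function(experiment = c("fcs638", "trast638", "trast785"),
                               truth = NULL,
                               replicates = 20, seed = 1, n_starts = NULL,
                               irradiances = NULL,
                               counts_per_point = 1e6, rel_sigma = 0.01,
                               geometry = detection_geometry(
                                 omega0 = 0.338, S = 6.8, N_m = 2, D = 300),
                               base = NULL,
                               w_grid = log_grid(1e-7, 1e-2, 30)) {
  experiment <- match.arg(experiment)
  n_starts <- n_starts %||% switch(experiment, trast785 = 12, 4)
  truth <- truth %||% scy7_params(switch(experiment,
    fcs638 = "fcs638", trast638 = "trast638", trast785 = "trast785"))
  one <- switch(experiment,
    fcs638 = function(rseed) {
      irr <- irradiances %||% (c(100, 200, 400, 800) * 1e3)
      curves <- gen_fcs_curves(truth, geometry, irr, wavelength = 638,
                               band = "B", rel_sigma = rel_sigma, seed = rseed)
      fit <- global_fit_fcs(curves, fit_spec_fcs(),
                            constants = list(sigma_N = truth$sigma_N,
                                             tau_f = truth$tau_f, S = geometry$S),
                            n_starts = n_starts, seed = rseed)
      truth_vals <- c(k_iso1 = truth$k_iso1,
                      sigma_biso1 = unname(truth$sigma_biso1["638"]),
                      sigma_iso2 = unname(truth$sigma_iso2["638"]),
                      sigma_biso2 = unname(truth$sigma_biso2["638"]))
      list(fit = fit, truth_vals = truth_vals)
    },
    trast638 = function(rseed) {
      irr <- irradiances %||% (c(0.6, 1, 1.4, 2, 2.6, 2.9, 3.9) * 1e3)
      combos <- tidyr::expand_grid(irradiance = irr, band = c("B", "R"))
      curves <- purrr::pmap(combos, function(irradiance, band) {
        proto <- excitation_protocol(638, irradiance, band = band)
        raw <- gen_trast_experiment(truth, proto, w_grid = w_grid,
                                    counts_per_point = counts_per_point,
                                    seed = rseed + 7919 * match(
                                      paste(irradiance, band),
                                      paste(combos$irradiance, combos$band)))
        preprocess_trast(raw)
      })
      fit <- global_fit_trast(curves, fit_spec_trast638(),
                              constants = list(sigma_N = truth$sigma_N,
                                               tau_f = truth$tau_f),
                              n_starts = n_starts, seed = rseed)
      truth_vals <- c(k_iso1 = truth$k_iso1,
                      sigma_biso1 = unname(truth$sigma_biso1["638"]),
                      sigma_iso2 = unname(truth$sigma_iso2["638"]),
                      sigma_biso2 = unname(truth$sigma_biso2["638"]),
                      k_th1 = truth$k_biso1_th, k_th2 = truth$k_biso2_th,
                      Q_R = unname(truth$Q_by_band["R"]))
      list(fit = fit, truth_vals = truth_vals)
    },
    trast785 = function(rseed) {
      irr <- irradiances %||% (c(1.7, 2.3, 3.3, 4.2, 4.9, 6.5) * 1e3)
      b <- base %||% {
        p638 <- scy7_params("trast638")
        list(k_iso1 = p638$k_iso1,
             sigma_biso1 = unname(p638$sigma_biso1["638"]),
             sigma_iso2 = unname(p638$sigma_iso2["638"]),
             k_th1 = p638$k_biso1_th, k_th2 = p638$k_biso2_th)
      }
      curves <- purrr::imap(irr, function(irradiance, i) {
        proto <- excitation_protocol(785, irradiance, band = "R")
        raw <- gen_trast_experiment(truth, proto, w_grid = w_grid,
                                    counts_per_point = counts_per_point,
                                    seed = rseed + 7919 * i)
        preprocess_trast(raw)
      })
      fit <- global_fit_trast(curves, fit_spec_trast785(b),
                              constants = list(sigma_N = truth$sigma_N,
                                               tau_f = truth$tau_f),
                              n_starts = n_starts, seed = rseed)
      truth_vals <- c(
        F = unname(truth$sigma_biso1["785"] / b$sigma_biso1),
        sigma_biso2 = unname(truth$sigma_biso2["785"]),
        Q_R = unname(truth$Q_by_band["R"]))
      list(fit = fit, truth_vals = truth_vals)
    })
  purrr::map_dfr(seq_len(replicates), function(r) {
    res <- one(seed * 1000 + r)
    est <- res$fit$estimates
    est <- est[is.na(est$curve) & est$term %in% names(res$truth_vals), ]
    tibble::tibble(replicate = r, term = est$term, estimate = est$estimate,
                   truth = unname(res$truth_vals[est$term]))
  })
}

#' Summarize a recovery experiment
#'
#' @param recovery Output of [recover_parameters()].
#' @return One row per parameter: median/mean estimate, truth, relative bias
#'   of the median, and relative RMSE.
#' @export
summarize_recovery <- function(recovery) {
  recovery |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      median = stats::median(.data$estimate),
      mean = mean(.data$estimate),
      rel_bias_median = stats::median(.data$estimate) / .data$truth[1] - 1,
      rel_rmse = sqrt(mean((.data$estimate / .data$truth[1] - 1)^2)),
      n = dplyr::n(),
      .groups = "drop")
}

# ---- config-driven entry points ---------------------------------------------

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) rlang::abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  config
}

config_params <- function(config) {
  if (!is.null(config$params_file)) {
    sets <- read_params(config$params_file)
    if (inherits(sets, "photo_params")) sets
    else sets[[config$params_set %||% names(sets)[1]]]
  } else if (!is.null(config$params_set)) {
    scy7_params(config$params_set)
  } else {
    rlang::abort("Config needs `params_file` or `params_set`.")
  }
}

#' Run a simulation job from a config
#'
#' Config fields: `kind` (`"trast"`, `"fcs"`, `"tcspc"`, or `"spectra"`),
#' `outdir`, `seed`, `params_set` (bundled set name) or `params_file`, and
#' per-kind settings (`irradiances` in W/cm^2, `wavelength`, `band`,
#' `duty_cycle`, plus generator options). Writes one data file per condition,
#' a `truth.params` sidecar, and a `manifest.tsv`.
#'
#' @param config A list or path to a YAML file.
#' @return Invisibly, the manifest tibble.
#' @export
run_simulate <- function(config) {
  cf <- load_config(config)
  outdir <- cf$outdir %||% rlang::abort("Config needs `outdir`.")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cf$seed %||% 1
  params <- config_params(cf)
  kind <- cf$kind %||% "trast"
  files <- character()
  if (kind == "trast") {
    irr <- cf$irradiances %||% rlang::abort("Config needs `irradiances`.")
    bands <- cf$bands %||% "B"
    combos <- tidyr::expand_grid(irradiance = irr, band = bands)
    files <- purrr::pmap_chr(combos, function(irradiance, band) {
      i <- match(paste(irradiance, band), paste(combos$irradiance, combos$band))
      proto <- excitation_protocol(cf$wavelength %||% 638, irradiance,
                                   duty_cycle = cf$duty_cycle %||% 0.01,
                                   band = band)
      raw <- gen_trast_experiment(params, proto,
                                  counts_per_point = cf$counts_per_point %||% 1e6,
                                  bleach_fraction = cf$bleach_fraction %||% 0,
                                  seed = seed + 7919 * i)
      cv <- preprocess_trast(raw)
      f <- file.path(outdir, sprintf("trast_%gnm_%gWcm2_%s.tsv",
                                     proto$wavelength, irradiance, band))
      write_curve(cv, f)
      f
    })
  } else if (kind == "fcs") {
    geometry <- detection_geometry(
      omega0 = cf$omega0 %||% 0.338, S = cf$S %||% 6.8,
      N_m = cf$N_m %||% 2, D = cf$D %||% 300)
    curves <- gen_fcs_curves(params, geometry, cf$irradiances,
                             wavelength = cf$wavelength %||% 638,
                             band = cf$band %||% "B",
                             rel_sigma = cf$rel_sigma %||% 0.01, seed = seed)
    files <- purrr::map2_chr(curves, cf$irradiances, function(cv, irr) {
      f <- file.path(outdir, sprintf("fcs_%gnm_%gWcm2.tsv",
                                     cf$wavelength %||% 638, irr))
      write_curve(cv, f)
      f
    })
  } else if (kind == "tcspc") {
    hist <- gen_tcspc(cf$amplitudes %||% 1,
                      cf$lifetimes %||% params$tau_f,
                      total_counts = cf$total_counts %||% 1e6,
                      irf_fwhm = cf$irf_fwhm, seed = seed)
    files <- file.path(outdir, "tcspc.tsv")
    write_decay(hist, files)
  } else if (kind == "spectra") {
    proto <- excitation_protocol(cf$wavelength %||% 638,
                                 cf$irradiance %||% 3900,
                                 duty_cycle = cf$duty_cycle %||% 0.01)
    stack <- gen_spectral_stack(params, proto,
                                Q_spec = cf$Q_spec %||% 1,
                                noise = cf$noise %||% "none", seed = seed)
    files <- file.path(outdir, "spectral_stack.tsv")
    write_stack(stack, files)
  } else {
    rlang::abort(paste0("Unknown simulation kind: ", kind))
  }
  write_params(params, file.path(outdir, "truth.params"))
  manifest <- tibble::tibble(file = files, kind = kind, seed = seed)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Run a global fit from a config
#'
#' Config fields: `curves` (vector of curve files) or `manifest` (a
#' `manifest.tsv` from [run_simulate()]), `fit` (`"fcs"`, `"trast638"`, or
#' `"trast785"`), `outdir`, `seed`, `n_starts`, and for `"trast785"` a `base`
#' list of 638 nm-derived values. Writes the tidied estimates and an audit
#' block (inputs, seed, convergence) to `fit_result.txt`.
#'
#' @param config A list or path to a YAML file.
#' @return Invisibly, the `photo_fit` object.
#' @export
run_fit <- function(config) {
  cf <- load_config(config)
  outdir <- cf$outdir %||% rlang::abort("Config needs `outdir`.")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- cf$curves %||% {
    mf <- utils::read.delim(cf$manifest %||%
                              rlang::abort("Config needs `curves` or `manifest`."))
    mf$file
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(paste0("Curve file(s) not found: ",
                        paste(missing, collapse = ", ")))
  }
  curves <- lapply(paths, read_curve)
  seed <- cf$seed %||% 1
  n_starts <- cf$n_starts %||% 16
  kind <- cf$fit %||% rlang::abort("Config needs `fit`.")
  fit <- switch(kind,
    fcs = global_fit_fcs(curves, fit_spec_fcs(), n_starts = n_starts,
                         seed = seed),
    trast638 = global_fit_trast(curves, fit_spec_trast638(),
                                n_starts = n_starts, seed = seed),
    trast785 = global_fit_trast(curves, fit_spec_trast785(cf$base),
                                n_starts = n_starts, seed = seed),
    rlang::abort(paste0("Unknown fit kind: ", kind)))
  est <- tidy(fit)
  out <- file.path(outdir, "fit_result.txt")
  lines <- c(
    "# fit result",
    paste0("# inputs: ", paste(paths, collapse = " ")),
    paste0("# seed: ", seed),
    paste0("# n_starts: ", n_starts),
    paste0("# rss: ", format(fit$rss, digits = 15)),
    paste0("# converged_starts: ", sum(is.finite(fit$start_rss))),
    "term\testimate\tse",
    sprintf("%s\t%.10g\t%.4g", est$term, est$estimate, est$se))
  writeLines(lines, out)
  invisible(fit)
}

#' Run a recovery study from a config
#'
#' Config fields: `experiment` (`"fcs638"`, `"trast638"`, `"trast785"`),
#' `replicates`, `seed`, `n_starts`, `outdir`, and optional generator
#' overrides. Writes per-replicate estimates and the summary table.
#'
#' @param config A list or path to a YAML file.
#' @return Invisibly, the summary tibble from [summarize_recovery()].
#' @export
run_recover <- function(config) {
  cf <- load_config(config)
  outdir <- cf$outdir %||% rlang::abort("Config needs `outdir`.")
  replicates <- cf$replicates %||% rlang::abort("Config needs `replicates`.")
  if (replicates < 1) rlang::abort("`replicates` must be >= 1.")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rec <- recover_parameters(cf$experiment %||% "trast638",
                            replicates = replicates,
                            seed = cf$seed %||% 1,
                            n_starts = cf$n_starts %||% 4)
  summ <- summarize_recovery(rec)
  utils::write.table(rec, file.path(outdir, "recovery_replicates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(summ, file.path(outdir, "recovery_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(summ)
}
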