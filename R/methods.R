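# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a global fit
#'
#' @param x A `photo_fit` from [global_fit_trast()] or [global_fit_fcs()].
#' @param ... Unused.
#' @return A tibble with one row per fitted (or resolved scaled) parameter:
#'   `term`, `name`, `curve` (NA for shared parameters), `estimate`, `se`.
#' @method tidy photo_fit
#' @export
tidy.photo_fit <- function(x, ...) x$estimates

#' @rdname tidy.photo_fit
#' @method glance photo_fit
#' @export
glance.photo_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, dof = x$dof, n_points = x$n_points,
                 n_curves = x$n_curves, n_starts = x$n_starts,
                 n_converged = sum(is.finite(x$start_rss)),
                 seed = x$seed, converged = x$converged)
}

#' Tidy a TCSPC decay fit
#'
#' @param x A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  n <- x$n_components
  tibble::tibble(
    term = c(paste0("amplitude", seq_len(n)), paste0("lifetime", seq_len(n)),
             "background"),
    estimate = c(x$amplitudes, x$lifetimes, x$background),
    fixed = c(rep(FALSE, n), !is.na(x$fixed_lifetimes), FALSE)
  )
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, chisq_red = x$chisq_red,
                 rel_amplitude = x$rel_amplitude,
                 mean_lifetime = x$mean_lifetime,
                 second_component_supported =
                   x$second_component_supported %||% NA)
}

#' Plot methods
#'
#' `autoplot()` methods draw each curve type the way it is usually shown:
#' TRAST curves on a log pulse-duration axis, FCS curves on a log lag axis,
#' state trajectories as populations versus log time, spectral stacks as one
#' spectrum per pulse duration, and decay histograms on a log count axis.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name phototrast-autoplot
NULL

#' @rdname phototrast-autoplot
#' @method autoplot trast_curve
#' @export
autoplot.trast_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$w, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pulse duration w (s)",
                  y = "normalized mean fluorescence")
}

#' @rdname phototrast-autoplot
#' @method autoplot fcs_curve
#' @export
autoplot.fcs_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$tau, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)))
}

#' @rdname phototrast-autoplot
#' @method autoplot state_trajectory
#' @export
autoplot.state_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("p_N", "p_P1", "p_P2"),
                            names_to = "state", values_to = "population")
  df$state <- sub("^p_", "", df$state)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$population,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time after excitation onset (s)", y = "population")
}

#' @rdname phototrast-autoplot
#' @method autoplot spectral_stack
#' @export
autoplot.spectral_stack <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$w_label <- factor(signif(df$w, 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$intensity,
                                   colour = .data$w_label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "emission wavelength (nm)", y = "intensity",
                  colour = "w (s)")
}

#' @rdname phototrast-autoplot
#' @method autoplot decay_histogram
#' @export
autoplot.decay_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "counts")
}
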