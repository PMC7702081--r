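#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial distribution function
#' @param object An [compute_rdf()] profile.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rdf_profile
#' @export
autoplot.rdf_profile <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "g(r)",
                  title = if (!is.null(pair)) paste(pair, collapse = "-")) +
    ggplot2::theme_minimal()
}

#' Plot a time correlation function
#' @param object A `tcf` tibble (e.g. [dipole_tcf()], [continuous_hb_tcf()]).
#' @param log_y Plot log10 of the value (default TRUE, the usual way to read
#'   exponential decays).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcf
#' @export
autoplot.tcf <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ps)", y = "C(t)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a VDOS spectrum
#' @param object A [vdos()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vdos_spectrum
#' @export
autoplot.vdos_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber, y = .data$intensity,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a dielectric spectrum
#' @param object A [dielectric_spectrum()].
#' @param ... Unused.
#' @return A ggplot (log-frequency axis; real and loss parts).
#' @method autoplot dielectric_spectrum
#' @export
autoplot.dielectric_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("eps_real", "eps_imag"),
                              names_to = "part", values_to = "eps")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq, y = .data$eps,
                                     colour = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (GHz)", y = "permittivity") +
    ggplot2::theme_minimal()
}

#' Plot a classified subpopulation table
#' @param object A [classify_empirical_rule()] table.
#' @param ... Unused.
#' @return A ggplot of retardation factors with the bulk window shaded.
#' @method autoplot subpop_table
#' @export
autoplot.subpop_table <- function(object, ...) {
  df <- object[!is.na(object$f), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$f))
  if (!is.null(attr(object, "bulk_sigma"))) {
    m <- attr(object, "bulk_mean"); s <- attr(object, "bulk_sigma")
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = m - 3 * s, ymax = m + 3 * s,
                               alpha = 0.15, fill = "green4")
  }
  if ("class" %in% names(df)) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$f - .data$f_sigma, ymax = .data$f + .data$f_sigma,
                   colour = .data$class))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = NULL, y = "retardation factor f") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a DRS hydration-number series
#' @param object A [run_drs_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot of N_hyd versus concentration.
#' @method autoplot drs_series
#' @export
autoplot.drs_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$concentration, y = .data$N_hyd)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "concentration (mol/kg)", y = expression(N[hyd])) +
    ggplot2::theme_minimal()
}
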