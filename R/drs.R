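#' Construct a dielectric spectrum
#'
#' Complex permittivity versus frequency over the GHz window, with the sample
#' metadata needed by the depolarization analysis.
#'
#' @param freq Frequency grid (GHz), strictly increasing.
#' @param eps_real,eps_imag Real and imaginary permittivity (dielectric
#'   convention: `eps = eps_real - i eps_imag`, `eps_imag >= 0` for a lossy
#'   medium).
#' @param conductivity DC conductivity (S/m); 0 for pure water.
#' @param concentration Solute molality (mol/kg).
#' @param water_concentration Water molarity (mol/L).
#' @return Tibble of class `dielectric_spectrum` with columns `freq`,
#'   `eps_real`, `eps_imag`; metadata in attributes.
#' @export
dielectric_spectrum <- function(freq, eps_real, eps_imag, conductivity = 0,
                                concentration = 0, water_concentration = NA_real_) {
  stopifnot(length(freq) == length(eps_real), length(freq) == length(eps_imag))
  if (any(diff(freq) <= 0)) stop("`freq` must be strictly increasing", call. = FALSE)
  out <- tibble::tibble(freq = freq, eps_real = eps_real, eps_imag = eps_imag)
  class(out) <- c("dielectric_spectrum", class(out))
  attr(out, "conductivity") <- conductivity
  attr(out, "concentration") <- concentration
  attr(out, "water_concentration") <- water_concentration
  out
}

#' Read / write dielectric spectra as CSV
#'
#' The CSV holds columns `freq_GHz`, `eps_real`, `eps_imag`; metadata
#' (conductivity, molality, water molarity) travels in a YAML sidecar
#' `<path>.yml` when present.
#'
#' @param path CSV path.
#' @return A [dielectric_spectrum()].
#' @export
read_dielectric_spectrum <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("freq_GHz", "eps_real", "eps_imag")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("spectrum CSV is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  meta <- list(conductivity_S_per_m = 0, molality = 0, water_molarity = NA_real_)
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) meta <- modifyList(meta, yaml::read_yaml(sidecar))
  dielectric_spectrum(df$freq_GHz, df$eps_real, df$eps_imag,
                      conductivity = meta$conductivity_S_per_m,
                      concentration = meta$molality,
                      water_concentration = meta$water_molarity)
}

#' @rdname read_dielectric_spectrum
#' @param spec A [dielectric_spectrum()].
#' @export
write_dielectric_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  readr::write_csv(tibble::tibble(freq_GHz = spec$freq, eps_real = spec$eps_real,
                                  eps_imag = spec$eps_imag), path)
  yaml::write_yaml(list(conductivity_S_per_m = attr(spec, "conductivity"),
                        molality = attr(spec, "concentration"),
                        water_molarity = attr(spec, "water_concentration")),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Calibrate an open-ended coaxial probe (bilinear model)
#'
#' The bilinear probe model maps the measured reflection coefficient rho to
#' the sample permittivity, `eps = (A rho + C) / (1 + B rho)`. Three standards
#' of known permittivity determine the complex coefficients A, B, C exactly
#' via the linear system `A rho - B rho eps + C = eps`.
#'
#' @param eps Complex (or numeric) vector of 3 known permittivities.
#' @param rho Complex vector of 3 measured reflection coefficients.
#' @return Object of class `probe_calibration` with fields `A`, `B`, `C` and
#'   an `apply(rho)` closure returning permittivities.
#' @export
calibrate_probe <- function(eps, rho) {
  stopifnot(length(eps) == 3, length(rho) == 3)
  eps <- as.complex(eps); rho <- as.complex(rho)
  m <- cbind(rho, -rho * eps, rep(1 + 0i, 3))
  sv <- svd(m)$d
  if (min(sv) < 1e-10 * max(sv)) {
    stop("calibration standards are degenerate (singular system)", call. = FALSE)
  }
  abc <- solve(m, eps)
  cal <- list(A = abc[1], B = abc[2], C = abc[3])
  cal$apply <- function(rho) (cal$A * rho + cal$C) / (1 + cal$B * rho)
  structure(cal, class = "probe_calibration")
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat(sprintf("<probe_calibration> A = %s, B = %s, C = %s\n",
              format(x$A), format(x$B), format(x$C)))
  invisible(x)
}

#' Remove the Ohmic conductivity loss from a spectrum
#'
#' Subtracts `sigma / (omega eps_0)` (with `omega = 2 pi nu` in rad/s) from
#' the dielectric loss so that only dipolar relaxation remains; the real part
#' is unchanged. [add_conductivity()] is the exact inverse.
#'
#' @param spec A [dielectric_spectrum()] carrying its conductivity.
#' @param conductivity Override (S/m); default from the spectrum.
#' @return Corrected spectrum (conductivity attribute set to 0).
#' @export
remove_conductivity <- function(spec, conductivity = NULL) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  sigma <- conductivity %||% attr(spec, "conductivity")
  if (is.null(sigma) || is.na(sigma)) stop("spectrum has no conductivity set", call. = FALSE)
  if (sigma < 0) stop("conductivity must be non-negative", call. = FALSE)
  omega <- 2 * pi * spec$freq * 1e9
  out <- dielectric_spectrum(spec$freq, spec$eps_real,
                             spec$eps_imag - sigma / (omega * .eps0),
                             conductivity = 0,
                             concentration = attr(spec, "concentration"),
                             water_concentration = attr(spec, "water_concentration"))
  out
}

#' @rdname remove_conductivity
#' @export
add_conductivity <- function(spec, conductivity) {
  stopifnot(inherits(spec, "dielectric_spectrum"), conductivity >= 0)
  omega <- 2 * pi * spec$freq * 1e9
  dielectric_spectrum(spec$freq, spec$eps_real,
                      spec$eps_imag + conductivity / (omega * .eps0),
                      conductivity = conductivity,
                      concentration = attr(spec, "concentration"),
                      water_concentration = attr(spec, "water_concentration"))
}

#' Double-Debye model permittivity
#'
#' `eps(nu) = S1/(1 + i omega tau1) + S2/(1 + i omega tau2) + eps_inf`, the
#' two modes being the slow (~20 GHz) and fast (~1 THz) relaxations of water.
#'
#' @param freq Frequencies (GHz).
#' @param S1,S2 Mode strengths.
#' @param tau1,tau2 Relaxation times (ps), slow mode first.
#' @param eps_inf High-frequency permittivity.
#' @return Complex vector `eps_real - i eps_imag`.
#' @export
double_debye_eps <- function(freq, S1, S2, tau1, tau2, eps_inf = 3.52) {
  omega_tau1 <- 2 * pi * freq * 1e9 * tau1 * 1e-12
  omega_tau2 <- 2 * pi * freq * 1e9 * tau2 * 1e-12
  S1 / (1 + 1i * omega_tau1) + S2 / (1 + 1i * omega_tau2) + eps_inf
}

#' Fit the double-Debye relaxation model
#'
#' Simultaneous bounded least squares on the real and imaginary parts of a
#' conductivity-corrected spectrum, with equal absolute weights. The slow and
#' fast modes are initialized at 20 GHz and 1 THz and multi-started over
#' perturbed time constants; after fitting, modes are swapped if needed so
#' that `tau1 > tau2` (mode 1 is the slow one).
#'
#' @param spec A conductivity-corrected [dielectric_spectrum()].
#' @param eps_inf Fixed high-frequency permittivity (default 3.52).
#' @param n_starts Multi-start count (default 5).
#' @return Object of class `debye_fit`: `S1`, `S2`, `tau1`, `tau2` (ps),
#'   `eps_inf`, `residual_rms`, plus the sample metadata of the spectrum.
#' @export
fit_double_debye <- function(spec, eps_inf = 3.52, n_starts = 5) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  freq <- spec$freq
  target <- c(spec$eps_real - eps_inf, spec$eps_imag)
  resid_fn <- function(p) {
    eps <- double_debye_eps(freq, p[1], p[2], p[3], p[4], eps_inf = 0)
    c(Re(eps), -Im(eps)) - target
  }
  s_total <- max(spec$eps_real) - eps_inf
  tau1_0 <- 1e12 / (2 * pi * 20e9)   # slow mode centred at 20 GHz -> ps
  tau2_0 <- 1e12 / (2 * pi * 1e12)   # fast mode centred at 1 THz -> ps
  scales <- exp(seq(-0.7, 0.7, length.out = n_starts))
  best <- NULL
  for (s in scales) {
    p0 <- c(S1 = max(s_total * 0.95, 1), S2 = max(s_total * 0.05, 0.1),
            tau1 = tau1_0 * s, tau2 = tau2_0 / s)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn, lower = c(0, 0, 1e-4, 1e-4),
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("double-Debye fit failed to converge from every start", call. = FALSE)
  p <- best$fit$par
  if (p[3] < p[4]) p <- p[c(2, 1, 4, 3)]  # enforce tau1 > tau2
  structure(
    list(S1 = unname(p[1]), S2 = unname(p[2]), tau1 = unname(p[3]),
         tau2 = unname(p[4]), eps_inf = eps_inf,
         residual_rms = sqrt(best$rss / (2 * length(freq))),
         conductivity = attr(spec, "conductivity"),
         concentration = attr(spec, "concentration"),
         water_concentration = attr(spec, "water_concentration")),
    class = "debye_fit"
  )
}

#' @export
print.debye_fit <- function(x, ...) {
  cat(sprintf(
    "<debye_fit> S1 = %.3f (tau1 = %.3f ps), S2 = %.3f (tau2 = %.3f ps), eps_inf = %.2f\n  static eps = %.3f, residual rms = %.3g\n",
    x$S1, x$tau1, x$S2, x$tau2, x$eps_inf, x$S1 + x$S2 + x$eps_inf, x$residual_rms
  ))
  invisible(x)
}

#' Tidy a double-Debye fit
#' @param x A `debye_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @method tidy debye_fit
#' @export
tidy.debye_fit <- function(x, ...) {
  tibble::tibble(
    term = c("S1", "tau1", "S2", "tau2", "eps_inf"),
    estimate = c(x$S1, x$tau1, x$S2, x$tau2, x$eps_inf)
  )
}

#' One-row summary of a double-Debye fit
#' @param x A `debye_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance debye_fit
#' @export
glance.debye_fit <- function(x, ...) {
  tibble::tibble(
    S_total = x$S1 + x$S2, static_eps = x$S1 + x$S2 + x$eps_inf,
    tau1 = x$tau1, tau2 = x$tau2, residual_rms = x$residual_rms,
    concentration = x$concentration %||% NA_real_
  )
}

#' Kinetic and static depolarization of a solution spectrum
#'
#' Splits the dielectric-strength change of a solution relative to pure water
#' into its kinetic and static parts. Strength changes are signed losses
#' (negative when the solution is depolarized):
#' `dS_total = S(c) - S(0)` with `S = S1 + S2`;
#' `dS_kinetic = -(2/3) sigma(c) tau1(0) (eps_s(0) - eps_inf(c)) /
#' (eps_s(0) eps_0)` in SI units, the 2/3 factor being the perfect-slip
#' boundary condition at the ion surface;
#' `dS_static = dS_total - dS_kinetic` is the strength removed by
#' irrotationally bound (slow) waters.
#'
#' @param fit_c [fit_double_debye()] of the solution spectrum.
#' @param fit_0 [fit_double_debye()] of the pure-water reference.
#' @param sigma_c Solution conductivity (S/m); default from `fit_c`.
#' @param eps_s0 Static permittivity of pure water; default
#'   `S1(0) + S2(0) + eps_inf`.
#' @param eps_inf_c High-frequency permittivity of the solution; default the
#'   fit's `eps_inf`.
#' @return Object of class `depolarization_result` with fields `dS_total`,
#'   `dS_kinetic`, `dS_static`, and the echoed inputs.
#' @export
static_depolarization <- function(fit_c, fit_0, sigma_c = NULL, eps_s0 = NULL,
                                  eps_inf_c = NULL) {
  stopifnot(inherits(fit_c, "debye_fit"))
  if (!inherits(fit_0, "debye_fit")) {
    stop("missing pure-water reference fit", call. = FALSE)
  }
  sigma_c <- sigma_c %||% fit_c$conductivity
  if (is.null(sigma_c) || is.na(sigma_c)) stop("solution conductivity not available", call. = FALSE)
  eps_s0 <- eps_s0 %||% (fit_0$S1 + fit_0$S2 + fit_0$eps_inf)
  eps_inf_c <- eps_inf_c %||% fit_c$eps_inf
  s_c <- fit_c$S1 + fit_c$S2
  s_0 <- fit_0$S1 + fit_0$S2
  tau1_0_s <- fit_0$tau1 * 1e-12
  dS_total <- s_c - s_0
  dS_kinetic <- -(2 / 3) * sigma_c * tau1_0_s * (eps_s0 - eps_inf_c) / (eps_s0 * .eps0)
  structure(
    list(dS_total = dS_total, dS_kinetic = dS_kinetic,
         dS_static = dS_total - dS_kinetic,
         S_c = s_c, S_0 = s_0, sigma_c = sigma_c, tau1_0 = fit_0$tau1,
         eps_s0 = eps_s0, eps_inf_c = eps_inf_c,
         concentration = fit_c$concentration,
         water_concentration_c = fit_c$water_concentration,
         water_concentration_0 = fit_0$water_concentration),
    class = "depolarization_result"
  )
}

#' @export
print.depolarization_result <- function(x, ...) {
  cat(sprintf(
    "<depolarization_result> dS_total = %.3f, dS_kinetic = %.3f, dS_static = %.3f\n",
    x$dS_total, x$dS_kinetic, x$dS_static
  ))
  invisible(x)
}

#' DRS hydration number from static depolarization
#'
#' `N_hyd = cH2O(c)/c - (S(0) + dS_static)/S(0) * cH2O(0)/c`: the number of
#' water molecules per dissolved salt unit removed from the bulk-like
#' relaxation, combining the dilution effect and the static depolarization.
#' A negative result (within fit noise for weakly hydrated salts) is reported
#' with a warning rather than clipped.
#'
#' @param dep A [static_depolarization()] result.
#' @param c Solute molality (mol/kg); default from the solution fit.
#' @param cH2O_c,cH2O_0 Water molarity of the solution and of pure water
#'   (mol/L); defaults from the fit metadata.
#' @param S0 Reference strength S(0); default `S1(0) + S2(0)` (switchable to
#'   `S1(0)` only by passing it explicitly).
#' @return N_hyd (waters per salt unit).
#' @export
drs_hydration_number <- function(dep, c = NULL, cH2O_c = NULL, cH2O_0 = NULL,
                                 S0 = NULL) {
  stopifnot(inherits(dep, "depolarization_result"))
  c <- c %||% dep$concentration
  cH2O_c <- cH2O_c %||% dep$water_concentration_c
  cH2O_0 <- cH2O_0 %||% dep$water_concentration_0
  S0 <- S0 %||% dep$S_0
  if (is.null(c) || is.na(c) || c <= 0) stop("solute concentration must be positive", call. = FALSE)
  if (anyNA(c(cH2O_c, cH2O_0))) stop("water concentrations not available", call. = FALSE)
  if (S0 <= 0) stop("`S0` must be positive", call. = FALSE)
  n_hyd <- cH2O_c / c - (S0 + dep$dS_static) / S0 * cH2O_0 / c
  if (n_hyd < 0) {
    warning(sprintf("negative hydration number (%.2f); reporting unclipped", n_hyd),
            call. = FALSE)
  }
  n_hyd
}
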