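#' Configuration for the hydration-number pipeline
#'
#' Validated bundle of every tunable the end-to-end analysis uses. Defaults
#' mirror the standard protocol for this analysis: 16 ps reorientation
#' window, 1024 time origins, 4 uncertainty blocks, 3-sigma Empirical-Rule
#' window, geometric HB criteria as in [hb_criteria()].
#'
#' @param cation,anion Ion element symbols.
#' @param cation_shells,anion_shells [shell_boundaries()] or `"auto"` to
#'   detect them from the cation-O / anion-H RDFs (with `fallback_*` used
#'   when detection fails).
#' @param window Reorientation TCF window (ps).
#' @param fit_start Bi-exponential fit start (ps).
#' @param n_origins_target Time-origin target.
#' @param n_blocks Uncertainty blocks.
#' @param n_sigma Empirical-Rule window width.
#' @param sigma_mode See [classify_empirical_rule()].
#' @param min_origin_samples See [subpopulation_taus()].
#' @param rdf_bin_width RDF bin width for `"auto"` shells (Angstrom).
#' @param fallback_cation_shells,fallback_anion_shells Boundaries used when
#'   auto-detection fails.
#' @param bulk_tau Optional externally supplied bulk reference time (ps).
#' @param output_dir Optional directory for the artifact bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cation = "Mg", anion = "Cl",
                       cation_shells = "auto", anion_shells = "auto",
                       window = 16, fit_start = 0.2, n_origins_target = 1024,
                       n_blocks = 4, n_sigma = 3,
                       sigma_mode = "combined", min_origin_samples = 50,
                       rdf_bin_width = 0.05,
                       fallback_cation_shells = shell_boundaries(3.0, 5.0),
                       fallback_anion_shells = shell_boundaries(3.0, 5.2),
                       bulk_tau = NULL, output_dir = NULL) {
  check_shells <- function(x, what) {
    if (!(identical(x, "auto") || inherits(x, "shell_boundaries"))) {
      stop(sprintf("`%s` must be \"auto\" or shell_boundaries()", what), call. = FALSE)
    }
  }
  check_shells(cation_shells, "cation_shells")
  check_shells(anion_shells, "anion_shells")
  stopifnot(window > 0, fit_start >= 0, n_origins_target >= 1, n_blocks >= 1,
            n_sigma > 0, rdf_bin_width > 0)
  structure(
    list(cation = cation, anion = anion, cation_shells = cation_shells,
         anion_shells = anion_shells, window = window, fit_start = fit_start,
         n_origins_target = n_origins_target, n_blocks = n_blocks,
         n_sigma = n_sigma, sigma_mode = sigma_mode,
         min_origin_samples = min_origin_samples,
         rdf_bin_width = rdf_bin_width,
         fallback_cation_shells = fallback_cation_shells,
         fallback_anion_shells = fallback_anion_shells,
         bulk_tau = bulk_tau, output_dir = output_dir),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full hydration-number pipeline on a trajectory
#'
#' Executes the whole chain: water topology, shell boundaries (RDF minima or
#' supplied), per-origin subpopulation labelling, per-subpopulation
#' reorientation TCFs and bi-exponential fits, retardation factors,
#' Empirical-Rule classification, and the hydration number. With
#' `output_dir` set, writes `subpopulations.csv`, `result.json`, per-label
#' TCF CSVs and a `log.txt` carrying the configuration digest.
#'
#' @param traj A [trajectory()].
#' @param config A [run_config()].
#' @return List of class `hydration_pipeline_result`: `result`
#'   (a [hydration_number()] object), `table` (classified subpopulation
#'   table), `boundaries`, `config`.
#' @export
run_hydration_pipeline <- function(traj, config = run_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(config, "run_config"))
  topo <- stage("topology", build_water_topology(traj))
  if (length(ion_atoms(topo, config$cation)) == 0) {
    stop(sprintf("[stage validate] no ions of species %s in the trajectory", config$cation),
         call. = FALSE)
  }
  if (length(ion_atoms(topo, config$anion)) == 0) {
    stop(sprintf("[stage validate] no ions of species %s in the trajectory", config$anion),
         call. = FALSE)
  }
  cs <- stage("shells", resolve_shells(traj, topo, config, "cation"))
  as_ <- stage("shells", resolve_shells(traj, topo, config, "anion"))
  table <- stage("subpopulations", subpopulation_taus(
    traj, topo, cs, as_, cation = config$cation, anion = config$anion,
    window = config$window, fit_start = config$fit_start,
    n_origins_target = config$n_origins_target, n_blocks = config$n_blocks,
    min_origin_samples = config$min_origin_samples))
  table <- stage("retardation", retardation_factors(table, bulk_tau = config$bulk_tau))
  table <- stage("classification", classify_empirical_rule(
    table, n_sigma = config$n_sigma, sigma_mode = config$sigma_mode))
  n_salt <- length(ion_atoms(topo, config$cation))
  result <- stage("hydration_number", hydration_number(table, n_salt))
  out <- structure(list(result = result, table = table,
                        boundaries = list(cation = cs, anion = as_),
                        config = config),
                   class = "hydration_pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_bundle(out, config$output_dir)
  out
}

resolve_shells <- function(traj, topo, config, which_ion) {
  given <- config[[paste0(which_ion, "_shells")]]
  if (inherits(given, "shell_boundaries")) return(given)
  species <- config[[which_ion]]
  site_el <- if (which_ion == "cation") "O" else "H"
  r_max <- min(traj$cell) / 2 * 0.99
  rdf <- compute_rdf(traj, c(species, site_el), r_max = r_max,
                     bin_width = config$rdf_bin_width,
                     frames = unique(round(seq(1, traj$n_frames, length.out = min(50, traj$n_frames)))))
  find_shell_minima(rdf, fallback = config[[paste0("fallback_", which_ion, "_shells")]])
}

#' @export
print.hydration_pipeline_result <- function(x, ...) {
  print(x$result)
  n_slow <- sum(x$table$class == "slow")
  cat(sprintf("  %d slow / %d fitted subpopulations; bulk sigma = %.3g\n",
              n_slow, sum(!is.na(x$table$tau)), attr(x$table, "bulk_sigma")))
  invisible(x)
}

write_pipeline_bundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tables"), showWarnings = FALSE)
  readr::write_csv(drop_tcf_class(out$table), file.path(dir, "tables", "subpopulations.csv"))
  jsonlite::write_json(glance(out$result), file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  curves <- attr(out$table, "curves")
  for (lab in names(curves)) {
    readr::write_csv(tibble::tibble(lag_ps = curves[[lab]]$lag,
                                    value = curves[[lab]]$value),
                     file.path(dir, "tables", paste0("c1_", lab, ".csv")))
  }
  cfg <- out$config
  cfg_str <- utils::capture.output(utils::str(cfg, give.attr = FALSE))
  writeLines(c(sprintf("solvshell %s", as.character(utils::packageVersion("solvshell"))),
               sprintf("config sha: %s", config_digest(cfg)), cfg_str),
             file.path(dir, "log.txt"))
  invisible(dir)
}

drop_tcf_class <- function(x) {
  class(x) <- setdiff(class(x), c("subpop_table", "tcf"))
  x
}

config_digest <- function(cfg) {
  # cheap structural digest (sum of char codes of the serialized config)
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

#' Run the dielectric-relaxation analysis over a concentration series
#'
#' Fits the pure-water reference and every solution spectrum with the
#' double-Debye model (after removing the Ohmic conductivity term), computes
#' the kinetic/static depolarization split against the reference, and the
#' DRS hydration number per concentration.
#'
#' @param reference Pure-water [dielectric_spectrum()] (conductivity 0).
#' @param solutions List of solution spectra, each carrying conductivity,
#'   molality and water molarity.
#' @param eps_inf Fixed high-frequency permittivity (default 3.52).
#' @return Tibble of class `drs_series` with one row per concentration:
#'   Debye parameters, `dS_total`, `dS_kinetic`, `dS_static`, `N_hyd`.
#'   Attribute `reference_fit` holds the pure-water [fit_double_debye()].
#' @export
run_drs_pipeline <- function(reference, solutions, eps_inf = 3.52) {
  if (missing(reference) || !inherits(reference, "dielectric_spectrum")) {
    stop("[stage validate] missing pure-water reference spectrum", call. = FALSE)
  }
  if (inherits(solutions, "dielectric_spectrum")) solutions <- list(solutions)
  for (s in solutions) {
    if (is.null(attr(s, "conductivity")) || is.na(attr(s, "conductivity"))) {
      stop("[stage validate] solution spectrum lacks conductivity_S_per_m", call. = FALSE)
    }
  }
  fit_0 <- stage("reference_fit", fit_double_debye(reference, eps_inf = eps_inf))
  rows <- purrr::map(solutions, function(s) {
    corrected <- stage("conductivity", remove_conductivity(s))
    fit_c <- stage("debye_fit", fit_double_debye(corrected, eps_inf = eps_inf))
    fit_c$conductivity <- attr(s, "conductivity")
    dep <- stage("depolarization", static_depolarization(fit_c, fit_0))
    n_hyd <- stage("hydration_number", drs_hydration_number(dep))
    tibble::tibble(
      concentration = attr(s, "concentration"),
      conductivity = attr(s, "conductivity"),
      S1 = fit_c$S1, tau1 = fit_c$tau1, S2 = fit_c$S2, tau2 = fit_c$tau2,
      dS_total = dep$dS_total, dS_kinetic = dep$dS_kinetic,
      dS_static = dep$dS_static, N_hyd = n_hyd
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("drs_series", class(out))
  attr(out, "reference_fit") <- fit_0
  out
}
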